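# shared fixtures: built in code, no stored data

# a small DKI-capable table: 1 b0 + the 6 coordinate/diagonal axes repeated
# is NOT rank-22; tests that need a full-rank scheme use default_gradients()
paper_gtab <- function() default_gradients()

# draw a random valid single-voxel parameter set: positive-definite-ish
# diagonal-dominant D and moderate kurtosis so all signals stay positive
random_tensors <- function() {
  d_diag <- runif(3, 0.4, 1.8) * 1e-3
  d_off <- runif(3, -0.1, 0.1) * 1e-3
  w <- c(runif(3, 0.2, 1.5), runif(12, -0.15, 0.15))
  list(s0 = runif(1, 50, 200), D = c(d_diag, d_off), W = w)
}

max_rel_err <- function(est, truth) {
  scale <- pmax(abs(truth), 1e-4 * max(abs(truth)))
  max(abs(est - truth) / scale)
}

# constant-map axis_metrics fixture
constant_maps <- function(vals, dims = c(12L, 12L, 8L), voxel = 2) {
  mk <- function(v) array(v, dims)
  axis_metric_maps(mk(vals[1]), mk(vals[2]), mk(vals[3]),
                   mk(vals[4]), mk(vals[5]), mk(vals[6]),
                   affine = diag(c(voxel, voxel, voxel, 1)))
}

# the ROI set used with 12x12x8 constant maps (mirrors the phantom layout)
test_roiset <- function(diameter = 5) {
  alps_roiset(list(proj_left = c(4, 4, 6), assoc_left = c(4, 18, 6),
                   proj_right = c(18, 4, 6), assoc_right = c(18, 18, 6)),
              diameter = diameter)
}
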