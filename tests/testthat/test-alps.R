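test_that("sphere masks contain exactly the lattice points inside the radius", {
  # independent oracle: enumerate integer offsets
  lattice_count <- function(spacing, diam) {
    g <- expand.grid(x = -5:5, y = -5:5, z = -5:5) * spacing
    sum(g$x^2 + g$y^2 + g$z^2 <= (diam / 2)^2)
  }
  # 1 mm grid, 5 mm sphere centered on a voxel center
  m1 <- sphere_mask(c(10, 10, 10), 5, diag(4), c(21L, 21L, 21L))
  expect_equal(sum(m1), lattice_count(1, 5))   # 81
  expect_equal(sum(m1), 81L)
  # 2 mm grid: center + six face neighbours
  m2 <- sphere_mask(c(10, 10, 10), 5, diag(c(2, 2, 2, 1)), c(11L, 11L, 11L))
  expect_equal(sum(m2), lattice_count(2, 5))   # 7
  expect_equal(sum(m2), 7L)

  expect_error(sphere_mask(c(500, 0, 0), 5, diag(4), c(10L, 10L, 10L),
                           name = "proj_left"), "proj_left")
})

test_that("the ALPS ratio follows the displayed form and its invariances", {
  expect_equal(alps_ratio(1.2, 1.4, 0.8, 0.9), 1.3 / 0.85)
  expect_equal(alps_ratio(0.7, 0.7, 0.7, 0.7), 1.0)
  # degree-0 homogeneity
  expect_equal(alps_ratio(2 * 1.2, 2 * 1.4, 2 * 0.8, 2 * 0.9),
               alps_ratio(1.2, 1.4, 0.8, 0.9))
  expect_error(alps_ratio(1, 1, -2, 1), "not positive")
})

test_that("ROI means average non-NaN voxels and report provenance", {
  maps <- constant_maps(c(1.0, 0.6, 1.6, 1.3, 0.8, 0.6) * 1e-3)
  rs <- test_roiset()
  left <- extract_roi_means(maps, rs, "left")
  expect_equal(left$dxx_proj, 1.0e-3)
  expect_equal(left$dzz_assoc, 1.6e-3)
  expect_equal(unname(left$n_voxels["proj"]), 7L)

  # one NaN voxel inside the proj ROI: mean over the remaining voxels
  maps$dxx[3, 3, 4] <- NaN                   # proj_left sphere member
  maps$dxx[2, 3, 4] <- 5e-3                  # another member, shifted
  left2 <- extract_roi_means(maps, rs, "left")
  expect_equal(left2$dxx_proj, (5 * 1.0e-3 + 5e-3) / 6)

  maps$dxx[sphere_mask(c(4, 4, 6), 5, maps$affine, dim(maps$dxx))] <- NaN
  expect_error(extract_roi_means(maps, rs, "left"), "proj_left")
})

test_that("roiset validation enforces the four keys and disjointness", {
  expect_error(alps_roiset(list(proj_left = c(0, 0, 0))), "exactly")
  expect_error(alps_roiset(list(proj_left = c(0, 0, 0), assoc_left = c(0, 0, 4),
                                proj_right = c(10, 0, 0), assoc_right = c(10, 0, 4)),
                           diameter = -1), "positive")
  # proj/assoc spheres 4 mm apart with 5 mm diameter overlap on a 2 mm grid
  rs <- alps_roiset(list(proj_left = c(4, 4, 6), assoc_left = c(4, 8, 6),
                         proj_right = c(18, 4, 6), assoc_right = c(18, 8, 6)))
  maps <- constant_maps(rep(1, 6))
  expect_error(extract_roi_means(maps, rs, "left"), "overlap")
})

test_that("indices reproduce direct substitution on region-constant maps", {
  # phantom-backed substitution: assigned diagonals, both hemispheres identical
  ph <- build_phantom(phantom_spec())
  maps <- axis_metrics(dki_fit(ph$dwi), "tensor")
  res <- compute_alps(maps, ph$roiset)
  expect_equal(res$dti_left, mean(c(1.0, 1.1)) / mean(c(0.6, 0.55)),
               tolerance = 1e-9)            # 1.826086...
  expect_equal(res$dti_right, res$dti_left, tolerance = 1e-9)
  expect_equal(res$dti_global, (res$dti_left + res$dti_right) / 2)
  expect_equal(res$dki_left, mean(c(1.30, 1.35)) / mean(c(0.80, 0.80)),
               tolerance = 1e-8)

  # kurtosis maps that copy the diffusivity maps force dki == dti
  m2 <- axis_metric_maps(maps$dxx, maps$dyy, maps$dzz,
                         maps$dxx, maps$dyy, maps$dzz, maps$affine)
  r2 <- compute_alps(m2, ph$roiset)
  expect_equal(r2$dki_left, r2$dti_left)
  expect_equal(r2$dki_global, r2$dti_global)
})

test_that("indices are scale invariant and monotone in dxx", {
  ph <- build_phantom(phantom_spec(grid_shape = c(12L, 12L, 8L), box_width = 3L))
  maps <- axis_metrics(dki_fit(ph$dwi), "tensor")
  res <- compute_alps(maps, ph$roiset)
  scaled <- maps
  for (nm in c("dxx", "dyy", "dzz", "kxxxx", "kyyyy", "kzzzz"))
    scaled[[nm]] <- 3.7 * maps[[nm]]
  rs <- compute_alps(scaled, ph$roiset)
  for (nm in c("dti_left", "dti_right", "dti_global",
               "dki_left", "dki_right", "dki_global"))
    expect_equal(rs[[nm]], res[[nm]], tolerance = 1e-12)

  up <- maps; up$dxx <- maps$dxx * 1.15     # raise dxx everywhere
  ru <- compute_alps(up, ph$roiset)
  expect_gt(ru$dti_left, res$dti_left)
  expect_gt(ru$dti_right, res$dti_right)
})

test_that("hemisphere asymmetry appears only on the altered side", {
  models <- default_phantom_models()
  mr <- models$proj_right
  models$proj_right <- explicit_model(mr$D[1:3] * c(1.3, 1, 1), mr$W[1:3], mr$s0)
  ph <- build_phantom(phantom_spec(models = models))
  maps <- axis_metrics(dki_fit(ph$dwi))
  res <- compute_alps(maps, ph$roiset)
  expect_gt(res$dti_right, res$dti_left)
  expect_equal(res$dti_global, (res$dti_left + res$dti_right) / 2)
  # analytic ground truth matches the altered-side pipeline too
  expect_equal(res$dti_right, ph$truth$dti[["right"]], tolerance = 1e-8)
})

test_that("the pooled whole-brain option averages ROI means before the ratio", {
  models <- default_phantom_models()
  mr <- models$proj_right
  models$proj_right <- explicit_model(mr$D[1:3] * c(1.4, 0.8, 1), mr$W[1:3], mr$s0)
  ph <- build_phantom(phantom_spec(models = models))
  maps <- axis_metrics(dki_fit(ph$dwi))
  rm_ <- compute_alps(maps, ph$roiset, global = "mean")
  rp <- compute_alps(maps, ph$roiset, global = "pooled")
  expect_equal(rp$dti_left, rm_$dti_left)   # sides unaffected
  expect_false(isTRUE(all.equal(rp$dti_global, rm_$dti_global)))
  left <- extract_roi_means(maps, ph$roiset, "left")
  right <- extract_roi_means(maps, ph$roiset, "right")
  expect_equal(rp$dti_global,
               alps_ratio((left$dxx_proj + right$dxx_proj) / 2,
                          (left$dxx_assoc + right$dxx_assoc) / 2,
                          (left$dyy_proj + right$dyy_proj) / 2,
                          (left$dzz_assoc + right$dzz_assoc) / 2))
})

test_that("axis-metric maps round-trip through NIfTI with their sidecar", {
  ph <- build_phantom(phantom_spec(grid_shape = c(10L, 10L, 6L), box_width = 3L))
  maps <- axis_metrics(dki_fit(ph$dwi), "apparent")
  d <- tempfile(); dir.create(d)
  write_axis_metrics(maps, d, extra = list(method = "wls"))
  back <- read_axis_metrics(d)
  expect_equal(back$convention, "apparent")
  expect_equal(back$dxx, maps$dxx, tolerance = 1e-6)
  r1 <- compute_alps(maps, ph$roiset)
  r2 <- compute_alps(back, ph$roiset)
  expect_equal(r2$dti_global, r1$dti_global, tolerance = 1e-5)
})
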