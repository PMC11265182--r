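#' Tissue models for phantom regions
#'
#' An explicit model is a single kurtosis-signal compartment with an assigned
#' diffusion-tensor diagonal and optional kurtosis diagonal. A mixture model
#' is a sum of Gaussian (zero-kurtosis) compartments — the standard way to
#' realize crossing fibres, whose mixture has positive excess kurtosis along
#' axes where the compartment diffusivities differ.
#'
#' @param D diffusion tensor: length-3 diagonal or length-6 vector (mm^2/s).
#' @param W kurtosis tensor: length-3 diagonal (`wxxxx, wyyyy, wzzzz`) or
#'   length-15 vector; `NULL` for zero kurtosis.
#' @param s0 non-weighted signal.
#' @return a `phantom_model` list.
#' @export
explicit_model <- function(D, W = NULL, s0 = 100) {
  D <- expand_d(D)
  if (any(D[1:3] <= 0)) stop("explicit D diagonal must be positive")
  structure(list(type = "explicit", s0 = s0, D = D, W = expand_w(W)),
            class = "phantom_model")
}

#' @param fractions compartment volume fractions (sum to 1).
#' @param Ds list of compartment diffusion tensors (length-3 or length-6).
#' @rdname explicit_model
#' @export
mixture_model <- function(fractions, Ds, s0 = 100) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("mixture fractions must sum to 1")
  if (length(fractions) != length(Ds)) stop("one fraction per compartment")
  Ds <- lapply(Ds, expand_d)
  structure(list(type = "mixture", s0 = s0, fractions = as.numeric(fractions),
                 Ds = Ds),
            class = "phantom_model")
}

#' Noiseless signal of a phantom model
#'
#' Explicit models evaluate the forward kurtosis signal ([dki_signal()]);
#' mixtures sum compartment mono-exponentials
#' `S(b, n) = s0 * sum_c f_c exp(-b n' D_c n)`.
#'
#' @param model a `phantom_model`.
#' @param gtab a [gradient_table()].
#' @return numeric vector of M signals.
#' @export
simulate_voxel <- function(model, gtab) {
  stopifnot(inherits(model, "phantom_model"))
  if (model$type == "explicit")
    return(dki_signal(model$s0, model$D, model$W, gtab))
  b <- gtab$bvals
  s <- numeric(length(b))
  for (c in seq_along(model$fractions))
    s <- s + model$fractions[c] *
      exp(-b * dki_apparent_diffusivity(model$Ds[[c]], gtab$bvecs))
  model$s0 * s
}

#' Effective tensor metrics of a phantom model along a direction
#'
#' For a mixture of Gaussian compartments with directional diffusivities
#' `d_c(n) = n' D_c n`, the effective diffusivity is the fraction-weighted
#' mean and the apparent excess kurtosis follows from the second-order
#' cumulant expansion of the compound signal:
#' `K_app(n) = 3 * Var_f(d_c(n)) / E_f(d_c(n))^2`.
#' For explicit models the assigned tensors are returned.
#'
#' @param model a `phantom_model`.
#' @param n unit direction (length 3).
#' @return list with `d` (effective diffusivity along `n`) and `k_app`
#'   (apparent kurtosis along `n`).
#' @export
model_direction_metrics <- function(model, n) {
  n <- as.numeric(n); n <- n / sqrt(sum(n^2))
  nv <- matrix(n, 1L, 3L)
  if (model$type == "explicit") {
    d <- dki_apparent_diffusivity(model$D, nv)
    md <- mean(model$D[1:3])
    k <- (md^2 / d^2) * dki_apparent_wtensor(model$W, nv)
    return(list(d = d, k_app = k))
  }
  dc <- vapply(model$Ds, function(D) dki_apparent_diffusivity(D, nv), numeric(1))
  f <- model$fractions
  m <- sum(f * dc)
  v <- sum(f * (dc - m)^2)
  list(d = m, k_app = 3 * v / m^2)
}

# effective axis diagonals of a model: D diag, W diag (tensor convention) and
# apparent-kurtosis diag
model_axis_truth <- function(model) {
  axes <- diag(3)
  d <- numeric(3); k <- numeric(3)
  for (i in 1:3) {
    mm <- model_direction_metrics(model, axes[i, ])
    d[i] <- mm$d; k[i] <- mm$k_app
  }
  md <- mean(d)
  list(d = d, k_app = k, w = k * d^2 / md^2, md = md)
}

#' Add acquisition noise to signals
#'
#' Gaussian: `S + e`; Rician: `sqrt((S + e1)^2 + e2^2)` with
#' `e ~ N(0, sigma^2)` and `sigma = s0_ref / snr` — the magnitude-image noise
#' model of MR. Uses the current R RNG state (seed upstream for
#' reproducibility).
#'
#' @param signal numeric vector or array of noiseless signals.
#' @param snr signal-to-noise ratio of the reference S0 (`Inf` = identity).
#' @param s0_ref reference non-weighted signal defining sigma.
#' @param model `"rician"` (default) or `"gaussian"`.
#' @return noisy signals, same shape.
#' @export
add_noise <- function(signal, snr, s0_ref = 100,
                      model = c("rician", "gaussian")) {
  model <- match.arg(model)
  if (!is.finite(snr)) return(signal)
  if (snr <= 0) stop("snr must be positive")
  sigma <- s0_ref / snr
  if (model == "gaussian")
    return(signal + stats::rnorm(length(signal), 0, sigma))
  e1 <- stats::rnorm(length(signal), 0, sigma)
  e2 <- stats::rnorm(length(signal), 0, sigma)
  out <- sqrt((signal + e1)^2 + e2^2)
  if (is.array(signal)) dim(out) <- dim(signal)
  out
}

# default region geometry: four disjoint boxes, two per hemisphere, each
# centered on a voxel so a 5 mm sphere sits wholly inside on a 2 mm grid
default_region_boxes <- function(grid_shape, box_width) {
  w <- box_width
  if (grid_shape[1L] < 2 * w + 3 || grid_shape[2L] < 2 * w + 3 ||
      grid_shape[3L] < w + 2)
    stop("grid too small for the region layout")
  z0 <- floor((grid_shape[3L] - w) / 2) + 1L
  xl <- c(2L, 1L + w); xr <- c(grid_shape[1L] - w, grid_shape[1L] - 1L)
  yp <- c(2L, 1L + w); ya <- c(grid_shape[2L] - w, grid_shape[2L] - 1L)
  zz <- c(z0, z0 + w - 1L)
  list(proj_left  = c(xl, yp, zz), assoc_left  = c(xl, ya, zz),
       proj_right = c(xr, yp, zz), assoc_right = c(xr, ya, zz))
}

#' Default phantom tissue parameters
#'
#' Projection-fibre regions have their principal diffusivity along z,
#' association-fibre regions along y, with a free perivascular x axis —
#' the geometry the ALPS construction assumes. Kurtosis diagonals are set so
#' the analytic DKI-ALPS (about 1.66) sits at the magnitude reported in vivo,
#' with along-fibre kurtosis below cross-fibre kurtosis.
#'
#' @param proj_D,assoc_D region diffusion diagonals (mm^2/s).
#' @param proj_W,assoc_W region kurtosis diagonals.
#' @param s0 non-weighted signal.
#' @return named list of `phantom_model`s keyed
#'   `proj_left, assoc_left, proj_right, assoc_right`.
#' @export
default_phantom_models <- function(proj_D = c(1.0, 0.6, 1.6) * 1e-3,
                                   assoc_D = c(1.1, 1.6, 0.55) * 1e-3,
                                   proj_W = c(1.30, 0.80, 0.60),
                                   assoc_W = c(1.35, 0.60, 0.80),
                                   s0 = 100) {
  proj <- explicit_model(proj_D, proj_W, s0)
  assoc <- explicit_model(assoc_D, assoc_W, s0)
  list(proj_left = proj, assoc_left = assoc,
       proj_right = proj, assoc_right = assoc)
}

#' Specify a synthetic ALPS phantom
#'
#' @param grid_shape 3 integers (default 16 x 16 x 10).
#' @param voxel_size isotropic voxel edge in mm (default 2, a typical
#'   clinical slice thickness).
#' @param models named list of `phantom_model`s for the four standard regions
#'   (see [default_phantom_models()]), optionally with extra named regions.
#' @param boxes named list of region boxes `c(x1, x2, y1, y2, z1, z2)`
#'   (1-based, inclusive); defaults to a mirrored two-per-hemisphere layout.
#' @param box_width edge length (voxels) of the default boxes.
#' @param gradients acquisition scheme (default: [default_gradients()],
#'   1 b0 + 56 directions at b = 1000 and 2000 s/mm^2).
#' @param snr S0-referenced signal-to-noise ratio (`Inf` = noiseless).
#' @param noise_model `"rician"` or `"gaussian"`.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(16L, 16L, 10L), voxel_size = 2,
                         models = default_phantom_models(),
                         boxes = NULL, box_width = 5L,
                         gradients = default_gradients(),
                         snr = Inf, noise_model = c("rician", "gaussian")) {
  noise_model <- match.arg(noise_model)
  need <- c("proj_left", "assoc_left", "proj_right", "assoc_right")
  if (!all(need %in% names(models)))
    stop("models must include: ", paste(need, collapse = ", "))
  if (is.null(boxes)) {
    boxes <- default_region_boxes(grid_shape, box_width)
    extra <- setdiff(names(models), need)
    if (length(extra))
      stop("extra regions require explicit boxes: ", paste(extra, collapse = ", "))
  }
  if (!setequal(names(boxes), names(models)))
    stop("boxes and models must have identical region names")
  # disjointness + bounds
  occ <- array(FALSE, grid_shape)
  for (nm in names(boxes)) {
    b <- boxes[[nm]]
    if (length(b) != 6L || b[1] < 1 || b[3] < 1 || b[5] < 1 ||
        b[2] > grid_shape[1] || b[4] > grid_shape[2] || b[6] > grid_shape[3])
      stop(sprintf("region '%s' box out of bounds", nm))
    sel <- occ[b[1]:b[2], b[3]:b[4], b[5]:b[6]]
    if (any(sel)) stop(sprintf("region '%s' overlaps another region", nm))
    occ[b[1]:b[2], b[3]:b[4], b[5]:b[6]] <- TRUE
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 models = models, boxes = boxes, gradients = gradients,
                 snr = snr, noise_model = noise_model),
            class = "phantom_spec")
}

# sphere ROI set centered on the four standard region boxes
phantom_roiset <- function(spec, diameter = 5) {
  ctr <- function(nm) {
    b <- spec$boxes[[nm]]
    v0 <- c(mean(b[1:2]), mean(b[3:4]), mean(b[5:6])) - 1  # 0-based voxel
    v0 * spec$voxel_size
  }
  alps_roiset(list(proj_left = ctr("proj_left"), assoc_left = ctr("assoc_left"),
                   proj_right = ctr("proj_right"), assoc_right = ctr("assoc_right")),
              diameter = diameter)
}

# analytic ground truth: region axis diagonals + indices by substitution
phantom_truth <- function(spec) {
  tr <- lapply(spec$models, model_axis_truth)
  side_index <- function(side, field) {
    p <- tr[[paste0("proj_", side)]][[field]]
    a <- tr[[paste0("assoc_", side)]][[field]]
    alps_ratio(p[1], a[1], p[2], a[3])
  }
  idx <- function(field) {
    l <- side_index("left", field); r <- side_index("right", field)
    c(left = l, right = r, global = (l + r) / 2)
  }
  list(regions = tr,
       dti = idx("d"),
       dki_tensor = idx("w"),
       dki_apparent = idx("k_app"))
}

#' Build a synthetic multi-shell DWI phantom with known ground truth
#'
#' Fills each region box with its model's noiseless signal, adds optional
#' noise, and attaches the analytic ground truth (region axis diagonals and
#' ALPS indices by direct substitution into the index equations, under both
#' kurtosis conventions) plus a matching four-sphere ROI set. Background
#' voxels are zero and excluded by the mask.
#'
#' @param spec a [phantom_spec()].
#' @param seed optional integer seed for the noise draw.
#' @return list of class `alps_phantom` with `dwi` ([dwi_volume()]), `truth`
#'   and `roiset`.
#' @export
build_phantom <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  gs <- spec$grid_shape
  M <- length(spec$gradients$bvals)
  data <- array(0, c(gs, M))
  mask <- array(FALSE, gs)
  for (nm in names(spec$boxes)) {
    b <- spec$boxes[[nm]]
    sig <- simulate_voxel(spec$models[[nm]], spec$gradients)
    nx <- b[2] - b[1] + 1L; ny <- b[4] - b[3] + 1L; nz <- b[6] - b[5] + 1L
    data[b[1]:b[2], b[3]:b[4], b[5]:b[6], ] <-
      rep(sig, each = nx * ny * nz)
    mask[b[1]:b[2], b[3]:b[4], b[5]:b[6]] <- TRUE
  }
  if (is.finite(spec$snr)) {
    s0_ref <- max(vapply(spec$models, `[[`, numeric(1), "s0"))
    mask4 <- array(mask, c(gs, M))
    data[mask4] <- add_noise(data[mask4], spec$snr, s0_ref, spec$noise_model)
  }
  affine <- diag(c(rep(spec$voxel_size, 3), 1))
  structure(list(dwi = dwi_volume(data, affine, spec$gradients, mask),
                 truth = phantom_truth(spec),
                 roiset = phantom_roiset(spec),
                 spec = spec),
            class = "alps_phantom")
}

#' Run the full ALPS pipeline on a DWI volume
#'
#' fit tensors -> axis metrics -> ROI means -> indices.
#'
#' @param dwi a [dwi_volume()].
#' @param roiset an [alps_roiset()].
#' @param method fit method, `"wls"` or `"ols"`.
#' @param convention kurtosis-axis convention, `"tensor"` or `"apparent"`.
#' @param global whole-brain rule, `"mean"` or `"pooled"`.
#' @return an `alps_result`.
#' @export
alps_pipeline <- function(dwi, roiset, method = "wls",
                          convention = "tensor", global = "mean") {
  fit <- dki_fit(dwi, method = method)
  maps <- axis_metrics(fit, convention = convention)
  compute_alps(maps, roiset, global = global)
}
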