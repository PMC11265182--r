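#' Spherical ROI mask on a voxel grid
#'
#' A voxel belongs to the sphere iff the world-coordinate distance from its
#' center to the sphere center is at most `diameter / 2` (voxel-center
#' membership; no partial-volume weighting).
#'
#' @param center world-coordinate sphere center (mm), length 3.
#' @param diameter sphere diameter (mm).
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @param dim spatial grid shape, length 3.
#' @param name ROI name used in error messages.
#' @return logical 3D array.
#' @export
sphere_mask <- function(center, diameter, affine, dim, name = "roi") {
  stopifnot(length(center) == 3L, diameter > 0, length(dim) == 3L)
  g <- as.matrix(expand.grid(x = seq_len(dim[1L]) - 1L,
                             y = seq_len(dim[2L]) - 1L,
                             z = seq_len(dim[3L]) - 1L))
  world <- t(affine %*% t(cbind(g, 1)))[, 1:3, drop = FALSE]
  d2 <- (world[, 1L] - center[1L])^2 + (world[, 2L] - center[2L])^2 +
    (world[, 3L] - center[3L])^2
  m <- array(d2 <= (diameter / 2)^2, dim = dim)
  if (!any(m))
    stop(sprintf("ROI '%s': sphere at (%s) mm contains no voxel centers",
                 name, paste(format(center, digits = 4), collapse = ", ")))
  m
}

#' The four-sphere ALPS ROI set
#'
#' The ALPS construction uses, per hemisphere, one ROI in projection-fibre
#' white matter (main fibres along z) and one in association-fibre white
#' matter (main fibres along y), conventionally 5 mm diameter spheres at the
#' level of the lateral-ventricle body. The study data this models give no
#' coordinates ("manually outlined"); centers are therefore always explicit
#' here — supply your own (template-space mm), or use the phantom's ROI set.
#'
#' @param centers named list with entries `proj_left`, `assoc_left`,
#'   `proj_right`, `assoc_right`, each a length-3 world coordinate (mm).
#' @param diameter sphere diameter in mm (default 5).
#' @return An object of class `alps_roiset`.
#' @export
alps_roiset <- function(centers, diameter = 5) {
  keys <- c("proj_left", "assoc_left", "proj_right", "assoc_right")
  if (!setequal(names(centers), keys))
    stop("centers must have exactly the names: ", paste(keys, collapse = ", "))
  if (diameter <= 0) stop("diameter must be positive")
  centers <- lapply(centers[keys], function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || any(!is.finite(p))) stop("each center is a finite length-3 mm coordinate")
    p
  })
  structure(list(centers = centers, diameter = diameter, source = "config"),
            class = "alps_roiset")
}

#' Read an ALPS ROI configuration from JSON
#'
#' Expected layout: `{"diameter": 5, "centers": {"proj_left": [x,y,z], ...}}`
#' with coordinates in template-space mm.
#'
#' @param path JSON file path.
#' @return [alps_roiset()].
#' @export
read_roi_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  alps_roiset(cfg$centers, diameter = cfg$diameter %||% 5)
}

#' @export
print.alps_roiset <- function(x, ...) {
  cat(sprintf("ALPS ROI set: four %g mm spheres\n", x$diameter))
  for (nm in names(x$centers))
    cat(sprintf("  %-12s (%s) mm\n", nm,
                paste(format(x$centers[[nm]], digits = 4), collapse = ", ")))
  invisible(x)
}

# materialize the four sphere masks on a grid; enforce intra-hemisphere
# disjointness of proj and assoc
roi_masks <- function(roiset, affine, dim) {
  masks <- lapply(names(roiset$centers), function(nm)
    sphere_mask(roiset$centers[[nm]], roiset$diameter, affine, dim, name = nm))
  names(masks) <- names(roiset$centers)
  for (side in c("left", "right")) {
    if (any(masks[[paste0("proj_", side)]] & masks[[paste0("assoc_", side)]]))
      stop(sprintf("proj and assoc ROIs overlap on the %s side", side))
  }
  masks
}

# warn if the affine's rotation part strays from axis alignment: the ALPS
# construction reads x/y/z tensor components and is meaningless off-axis
check_axis_alignment <- function(affine, tol_deg = 5) {
  R <- affine[1:3, 1:3]
  R <- R %*% diag(1 / sqrt(colSums(R^2)))
  ang <- acos(pmin(1, abs(diag(R)))) * 180 / pi
  if (any(ang > tol_deg))
    warning(sprintf(paste0("image axes deviate from world axes by up to %.1f deg; ",
                           "ALPS axis metrics assume axis-aligned (template-like) space"),
                    max(ang)))
  invisible(max(ang))
}

#' ROI-mean axis metrics for one hemisphere
#'
#' The projection-fibre ROI contributes its mean `dxx`, `dyy`, `kxxxx`,
#' `kyyyy`; the association-fibre ROI its mean `dxx`, `dzz`, `kxxxx`,
#' `kzzzz`. NaN voxels are excluded from the means; an ROI must retain at
#' least one valid voxel (and is flagged below 50% validity).
#'
#' @param maps an [axis_metrics()] object.
#' @param roiset an [alps_roiset()].
#' @param side `"left"` or `"right"`.
#' @return list of ROI means plus provenance (voxel counts, flags).
#' @export
extract_roi_means <- function(maps, roiset, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(maps, "axis_metrics"), inherits(roiset, "alps_roiset"))
  dims <- dim(maps$dxx)
  masks <- roi_masks(roiset, maps$affine, dims)
  roi_mean <- function(map, mask, roi_name) {
    vals <- map[mask]
    n_ok <- sum(is.finite(vals))
    if (n_ok == 0L)
      stop(sprintf("ROI '%s': no valid (non-NaN) voxels", roi_name))
    list(mean = mean(vals[is.finite(vals)]), n = sum(mask), n_valid = n_ok)
  }
  pm <- masks[[paste0("proj_", side)]]
  am <- masks[[paste0("assoc_", side)]]
  pn <- paste0("proj_", side); an <- paste0("assoc_", side)
  vals <- list(
    dxx_proj = roi_mean(maps$dxx, pm, pn), dyy_proj = roi_mean(maps$dyy, pm, pn),
    kxxxx_proj = roi_mean(maps$kxxxx, pm, pn), kyyyy_proj = roi_mean(maps$kyyyy, pm, pn),
    dxx_assoc = roi_mean(maps$dxx, am, an), dzz_assoc = roi_mean(maps$dzz, am, an),
    kxxxx_assoc = roi_mean(maps$kxxxx, am, an), kzzzz_assoc = roi_mean(maps$kzzzz, am, an))
  means <- lapply(vals, `[[`, "mean")
  frac_valid <- min(vapply(vals, function(v) v$n_valid / v$n, numeric(1)))
  c(means, list(side = side,
                n_voxels = c(proj = sum(pm), assoc = sum(am)),
                min_frac_valid = frac_valid,
                low_validity = frac_valid < 0.5))
}

#' The ALPS ratio
#'
#' `mean(x_proj, x_assoc) / mean(y_proj, z_assoc)`: x-axis (perivascular)
#' diffusivity or kurtosis in both fibre regions over the along-fibre
#' references (y in projection fibres, z in association fibres). The same
#' formula serves DTI-ALPS (diffusivities) and DKI-ALPS (kurtosis values).
#'
#' @param x_proj,x_assoc x-axis metric in the projection / association ROI.
#' @param y_proj y-axis metric in the projection ROI.
#' @param z_assoc z-axis metric in the association ROI.
#' @return the dimensionless index.
#' @export
alps_ratio <- function(x_proj, x_assoc, y_proj, z_assoc) {
  num <- (x_proj + x_assoc) / 2
  den <- (y_proj + z_assoc) / 2
  if (!is.finite(den) || den <= 0)
    stop("ALPS index undefined: denominator mean(y_proj, z_assoc) is not positive")
  num / den
}

#' Compute DTI-ALPS and DKI-ALPS for left, right and whole brain
#'
#' Left and right indices come from the hemisphere's own ROI pair; the
#' whole-brain ("global") index is by default the arithmetic mean of the two
#' sides, with `global = "pooled"` (average the four ROI means before the
#' ratio) as an alternative.
#'
#' @param maps an [axis_metrics()] object.
#' @param roiset an [alps_roiset()].
#' @param global `"mean"` (default) or `"pooled"`.
#' @return An object of class `alps_result` with fields `dti_left`,
#'   `dti_right`, `dti_global`, `dki_left`, `dki_right`, `dki_global`, and
#'   `provenance` (ROI voxel counts, kurtosis convention, global rule).
#' @examples
#' # maps where every metric is constant give index 1 everywhere
#' @export
compute_alps <- function(maps, roiset, global = c("mean", "pooled")) {
  global <- match.arg(global)
  check_axis_alignment(maps$affine)
  left <- extract_roi_means(maps, roiset, "left")
  right <- extract_roi_means(maps, roiset, "right")
  dti <- function(m) alps_ratio(m$dxx_proj, m$dxx_assoc, m$dyy_proj, m$dzz_assoc)
  dki <- function(m) alps_ratio(m$kxxxx_proj, m$kxxxx_assoc, m$kyyyy_proj, m$kzzzz_assoc)
  res <- list(dti_left = dti(left), dti_right = dti(right),
              dki_left = dki(left), dki_right = dki(right))
  if (global == "mean") {
    res$dti_global <- (res$dti_left + res$dti_right) / 2
    res$dki_global <- (res$dki_left + res$dki_right) / 2
  } else {
    pool <- function(f) (f(left) + f(right)) / 2
    res$dti_global <- alps_ratio(pool(function(m) m$dxx_proj),
                                 pool(function(m) m$dxx_assoc),
                                 pool(function(m) m$dyy_proj),
                                 pool(function(m) m$dzz_assoc))
    res$dki_global <- alps_ratio(pool(function(m) m$kxxxx_proj),
                                 pool(function(m) m$kxxxx_assoc),
                                 pool(function(m) m$kyyyy_proj),
                                 pool(function(m) m$kzzzz_assoc))
  }
  for (nm in names(res))
    if (!is.finite(res[[nm]]) || res[[nm]] <= 0)
      stop(sprintf("index %s is not a positive finite number", nm))
  structure(c(res[c("dti_left", "dti_right", "dti_global",
                    "dki_left", "dki_right", "dki_global")],
              list(provenance = list(
                convention = maps$convention, global = global,
                n_voxels_left = left$n_voxels, n_voxels_right = right$n_voxels,
                low_validity = left$low_validity || right$low_validity))),
            class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat("ALPS indices (kurtosis convention:", x$provenance$convention, ")\n")
  m <- rbind(`DTI-ALPS` = c(x$dti_left, x$dti_right, x$dti_global),
             `DKI-ALPS` = c(x$dki_left, x$dki_right, x$dki_global))
  colnames(m) <- c("left", "right", "global")
  print(round(m, 4))
  if (isTRUE(x$provenance$low_validity))
    cat("warning: an ROI retained < 50% valid voxels\n")
  invisible(x)
}

#' One-row data frame of the six indices (for cohort TSVs)
#'
#' @param x an `alps_result`.
#' @param ... unused.
#' @return data.frame with columns `dti_left, dti_right, dti_global,
#'   dki_left, dki_right, dki_global`.
#' @export
as.data.frame.alps_result <- function(x, ...) {
  data.frame(dti_left = x$dti_left, dti_right = x$dti_right,
             dti_global = x$dti_global, dki_left = x$dki_left,
             dki_right = x$dki_right, dki_global = x$dki_global)
}
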