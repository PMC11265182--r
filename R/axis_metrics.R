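#' Axis-aligned diffusivity and kurtosis maps
#'
#' Extracts from a fitted [dki_fit()] the six maps the ALPS indices are built
#' from: the diffusion-tensor diagonal `dxx, dyy, dzz` (mm^2/s) and an
#' axis kurtosis value per coordinate axis. Two conventions for the latter
#' are supported:
#'
#' * `"tensor"` (default): the raw fitted kurtosis-tensor diagonal
#'   `W_xxxx, W_yyyy, W_zzzz` — what per-component kurtosis-tensor output
#'   files of common kurtosis estimators contain;
#' * `"apparent"`: the apparent (directional) kurtosis along each axis,
#'   `K_app(e_i) = (md^2 / D_ii^2) * W_iiii`.
#'
#' Flagged voxels and voxels outside the fitted mask are NaN.
#'
#' @param fit a [dki_fit()] on a volume.
#' @param convention `"tensor"` or `"apparent"`.
#' @return An object of class `axis_metrics`: list of 3D arrays `dxx, dyy,
#'   dzz, kxxxx, kyyyy, kzzzz`, plus `convention` and `affine`.
#' @export
axis_metrics <- function(fit, convention = c("tensor", "apparent")) {
  stopifnot(inherits(fit, "dki_fit"))
  convention <- match.arg(convention)
  dims <- fit$dim
  lin <- fit$voxels[, 1L] + (fit$voxels[, 2L] - 1L) * dims[1L] +
    (fit$voxels[, 3L] - 1L) * dims[1L] * dims[2L]

  fill <- function(values) {
    m <- array(NaN, dims)
    v <- values
    v[!fit$valid] <- NaN
    m[lin] <- v
    m
  }
  kvals <- function(i) {
    w <- fit$W[, i]
    if (convention == "apparent") (fit$md^2 / fit$D[, i]^2) * w else w
  }
  structure(list(dxx = fill(fit$D[, 1L]), dyy = fill(fit$D[, 2L]),
                 dzz = fill(fit$D[, 3L]),
                 kxxxx = fill(kvals(1L)), kyyyy = fill(kvals(2L)),
                 kzzzz = fill(kvals(3L)),
                 convention = convention, affine = fit$affine),
            class = "axis_metrics")
}

#' Build axis-metric maps directly from arrays
#'
#' Convenience constructor for tests and for reading maps produced by other
#' software.
#'
#' @param dxx,dyy,dzz,kxxxx,kyyyy,kzzzz 3D arrays of equal shape.
#' @param affine 4x4 voxel-to-world matrix.
#' @param convention kurtosis-axis convention label.
#' @return `axis_metrics` object.
#' @export
axis_metric_maps <- function(dxx, dyy, dzz, kxxxx, kyyyy, kzzzz, affine,
                             convention = "tensor") {
  maps <- list(dxx = dxx, dyy = dyy, dzz = dzz,
               kxxxx = kxxxx, kyyyy = kyyyy, kzzzz = kzzzz)
  shp <- dim(maps[[1L]])
  for (nm in names(maps)) {
    if (!identical(dim(maps[[nm]]), shp))
      stop(sprintf("map %s has a different shape", nm))
  }
  structure(c(maps, list(convention = convention, affine = as.matrix(affine))),
            class = "axis_metrics")
}

#' Write the six axis-metric maps as NIfTI with a JSON sidecar
#'
#' @param maps an [axis_metrics()] object.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @param extra named list merged into the sidecar (e.g. QC counts, method).
#' @return invisibly, the sidecar path.
#' @export
write_axis_metrics <- function(maps, dir, prefix = "", extra = list()) {
  stopifnot(inherits(maps, "axis_metrics"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("dxx", "dyy", "dzz", "kxxxx", "kyyyy", "kzzzz"))
    write_map(maps[[nm]], maps$affine,
              file.path(dir, paste0(prefix, nm, ".nii.gz")))
  sidecar <- file.path(dir, paste0(prefix, "maps.json"))
  jsonlite::write_json(c(list(convention = maps$convention), extra),
                       sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}

#' Read six axis-metric maps written by [write_axis_metrics()]
#'
#' @param dir directory containing the maps.
#' @param prefix file-name prefix used when writing.
#' @return `axis_metrics` object.
#' @export
read_axis_metrics <- function(dir, prefix = "") {
  nms <- c("dxx", "dyy", "dzz", "kxxxx", "kyyyy", "kzzzz")
  maps <- lapply(nms, function(nm)
    read_map(file.path(dir, paste0(prefix, nm, ".nii.gz"))))
  convention <- "tensor"
  sidecar <- file.path(dir, paste0(prefix, "maps.json"))
  if (file.exists(sidecar))
    convention <- jsonlite::read_json(sidecar)$convention %||% "tensor"
  do.call(axis_metric_maps,
          c(lapply(maps, `[[`, "data"),
            list(affine = maps[[1L]]$affine, convention = convention)))
}

#' Plot one axial slice of each axis-metric map
#'
#' @param x an [axis_metrics()] object.
#' @param slice axial (z) slice index; defaults to the middle slice.
#' @param ... passed to [graphics::image()].
#' @export
plot.axis_metrics <- function(x, slice = NULL, ...) {
  if (is.null(slice)) slice <- ceiling(dim(x$dxx)[3L] / 2)
  op <- graphics::par(mfrow = c(2, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (nm in c("dxx", "dyy", "dzz", "kxxxx", "kyyyy", "kzzzz")) {
    m <- x[[nm]][, , slice]
    m[!is.finite(m)] <- NA
    graphics::image(m, main = nm, axes = FALSE, useRaster = TRUE, ...)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
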