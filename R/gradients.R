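#' Multi-shell gradient tables
#'
#' A gradient table bundles the diffusion weightings (b-values, s/mm^2) and
#' unit encoding directions of a DWI acquisition, with a per-measurement
#' shell label. Shells are the distinct non-zero b-values after rounding to
#' the nearest 50 s/mm^2 (robust to per-volume b-value jitter); measurements
#' at or below `b0_threshold` are labelled shell 0.
#'
#' @param bvals numeric vector of b-values (s/mm^2).
#' @param bvecs numeric matrix of encoding directions, either 3 x M or M x 3
#'   (auto-detected by shape; for a 3 x 3 matrix rows are taken as the three
#'   coordinate rows, the FSL convention). Directions for b0 entries may be
#'   zero; all others must be unit vectors.
#' @param b0_threshold b-values at or below this are treated as b0
#'   (default 50 s/mm^2, covering typical vendor jitter).
#' @param on_nonunit what to do with a direction whose norm deviates from 1
#'   by more than `tol`: `"fail"` (default), or `"renormalize"` which warns
#'   and rescales.
#' @param tol unit-norm tolerance (default 1e-3).
#' @return An object of class `gradient_table`: a list with `bvals`, `bvecs`
#'   (M x 3), `shell_labels` (0 = b0), `shells` (sorted distinct nonzero
#'   rounded b-values) and `b0_threshold`.
#' @examples
#' gt <- gradient_table(c(0, 1000, 1000), rbind(c(0,0,0), c(1,0,0), c(0,1,0)))
#' gt$shells
#' @export
gradient_table <- function(bvals, bvecs, b0_threshold = 50,
                           on_nonunit = c("fail", "renormalize"),
                           tol = 1e-3) {
  on_nonunit <- match.arg(on_nonunit)
  bvals <- as.numeric(bvals)
  if (any(!is.finite(bvals))) stop("non-numeric or non-finite b-value")
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L)
    stop("bvecs must be a 3 x M or M x 3 matrix of direction cosines")
  if (nrow(bvecs) != length(bvals))
    stop(sprintf("length mismatch: %d b-values but %d directions",
                 length(bvals), nrow(bvecs)))
  if (length(bvals) < 1L) stop("empty gradient table")
  if (any(!is.finite(bvecs))) stop("non-numeric or non-finite direction")

  is_b0 <- bvals <= b0_threshold
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- !is_b0 & abs(nrm - 1) > tol
  if (any(bad)) {
    if (on_nonunit == "fail")
      stop(sprintf("non-unit direction at measurement %d (norm %.4f)",
                   which(bad)[1L], nrm[which(bad)[1L]]))
    warning(sprintf("renormalizing %d non-unit direction(s)", sum(bad)))
    bvecs[bad, ] <- bvecs[bad, , drop = FALSE] / nrm[bad]
  }

  rounded <- round(bvals / 50) * 50
  rounded[is_b0] <- 0
  shells <- sort(unique(rounded[!is_b0]))
  shell_labels <- integer(length(bvals))
  shell_labels[!is_b0] <- match(rounded[!is_b0], shells)

  structure(list(bvals = bvals, bvecs = bvecs, shell_labels = shell_labels,
                 shells = shells, b0_threshold = b0_threshold),
            class = "gradient_table")
}

#' Read FSL-style bval/bvec files
#'
#' `bval` holds one whitespace-separated row of b-values; `bvec` holds three
#' rows (x, y, z) of equal length. The transposed M x 3 layout is also
#' accepted and detected by shape.
#'
#' @param bval_path,bvec_path paths to the text files.
#' @inheritParams gradient_table
#' @return A [gradient_table()].
#' @export
read_gradients <- function(bval_path, bvec_path, b0_threshold = 50,
                           on_nonunit = c("fail", "renormalize")) {
  parse_numeric_table <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) {
      toks <- strsplit(trimws(l), "[[:space:]]+")[[1L]]
      vals <- suppressWarnings(as.numeric(toks))
      if (any(is.na(vals)))
        stop(sprintf("non-numeric token '%s' in %s", toks[which(is.na(vals))[1L]], path))
      vals
    })
    if (length(unique(lengths(rows))) != 1L)
      stop(sprintf("ragged rows in %s", path))
    do.call(rbind, rows)
  }
  bv <- parse_numeric_table(bval_path)
  if (nrow(bv) != 1L) stop("bval file must hold a single row of b-values")
  vec <- parse_numeric_table(bvec_path)
  gradient_table(drop(bv), vec, b0_threshold = b0_threshold,
                 on_nonunit = match.arg(on_nonunit))
}

#' Write a gradient table as FSL bval/bvec files
#'
#' @param gtab a [gradient_table()].
#' @param bval_path,bvec_path output paths.
#' @export
write_gradients <- function(gtab, bval_path, bvec_path) {
  stopifnot(inherits(gtab, "gradient_table"))
  writeLines(paste(format(gtab$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval_path)
  writeLines(apply(t(gtab$bvecs), 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' Can a gradient table support the 22-parameter kurtosis model?
#'
#' The log-linearized diffusion-kurtosis model has 22 unknowns (log S0, 6
#' diffusion-tensor components, 15 kurtosis-tensor components); identifying
#' them requires at least two distinct non-zero shells and at least 22
#' measurements in total.
#'
#' @param gtab a [gradient_table()].
#' @return logical.
#' @export
is_dki_capable <- function(gtab) {
  stopifnot(inherits(gtab, "gradient_table"))
  length(gtab$shells) >= 2L && length(gtab$bvals) >= 22L
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("Gradient table: %d measurements (%d b0), shells: %s\n",
              length(x$bvals), sum(x$shell_labels == 0L),
              paste(x$shells, collapse = ", ")))
  cat(sprintf("DKI-capable (>= 2 shells, >= 22 measurements): %s\n",
              is_dki_capable(x)))
  invisible(x)
}

#' Deterministic well-spread unit directions (spherical Fibonacci layout)
#'
#' Generates `n` antipodally distinct unit vectors on the upper hemisphere
#' from the Fibonacci spiral lattice. Used for the default acquisition
#' scheme; deterministic, no RNG.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  # map onto the upper hemisphere: z in (0, 1), golden-angle azimuth
  z <- i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' The default two-shell acquisition scheme
#'
#' One b0 plus 56 directions at b = 1000 and the same 56 at b = 2000 s/mm^2
#' (113 measurements), mirroring a common clinical multi-shell kurtosis
#' protocol. Directions come from the packaged fixture
#' `extdata/directions56.txt` when installed, else are regenerated by
#' [fibonacci_directions()] (the two are identical).
#'
#' @return A [gradient_table()].
#' @export
default_gradients <- function() {
  path <- system.file("extdata", "directions56.txt", package = "dkialps")
  dirs <- if (nzchar(path)) {
    as.matrix(utils::read.table(path))
  } else {
    fibonacci_directions(56)
  }
  dimnames(dirs) <- NULL
  gradient_table(c(0, rep(1000, 56), rep(2000, 56)),
                 rbind(c(0, 0, 0), dirs, dirs))
}
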