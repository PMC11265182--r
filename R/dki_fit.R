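#' Fit the diffusion and kurtosis tensors per voxel
#'
#' Estimates, for every voxel of a multi-shell DWI series (or for a single
#' signal vector), the non-weighted signal S0, the diffusion tensor D (6
#' components) and the fourth-order kurtosis tensor W (15 components) from
#' the log-linearized kurtosis signal representation. The linear unknowns are
#' `ln S0`, D, and `U = md^2 * W`; W is recovered by dividing the fitted U by
#' the squared mean diffusivity of the fitted D.
#'
#' `method = "ols"` solves the log-linear system by ordinary least squares;
#' `method = "wls"` (default) re-solves with weights equal to the squared
#' OLS-predicted signals, countering the heteroscedasticity of log-signals.
#'
#' Voxels with any non-positive signal are flagged invalid rather than
#' floored (flooring biases kurtosis). Voxels with non-positive mean
#' diffusivity, or `md^2 < 1e-12` (kurtosis undefined), are flagged. Voxels
#' whose apparent kurtosis along a coordinate axis falls outside the
#' physical-plausibility window [-3, 10] are flagged but kept. No positivity
#' constraints are imposed in the fit; out-of-range voxels are reported, not
#' projected.
#'
#' @param x a [dwi_volume()], or a numeric vector of M signals for one voxel.
#' @param gtab a DKI-capable [gradient_table()]; taken from `x` when `x` is a
#'   `dwi_volume`.
#' @param method `"wls"` (default) or `"ols"`.
#' @param mask optional logical 3D array overriding the volume's mask;
#'   voxels outside the mask are not fit (NaN in derived maps).
#' @return An object of class `dki_fit` with components `s0`, `D` (V x 6),
#'   `W` (V x 15), `md`, `flags` (data frame of QC logicals), `valid`,
#'   `voxels` (V x 3 integer voxel indices), `dim`, `affine`, `gtab`,
#'   `method`, `signal` (V x M observed signals).
#' @seealso [axis_metrics()], [dki_signal()], [predict.dki_fit()]
#' @examples
#' gt <- default_gradients()
#' y <- dki_signal(100, c(1.2, 0.8, 1.7) * 1e-3, c(0.9, 1.1, 0.6), gt)
#' fit <- dki_fit(y, gt)
#' coef(fit)[c("dxx", "dyy", "dzz")]
#' @export
dki_fit <- function(x, gtab = NULL, method = c("wls", "ols"), mask = NULL) {
  method <- match.arg(method)
  if (inherits(x, "dwi_volume")) {
    gtab <- x$gradients
    dims <- dim(x$data)[1:3]
    if (is.null(mask)) mask <- x$mask
    if (is.null(mask)) mask <- array(TRUE, dims)
    if (!identical(dim(mask), dims)) stop("mask shape mismatch")
    if (!any(mask)) stop("empty mask: no voxels to fit")
    vox <- which(mask, arr.ind = TRUE)
    flat <- matrix(x$data, prod(dims), dim(x$data)[4L])
    sig <- flat[as.vector(mask), , drop = FALSE]    # V x M
    affine <- x$affine
  } else {
    x <- as.numeric(x)
    if (is.null(gtab)) stop("gtab is required when fitting a raw signal vector")
    if (length(x) != length(gtab$bvals))
      stop("signal length does not match gradient table")
    sig <- matrix(x, nrow = 1L)
    vox <- matrix(1L, 1L, 3L)
    dims <- c(1L, 1L, 1L)
    affine <- diag(4)
  }
  stopifnot(inherits(gtab, "gradient_table"))
  A <- dki_design_matrix(gtab)
  V <- nrow(sig)

  theta <- matrix(NA_real_, V, 22L)
  ok <- rowSums(!is.finite(sig) | sig <= 0) == 0L
  if (any(ok)) {
    idx <- which(ok)
    logs <- log(sig[idx, , drop = FALSE])           # Vok x M
    qrA <- qr(A)
    th <- t(qr.coef(qrA, t(logs)))                  # Vok x 22  (OLS)
    if (method == "wls") {
      for (j in seq_along(idx)) {
        w <- exp(2 * drop(A %*% th[j, ]))           # squared predicted signals
        AtWA <- crossprod(A, w * A)
        sol <- try(solve(AtWA, crossprod(A, w * logs[j, ])), silent = TRUE)
        if (inherits(sol, "try-error")) { ok[idx[j]] <- FALSE; next }
        th[j, ] <- drop(sol)
      }
    }
    theta[idx[ok[idx]], ] <- th[ok[idx], , drop = FALSE]
  }

  s0 <- exp(theta[, 1L])
  D <- theta[, 2:7, drop = FALSE]
  U <- theta[, 8:22, drop = FALSE]
  md <- rowMeans(D[, 1:3, drop = FALSE])
  md2 <- md^2
  kurt_defined <- ok & is.finite(md2) & md2 >= 1e-12
  W <- U / md2
  W[!kurt_defined, ] <- NA_real_

  # apparent kurtosis along the coordinate axes, for QC
  kqc <- matrix(NA_real_, V, 3L)
  for (i in 1:3) kqc[, i] <- (md2 / D[, i]^2) * W[, i]
  flag_range <- kurt_defined &
    (apply(kqc, 1L, function(r) any(is.finite(r) & (r < -3 | r > 10))))

  flags <- data.frame(
    invalid_signal = !ok,
    nonpos_md = ok & !(is.finite(md) & md > 0),
    kurtosis_undefined = ok & !kurt_defined,
    kurtosis_out_of_range = flag_range)
  valid <- ok & flags$nonpos_md == FALSE

  colnames(D) <- .d_names
  colnames(W) <- .w_names
  structure(list(s0 = s0, D = D, W = W, md = md, flags = flags,
                 valid = valid, voxels = vox, dim = dims, affine = affine,
                 gtab = gtab, method = method, signal = sig),
            class = "dki_fit")
}

#' @export
print.dki_fit <- function(x, ...) {
  cat(sprintf("Diffusion-kurtosis fit (%s): %d voxel(s), %d measurements\n",
              toupper(x$method), nrow(x$D), length(x$gtab$bvals)))
  cat(sprintf("valid voxels: %d; flagged: %d invalid-signal, %d nonpositive-MD, %d kurtosis out of [-3, 10]\n",
              sum(x$valid), sum(x$flags$invalid_signal),
              sum(x$flags$nonpos_md), sum(x$flags$kurtosis_out_of_range)))
  if (nrow(x$D) == 1L && x$valid[1L]) {
    cat("\nCoefficients:\n")
    print(signif(coef(x), 6))
  }
  invisible(x)
}

#' @export
coef.dki_fit <- function(object, ...) {
  out <- cbind(s0 = object$s0, object$D, object$W, md = object$md)
  if (nrow(out) == 1L) drop(out) else out
}

#' @export
fitted.dki_fit <- function(object, ...) {
  pr <- predict(object)
  if (nrow(object$signal) == 1L) drop(pr) else pr
}

#' @export
residuals.dki_fit <- function(object, ...) {
  r <- object$signal - predict(object)
  if (nrow(r) == 1L) drop(r) else r
}

#' Predict diffusion-kurtosis signals from a fit
#'
#' @param object a [dki_fit()] result.
#' @param gtab optional [gradient_table()] to predict for (defaults to the
#'   acquisition the model was fit on).
#' @param ... unused.
#' @return V x M matrix of predicted signals (NaN rows for invalid voxels).
#' @export
predict.dki_fit <- function(object, gtab = NULL, ...) {
  if (is.null(gtab)) gtab <- object$gtab
  b <- gtab$bvals
  dapp <- .d_products(gtab$bvecs)                 # M x 6
  wapp <- .w_products(gtab$bvecs)                 # M x 15
  V <- nrow(object$D)
  out <- matrix(NA_real_, V, length(b))
  for (v in which(object$valid)) {
    W <- object$W[v, ]
    wterm <- if (all(is.finite(W))) (b^2 / 6) * object$md[v]^2 *
      drop(wapp %*% W) else 0
    out[v, ] <- object$s0[v] *
      exp(-b * drop(dapp %*% object$D[v, ]) + wterm)
  }
  out
}

#' @export
summary.dki_fit <- function(object, ...) {
  v <- object$valid
  s <- list(
    n_voxels = length(v), n_valid = sum(v),
    qc = colSums(object$flags),
    md_range = if (any(v)) range(object$md[v]) else c(NA_real_, NA_real_),
    method = object$method)
  class(s) <- "summary.dki_fit"
  s
}

#' @export
print.summary.dki_fit <- function(x, ...) {
  cat(sprintf("DKI fit (%s): %d / %d voxels valid\n", toupper(x$method),
              x$n_valid, x$n_voxels))
  cat("QC flags:\n"); print(x$qc)
  cat(sprintf("MD range (mm^2/s): %.3e .. %.3e\n", x$md_range[1], x$md_range[2]))
  invisible(x)
}
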