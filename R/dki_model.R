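# Component ordering and forward model for the log-linear diffusion-kurtosis
# signal representation
#
#   ln S(b, n) = ln S0 - b * sum_ij n_i n_j D_ij
#                      + (b^2/6) * sum_ijkl n_i n_j n_k n_l U_ijkl
#
# with U = md^2 * W (W the dimensionless kurtosis tensor). All 22 unknowns
# enter linearly; symmetry multiplicities are folded into the design matrix
# so that each unique component appears once.

# diffusion-tensor component order (6)
.d_names <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")

# kurtosis-tensor component order (15) with index powers and multiplicities
.w_names <- c("wxxxx", "wyyyy", "wzzzz",
              "wxxxy", "wxxxz", "wxyyy", "wyyyz", "wxzzz", "wyzzz",
              "wxxyy", "wxxzz", "wyyzz",
              "wxxyz", "wxyyz", "wxyzz")
.w_powers <- rbind(
  c(4, 0, 0), c(0, 4, 0), c(0, 0, 4),
  c(3, 1, 0), c(3, 0, 1), c(1, 3, 0), c(0, 3, 1), c(1, 0, 3), c(0, 1, 3),
  c(2, 2, 0), c(2, 0, 2), c(0, 2, 2),
  c(2, 1, 1), c(1, 2, 1), c(1, 1, 2))
.w_mult <- c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)

# M x 6 matrix of quadratic direction products (with cross-term multiplicity 2)
.d_products <- function(bvecs) {
  nx <- bvecs[, 1L]; ny <- bvecs[, 2L]; nz <- bvecs[, 3L]
  cbind(nx^2, ny^2, nz^2, 2 * nx * ny, 2 * nx * nz, 2 * ny * nz)
}

# M x 15 matrix of quartic direction products including symmetry multiplicity
.w_products <- function(bvecs) {
  nx <- bvecs[, 1L]; ny <- bvecs[, 2L]; nz <- bvecs[, 3L]
  out <- matrix(0, nrow(bvecs), 15L)
  for (k in seq_len(15L)) {
    p <- .w_powers[k, ]
    out[, k] <- .w_mult[k] * nx^p[1L] * ny^p[2L] * nz^p[3L]
  }
  out
}

#' Design matrix of the log-linear diffusion-kurtosis model
#'
#' Row m encodes the log-signal for measurement m as a linear function of the
#' 22 unknowns, in the fixed column order `lnS0`, the six diffusion-tensor
#' components (`dxx, dyy, dzz, dxy, dxz, dyz`; off-diagonals carry their
#' symmetry multiplicity 2), then the fifteen scaled kurtosis components
#' `U = md^2 * W` (order `wxxxx, wyyyy, wzzzz, wxxxy, wxxxz, wxyyy, wyyyz,
#' wxzzz, wyzzz, wxxyy, wxxzz, wyyzz, wxxyz, wxyyz, wxyzz`; multiplicities
#' 1/4/6/12 per symmetry class).
#'
#' @param gtab a DKI-capable [gradient_table()].
#' @return M x 22 numeric matrix with column names.
#' @export
dki_design_matrix <- function(gtab) {
  stopifnot(inherits(gtab, "gradient_table"))
  if (!is_dki_capable(gtab))
    stop("model underdetermined: gradient table needs >= 2 shells and >= 22 measurements")
  b <- gtab$bvals
  A <- cbind(1, -b * .d_products(gtab$bvecs), (b^2 / 6) * .w_products(gtab$bvecs))
  colnames(A) <- c("lnS0", .d_names, paste0("u_", sub("^w", "", .w_names)))
  if (qr(A)$rank < 22L)
    stop("model underdetermined: design matrix rank below 22 (directions too sparse)")
  A
}

# apparent diffusivity along rows of bvecs: D_app(n) = n' D n
dki_apparent_diffusivity <- function(D, bvecs) {
  drop(.d_products(bvecs) %*% as.numeric(D))
}

# apparent kurtosis-tensor contraction W_app(n) = sum n_i n_j n_k n_l W_ijkl
dki_apparent_wtensor <- function(W, bvecs) {
  drop(.w_products(bvecs) %*% as.numeric(W))
}

#' Forward diffusion-kurtosis signal
#'
#' Computes `S(b, n) = s0 * exp(-b * D_app(n) + (b^2/6) * md^2 * W_app(n))`
#' where `D_app(n) = n' D n` and `W_app(n)` is the full contraction of the
#' kurtosis tensor with the direction.
#'
#' @param s0 non-diffusion-weighted signal (> 0).
#' @param D diffusion tensor, length-6 vector in the order
#'   `dxx, dyy, dzz, dxy, dxz, dyz` (mm^2/s), or a length-3 diagonal.
#' @param W kurtosis tensor, length-15 vector in the package component order,
#'   a length-3 vector taken as the `wxxxx, wyyyy, wzzzz` diagonal (all other
#'   components zero), or `NULL` for zero kurtosis.
#' @param gtab a [gradient_table()].
#' @return numeric vector of M signals.
#' @export
dki_signal <- function(s0, D, W = NULL, gtab) {
  stopifnot(inherits(gtab, "gradient_table"), s0 > 0)
  D <- expand_d(D); W <- expand_w(W)
  md <- mean(D[1:3])
  b <- gtab$bvals
  dapp <- dki_apparent_diffusivity(D, gtab$bvecs)
  wapp <- dki_apparent_wtensor(W, gtab$bvecs)
  s0 * exp(-b * dapp + (b^2 / 6) * md^2 * wapp)
}

expand_d <- function(D) {
  D <- as.numeric(D)
  if (length(D) == 3L) D <- c(D, 0, 0, 0)
  if (length(D) == 9L) {                      # 3x3 symmetric matrix
    m <- matrix(D, 3L, 3L)
    D <- c(diag(m), m[1, 2], m[1, 3], m[2, 3])
  }
  if (length(D) != 6L) stop("D must have 3 (diagonal), 6 or 9 elements")
  D
}

expand_w <- function(W) {
  if (is.null(W)) return(numeric(15L))
  W <- as.numeric(W)
  if (length(W) == 3L) W <- c(W, numeric(12L))
  if (length(W) != 15L) stop("W must have 3 (diagonal) or 15 elements")
  W
}
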