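# Group-comparison statistics used in ALPS cohort studies. Light wrappers
# over base stats where a canonical routine exists; the Lilliefors
# Monte-Carlo test and the exact-enumeration Mann-Whitney are implemented
# here (base R offers neither with the required tie handling / MC p-value).

new_test_result <- function(method, statistic, p_value, n, details = list()) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n = n, details = details),
            class = "alps_test")
}

#' @export
print.alps_test <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.4f, p = %.4g  (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}

# Lilliefors D: KS distance between the empirical CDF and a normal with
# estimated mean / sd
lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(pmax(i / n - p, p - (i - 1) / n))
}

# cache of Monte-Carlo null distributions of D, keyed by (n, reps, seed) —
# the null depends on the sample size only, so calibration loops reuse it
.lilliefors_cache <- new.env(parent = emptyenv())

#' Monte-Carlo null distribution of the Lilliefors statistic
#'
#' @param n sample size.
#' @param reps number of standard-normal samples to draw (default 5000).
#' @param seed RNG seed for the null draw.
#' @return numeric vector of `reps` null D values (cached per
#'   `(n, reps, seed)`).
#' @export
lilliefors_null <- function(n, reps = 5000, seed = 1) {
  key <- sprintf("n%d_r%d_s%d", n, reps, seed)
  if (!is.null(.lilliefors_cache[[key]])) return(.lilliefors_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  d0 <- vapply(seq_len(reps),
               function(i) lilliefors_statistic(stats::rnorm(n)), numeric(1))
  .lilliefors_cache[[key]] <- d0
  d0
}

#' Lilliefors test of normality (Monte-Carlo p-value)
#'
#' Kolmogorov-Smirnov-type test with mean and variance estimated from the
#' sample: `D = sup |Fhat(x) - Phi((x - xbar)/s)|`. The p-value is the
#' fraction of `reps` standard-normal samples of the same size whose D
#' exceeds the observed one (with the usual +1 continuity adjustment).
#'
#' @param x numeric sample, length >= 4, not constant.
#' @param reps Monte-Carlo replicates (default 5000).
#' @param seed seed for the null draw.
#' @return an `alps_test` with the D statistic and Monte-Carlo p.
#' @export
lilliefors <- function(x, reps = 5000, seed = 1) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("Lilliefors test needs n >= 4")
  if (stats::sd(x) == 0) stop("constant sample: normality test undefined")
  d <- lilliefors_statistic(x)
  d0 <- lilliefors_null(n, reps, seed)
  p <- (1 + sum(d0 >= d)) / (reps + 1)
  new_test_result("Lilliefors normality test (Monte-Carlo)", d, p, n,
                  list(reps = reps, seed = seed))
}

#' Two-sample t-test (pooled or Welch)
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param variant `"student"` (pooled variance, the classical two-sample
#'   t-test; default) or `"welch"` (Satterthwaite degrees of freedom).
#' @return an `alps_test` (two-sided p).
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(new_test_result(paste0("Two-sample t-test (", variant, ")"),
                             0, 1, c(length(a), length(b))))
    stop("zero variance with unequal means: t undefined")
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "student"))
  new_test_result(paste0("Two-sample t-test (", variant, ")"),
                  unname(ht$statistic), ht$p.value,
                  c(length(a), length(b)),
                  list(df = unname(ht$parameter),
                       means = c(mean(a), mean(b))))
}

#' Two-sample t-test from printed summary statistics
#'
#' Recomputes the pooled or Welch t-test from per-group mean, SD and n —
#' e.g. from a published "mean +/- SD" table. Identical to [two_sample_t()]
#' when the summaries are computed from the raw samples.
#'
#' @param m1,s1,n1 mean, SD, n of group 1.
#' @param m2,s2,n2 mean, SD, n of group 2.
#' @param variant `"student"` or `"welch"`.
#' @return an `alps_test` (two-sided p).
#' @export
t_from_summary <- function(m1, s1, n1, m2, s2, n2,
                           variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2)
      return(new_test_result(paste0("Summary t-test (", variant, ")"),
                             0, 1, c(n1, n2)))
    stop("zero variance with unequal means: t undefined")
  }
  if (variant == "student") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  new_test_result(paste0("Summary t-test (", variant, ")"), t, p, c(n1, n2),
                  list(df = df, means = c(m1, m2)))
}

# midranks of the pooled sample
pooled_u <- function(ranks_a, n1, n2) sum(ranks_a) - n1 * (n1 + 1) / 2

#' Mann-Whitney U test (exact enumeration or normal approximation)
#'
#' U is computed from midranks (ties allowed). In `"exact"` mode the null
#' distribution of U is enumerated over all `choose(n1 + n2, n1)` group
#' assignments of the pooled values (limited to n1 + n2 <= 20); the
#' two-sided p is `2 * min(P(U <= u), P(U >= u))` capped at 1. In
#' `"normal"` mode the tie-corrected variance and a 0.5 continuity
#' correction are used.
#'
#' @param a,b numeric samples.
#' @param mode `"exact"` or `"normal"`; default `"auto"` picks exact when
#'   n1 + n2 <= 20.
#' @return an `alps_test` with the U statistic of the first sample.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("each group needs n >= 1")
  if (mode == "auto") mode <- if (N <= 20) "exact" else "normal"
  pooled <- c(a, b)
  rk <- rank(pooled)                       # midranks
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (mode == "exact") {
    if (N > 20) stop("exact mode limited to n1 + n2 <= 20")
    combos <- utils::combn(N, n1)
    us <- apply(combos, 2L, function(ix) sum(rk[ix])) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(us <= u + eps), mean(us >= u - eps)))
    return(new_test_result("Mann-Whitney U test (exact)", u, p, c(n1, n2),
                           list(n_assignments = ncol(combos))))
  }
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(new_test_result("Mann-Whitney U test (normal)", u, 1,
                                     c(n1, n2)))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)
  if (u == mu) z <- 0
  p <- 2 * stats::pnorm(-abs(z))
  new_test_result("Mann-Whitney U test (normal)", u, min(1, p), c(n1, n2),
                  list(z = z))
}

#' 2x2 chi-square test
#'
#' `chi2 = N (ad - bc)^2 / (r1 r2 c1 c2)`, upper tail of the chi-square
#' distribution with 1 degree of freedom. No continuity correction by
#' default; `yates = TRUE` subtracts N/2 from |ad - bc|.
#'
#' @param tab 2x2 matrix of nonnegative counts with positive margins.
#' @param yates apply Yates continuity correction (default FALSE).
#' @return an `alps_test`.
#' @export
chi2_2x2 <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)) || any(tab < 0))
    stop("tab must be a 2x2 matrix of nonnegative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: chi-square undefined")
  N <- sum(tab)
  det_ <- abs(tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])
  if (yates) det_ <- max(0, det_ - N / 2)
  stat <- N * det_^2 / prod(rowSums(tab), colSums(tab))
  new_test_result(paste0("Chi-square (2x2", if (yates) ", Yates", ")"),
                  stat, chi2_tail(stat), c(N))
}

#' Upper tail of the 1-df chi-square distribution
#'
#' @param statistic chi-square value.
#' @return `P(X >= statistic)` for X ~ chi-square(1).
#' @export
chi2_tail <- function(statistic) stats::pchisq(statistic, df = 1, lower.tail = FALSE)

#' Correlation between an index and a clinical variable
#'
#' Pearson or Spearman, pairwise-complete (listwise deletion of missing
#' pairs); two-sided p via the t transform (on midranks for Spearman).
#'
#' @param x,y paired numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return an `alps_test` whose statistic is the correlation coefficient.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(t), n - 2)
  new_test_result(paste0(toupper(substr(method, 1, 1)),
                         substr(method, 2, 20), " correlation"),
                  r, p, n, list(t = t))
}
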