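#' Two-group cohort report
#'
#' Reproduces the standard ALPS-study report layout: per-group mean +/- SD
#' for demographics, clinical scores and the six ALPS indices, with the test
#' battery conventionally used — Mann-Whitney U for continuous demographics,
#' 2x2 chi-square for sex, and, for each index, a Lilliefors normality check
#' per group followed by the two-sample t-test. Significance is starred at
#' `alpha` (no multiple-testing correction, matching common practice in this
#' literature). Both pooled and Welch t p-values are recorded; the pooled
#' one decides the star by default.
#'
#' @param cohort an `alps_cohort` data frame (see [simulate_cohort()] /
#'   [read_cohort()]): `group` must have the two levels `migraine` and
#'   `control`.
#' @param alpha significance threshold (default 0.05).
#' @param lilliefors_reps,seed Monte-Carlo settings for the normality check.
#' @param inter_index_correlation also report the Pearson correlation
#'   between the global DTI-ALPS and DKI-ALPS indices (default TRUE).
#' @return list of class `group_report` with data frames `demographics` and
#'   `indices`, and optionally `inter_index`.
#' @export
group_report <- function(cohort, alpha = 0.05, lilliefors_reps = 5000,
                         seed = 1, inter_index_correlation = TRUE) {
  if (!all(c("migraine", "control") %in% cohort$group))
    stop("cohort must contain both groups 'migraine' and 'control'")
  mig <- cohort[cohort$group == "migraine", , drop = FALSE]
  ctl <- cohort[cohort$group == "control", , drop = FALSE]

  msd <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return("-")
    sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  }

  demo_rows <- list()
  if ("sex" %in% names(cohort)) {
    tab <- rbind(c(sum(mig$sex == "M"), sum(mig$sex == "F")),
                 c(sum(ctl$sex == "M"), sum(ctl$sex == "F")))
    ch <- chi2_2x2(tab)
    demo_rows[["sex"]] <- data.frame(
      variable = "sex (M/F)",
      migraine = sprintf("%d/%d", tab[1, 1], tab[1, 2]),
      control = sprintf("%d/%d", tab[2, 1], tab[2, 2]),
      test = "chi-square", statistic = ch$statistic, p = ch$p_value)
  }
  for (v in intersect(c("age", "education"), names(cohort))) {
    mw <- mann_whitney(mig[[v]], ctl[[v]], mode = "normal")
    demo_rows[[v]] <- data.frame(
      variable = v, migraine = msd(mig[[v]]), control = msd(ctl[[v]]),
      test = "Mann-Whitney U", statistic = mw$statistic, p = mw$p_value)
  }
  for (v in intersect(c("duration", "frequency", "phq9", "gad7", "midas",
                        "hit6"), names(cohort))) {
    demo_rows[[v]] <- data.frame(
      variable = v, migraine = msd(mig[[v]]), control = msd(ctl[[v]]),
      test = "-", statistic = NA_real_, p = NA_real_)
  }
  demographics <- do.call(rbind, demo_rows)
  rownames(demographics) <- NULL

  index_cols <- c("dti_left", "dti_right", "dti_global",
                  "dki_left", "dki_right", "dki_global")
  idx_rows <- lapply(index_cols, function(v) {
    lm_ <- lilliefors(mig[[v]], reps = lilliefors_reps, seed = seed)
    lc_ <- lilliefors(ctl[[v]], reps = lilliefors_reps, seed = seed)
    ts <- two_sample_t(mig[[v]], ctl[[v]], "student")
    tw <- two_sample_t(mig[[v]], ctl[[v]], "welch")
    data.frame(index = v, migraine = msd(mig[[v]]), control = msd(ctl[[v]]),
               lilliefors_p_migraine = lm_$p_value,
               lilliefors_p_control = lc_$p_value,
               t = ts$statistic, p = ts$p_value, p_welch = tw$p_value,
               significant = ts$p_value < alpha)
  })
  indices <- do.call(rbind, idx_rows)
  rownames(indices) <- NULL

  out <- list(demographics = demographics, indices = indices, alpha = alpha,
              n = c(migraine = nrow(mig), control = nrow(ctl)))
  if (inter_index_correlation)
    out$inter_index <- correlate(cohort$dti_global, cohort$dki_global,
                                 "pearson")
  class(out) <- "group_report"
  out
}

#' @export
print.group_report <- function(x, ...) {
  cat(sprintf("Two-group report (migraine n = %d, control n = %d, alpha = %g)\n\n",
              x$n[["migraine"]], x$n[["control"]], x$alpha))
  cat("Demographics and clinical scores:\n")
  d <- x$demographics
  d$statistic <- ifelse(is.na(d$statistic), "-", sprintf("%.3f", d$statistic))
  d$p <- ifelse(is.na(d$p), "-", sprintf("%.4f", d$p))
  print(d, row.names = FALSE)
  cat("\nALPS indices (pooled two-sample t; Welch in p_welch):\n")
  i <- x$indices
  i$star <- ifelse(i$significant, "*", "")
  print(data.frame(index = i$index, migraine = i$migraine,
                   control = i$control, t = sprintf("%.3f", i$t),
                   p = sprintf("%.4f", i$p), star = i$star),
        row.names = FALSE)
  if (!is.null(x$inter_index))
    cat(sprintf("\nDTI-ALPS vs DKI-ALPS (global): r = %.3f, p = %.4g\n",
                x$inter_index$statistic, x$inter_index$p_value))
  invisible(x)
}

#' Write a group report as TSV files
#'
#' @param report a [group_report()] result.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_group_report <- function(report, dir, prefix = "report_") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$demographics,
                     file.path(dir, paste0(prefix, "demographics.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$indices,
                     file.path(dir, paste0(prefix, "indices.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
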