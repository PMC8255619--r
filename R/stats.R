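# Between-group discrimination: Cohen's d and rank-based ROC AUC.

#' Cohen's d from group summary statistics
#'
#' The symmetric two-group form
#' `d = (mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)`; the sign is
#' preserved, so the orientation is whatever the caller's (a, b) order
#' implies.
#'
#' @param mean_a,sd_a mean and SD of group a.
#' @param mean_b,sd_b mean and SD of group b.
#' @return Signed effect size.
#' @export
cohens_d <- function(mean_a, sd_a, mean_b, sd_b) {
  if (sd_a < 0 || sd_b < 0)
    persi_error("standard deviations must be non-negative", "persi_parameter_error")
  if (sd_a == 0 && sd_b == 0)
    persi_error("both SDs are zero; effect size undefined",
                "persi_undefined_effect_error")
  (mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)
}

#' Nonparametric ROC AUC by rank statistic
#'
#' `AUC = P(b > a) + P(b = a) / 2`, the probability that a randomly chosen
#' member of the positive (patient) group `b` scores above a randomly chosen
#' member of group `a`, with half credit for ties. Computed via midranks
#' (the Mann-Whitney identity), which equals the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param values_a scores of the negative (control) group, >= 2 finite values.
#' @param values_b scores of the positive (patient) group, >= 2 finite values.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(values_a, values_b) {
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  if (length(a) < 2L || length(b) < 2L || any(!is.finite(c(a, b))))
    persi_error("each group needs at least 2 finite values",
                "persi_sample_size_error")
  r <- rank(c(a, b))
  nb <- length(b)
  (sum(r[(length(a) + 1L):(length(a) + nb)]) - nb * (nb + 1) / 2) /
    (length(a) * nb)
}

#' Group discrimination per region and reference method
#'
#' For one pair of diagnostic groups, computes per (region, method) the
#' signed Cohen's d (patient minus control) from group SUVR means/SDs and
#' the ROC AUC from subject-level SUVRs with the patient group as the
#' positive class.
#'
#' @param table a `suvr_table`.
#' @param pair character length-2, `c(control, patient)`, e.g.
#'   `c("HC", "AD")`.
#' @return A data.frame of class `group_comparison`: `region`, `method`,
#'   `pair`, `cohens_d`, `auc`, `n_a`, `n_b`.
#' @export
compare_groups <- function(table, pair = c("HC", "AD")) {
  stopifnot(length(pair) == 2L)
  df <- as.data.frame(table)
  missing <- setdiff(pair, unique(df$group))
  if (length(missing) > 0L)
    persi_error(sprintf("group(s) absent from table: %s",
                        paste(missing, collapse = ", ")), "persi_cohort_error")
  out <- list()
  for (m in unique(df$method)) {
    for (reg in unique(df$region)) {
      a <- df$suvr[df$group == pair[1] & df$method == m & df$region == reg]
      b <- df$suvr[df$group == pair[2] & df$method == m & df$region == reg]
      if (length(a) < 2L || length(b) < 2L)
        persi_error(sprintf("fewer than 2 subjects for %s/%s in pair %s",
                            reg, m, paste(pair, collapse = "-vs-")),
                    "persi_sample_size_error")
      out[[length(out) + 1L]] <- data.frame(
        region = reg, method = m, pair = paste(pair, collapse = "-vs-"),
        cohens_d = cohens_d(mean(b), stats::sd(b), mean(a), stats::sd(a)),
        auc = auc_rank(a, b), n_a = length(a), n_b = length(b),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("group_comparison", "data.frame")
  res
}
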