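# shared machinery: vectorized per-group means/variances and pooled
# two-sample t-tests on log intensities
group_stats <- function(dt) {
  dt[, .(mean_raw = mean(intensity),
         mean_log = mean(log(intensity)),
         var_log = stats::var(log(intensity)),
         n = .N),
     by = .(mutant, timepoint_min, metabolite_id)]
}

pooled_t_pvalue <- function(m1, v1, n1, m2, v2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs((m1 - m2) / se), df)
  # degenerate groups: zero pooled variance
  zero <- is.finite(sp2) & sp2 == 0
  p[zero] <- as.numeric(m1[zero] == m2[zero])
  p[n1 < 2 | n2 < 2 | df < 1] <- NA_real_
  p
}

welch_t_pvalue <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs((m1 - m2) / sqrt(se2)), df)
  zero <- is.finite(se2) & se2 == 0
  p[zero] <- as.numeric(m1[zero] == m2[zero])
  p[n1 < 2 | n2 < 2] <- NA_real_
  p
}

#' Mutant-versus-reference log2 fold-change metabolome profiles
#'
#' For every (mutant, timepoint, metabolite), computes the log2 fold-change
#' of the mutant's mean intensity over the reference strain's mean intensity
#' at the matched timepoint, and a two-sided t-test p-value on natural-log
#' intensities (pooled-variance Student by default).
#'
#' @param intensities long-format intensity table.
#' @param reference reference strain name (default \code{"WT"}).
#' @param fc_method \code{"ratio_of_means"} (log2 of the ratio of group mean
#'   intensities, the default) or \code{"mean_of_ratios"} (difference of
#'   group mean log2 intensities).
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @return data.table of class \code{mg_profiles}: mutant, timepoint_min,
#'   metabolite_id, mean_log2_fc, p_value, n_mutant_reps, n_wt_reps.
#'   Cells where the reference is missing carry NA fold-changes.
#' @export
log2_fold_change_profiles <- function(intensities, reference = "WT",
                                      fc_method = c("ratio_of_means",
                                                    "mean_of_ratios"),
                                      var_equal = TRUE) {
  fc_method <- match.arg(fc_method)
  dt <- data.table::as.data.table(intensities)
  if (!reference %in% dt$mutant) {
    stop("reference strain '", reference, "' absent from the table")
  }
  st <- group_stats(dt)
  ref <- st[mutant == reference,
            .(timepoint_min, metabolite_id, ref_mean_raw = mean_raw,
              ref_mean_log = mean_log, ref_var_log = var_log, ref_n = n)]
  mut <- st[mutant != reference]
  out <- merge(mut, ref, by = c("timepoint_min", "metabolite_id"),
               all.x = TRUE)
  # difference of log2 means (not log2 of the ratio) so that swapping the
  # two groups negates the fold-change bit-exactly
  out[, mean_log2_fc := if (fc_method == "ratio_of_means") {
        log2(mean_raw) - log2(ref_mean_raw)
      } else {
        (mean_log - ref_mean_log) / log(2)
      }]
  pfun <- if (var_equal) pooled_t_pvalue else welch_t_pvalue
  out[, p_value := pfun(mean_log, var_log, n,
                        ref_mean_log, ref_var_log, ref_n)]
  res <- out[, .(mutant, timepoint_min, metabolite_id, mean_log2_fc,
                 p_value, n_mutant_reps = n, n_wt_reps = ref_n)]
  data.table::setorder(res, mutant, timepoint_min, metabolite_id)
  data.table::setattr(res, "class", c("mg_profiles", class(res)))
  data.table::setattr(res, "reference", reference)
  res[]
}

#' Significance calls and per-(mutant, timepoint) counts
#'
#' A metabolite change is called significant when the absolute log2
#' fold-change exceeds \code{fc_cut} and the p-value is below \code{p_cut}.
#' Missing fold-changes or p-values are never significant (flagged in the
#' output). No multiple-testing correction is applied: counts are raw
#' p < \code{p_cut} tallies.
#'
#' @param profiles an \code{mg_profiles} table.
#' @param fc_cut absolute log2 fold-change threshold (default 0.5).
#' @param p_cut p-value threshold (default 0.05).
#' @return list: \code{calls} (profiles plus \code{significant} and
#'   \code{missing} flags), \code{counts} (data.table mutant, timepoint_min,
#'   n_significant), \code{fc_cut}, \code{p_cut}.
#' @export
significant_changes <- function(profiles, fc_cut = 0.5, p_cut = 0.05) {
  calls <- data.table::as.data.table(profiles)
  calls[, missing := is.na(mean_log2_fc) | is.na(p_value)]
  calls[, significant := !missing & abs(mean_log2_fc) > fc_cut &
                          p_value < p_cut]
  counts <- calls[, .(n_significant = sum(significant)),
                  by = .(mutant, timepoint_min)]
  list(calls = calls[], counts = counts[], fc_cut = fc_cut, p_cut = p_cut)
}

#' Within-strain treatment response profiles
#'
#' Fold-changes of each treated timepoint against the same strain's
#' untreated (t = 0) samples, with the same test as
#' \code{\link{log2_fold_change_profiles}}.
#'
#' @inheritParams log2_fold_change_profiles
#' @param mutant strain to profile.
#' @return an \code{mg_profiles}-style data.table (timepoint_min > 0 only),
#'   with columns n_mutant_reps/n_wt_reps giving treated/untreated counts.
#' @export
treatment_response <- function(intensities, mutant = "WT",
                               fc_method = c("ratio_of_means",
                                             "mean_of_ratios"),
                               var_equal = TRUE) {
  fc_method <- match.arg(fc_method)
  dt <- data.table::as.data.table(intensities)
  keep <- dt$mutant == mutant
  dt <- dt[keep]
  if (nrow(dt) == 0) stop("strain '", mutant, "' absent from the table")
  if (!any(dt$timepoint_min == 0)) {
    stop("strain '", mutant, "' has no untreated (t = 0) samples")
  }
  st <- group_stats(dt)
  ref <- st[timepoint_min == 0,
            .(metabolite_id, ref_mean_raw = mean_raw, ref_mean_log = mean_log,
              ref_var_log = var_log, ref_n = n)]
  trt <- st[timepoint_min > 0]
  out <- merge(trt, ref, by = "metabolite_id", all.x = TRUE)
  out[, mean_log2_fc := if (fc_method == "ratio_of_means") {
        log2(mean_raw) - log2(ref_mean_raw)
      } else {
        (mean_log - ref_mean_log) / log(2)
      }]
  pfun <- if (var_equal) pooled_t_pvalue else welch_t_pvalue
  out[, p_value := pfun(mean_log, var_log, n,
                        ref_mean_log, ref_var_log, ref_n)]
  res <- out[, .(mutant, timepoint_min, metabolite_id, mean_log2_fc,
                 p_value, n_mutant_reps = n, n_wt_reps = ref_n)]
  data.table::setorder(res, timepoint_min, metabolite_id)
  res[]
}
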