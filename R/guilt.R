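#' Distance-to-positive-set scores
#'
#' Scores each mutant by the median (or mean) of its distances to the
#' annotated positive regulators. Annotated positives are scored
#' leave-one-out: a positive's own distance to itself never enters its score.
#' Lower scores mean more positive-regulator-like.
#'
#' @param dist symmetric distance matrix with mutant dimnames.
#' @param positives character vector of annotated positive mutants (>= 2,
#'   all present in \code{dist}).
#' @param summary \code{"median"} (default) or \code{"mean"}.
#' @return data.table of class \code{mg_scores}: mutant, score,
#'   is_annotated_positive; attributes \code{summary} and
#'   \code{timepoint_min}.
#' @export
set_distance_scores <- function(dist, positives,
                                summary = c("median", "mean")) {
  summary <- match.arg(summary)
  D <- as.matrix(dist)
  lbl <- rownames(D)
  if (!all(positives %in% lbl)) {
    stop("positives absent from the distance matrix: ",
         paste(setdiff(positives, lbl), collapse = ", "))
  }
  positives <- unique(positives)
  if (length(positives) < 2) stop("need at least 2 annotated positives")
  sfun <- if (summary == "median") stats::median else mean
  score <- vapply(lbl, function(m) {
    ref <- setdiff(positives, m)
    sfun(D[m, ref])
  }, numeric(1))
  out <- data.table::data.table(mutant = lbl, score = unname(score),
                                is_annotated_positive = lbl %in% positives)
  data.table::setattr(out, "class", c("mg_scores", class(out)))
  data.table::setattr(out, "summary", summary)
  data.table::setattr(out, "timepoint_min", attr(dist, "timepoint_min"))
  out[]
}

#' Permutation test for positive-set cohesion
#'
#' Observed statistic: the median pairwise distance within the positive set.
#' Null: the same statistic on \code{B} uniformly random mutant subsets of
#' the same size (label randomization on correlation profiles). Empirical
#' p-value with the add-one rule: \code{p = (1 + #\{null <= obs\}) / (1 + B)}.
#'
#' @param dist symmetric distance matrix with mutant dimnames.
#' @param positives annotated positive mutants (>= 2).
#' @param B number of randomizations (default 10000).
#' @param seed optional RNG seed for reproducibility.
#' @return list of class \code{mg_permutation}: observed, null (length-B
#'   numeric), B, p_value, seed.
#' @export
permutation_pvalue <- function(dist, positives, B = 10000L, seed = NULL) {
  D <- as.matrix(dist)
  lbl <- rownames(D)
  positives <- unique(positives)
  if (!all(positives %in% lbl)) stop("positives absent from distance matrix")
  k <- length(positives)
  if (k < 2) stop("need at least 2 positives")
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(D)

  median_within <- function(members) {
    sub <- D[members, members]
    stats::median(sub[upper.tri(sub)])
  }
  observed <- median_within(match(positives, lbl))
  if (k == n) {
    out <- list(observed = observed, null = rep(observed, B), B = as.integer(B),
                p_value = 1, seed = seed)
    class(out) <- "mg_permutation"
    return(out)
  }
  pair_idx <- utils::combn(k, 2)
  null <- vapply(seq_len(B), function(b) {
    s <- sample.int(n, k)
    stats::median(D[cbind(s[pair_idx[1, ]], s[pair_idx[2, ]])])
  }, numeric(1))
  p <- (1 + sum(null <= observed)) / (1 + B)
  out <- list(observed = observed, null = null, B = as.integer(B),
              p_value = p, seed = seed)
  class(out) <- "mg_permutation"
  out
}

#' ROC curve and AUC for recovery of annotated positives
#'
#' A mutant is predicted positive when its score is at or below a threshold;
#' thresholds sweep all observed scores. The AUC is computed by the rank
#' (Mann-Whitney) formulation with ties counted one half, which equals the
#' trapezoidal integral of the (FPR, TPR) curve.
#'
#' @param scores an \code{mg_scores} table (\code{\link{set_distance_scores}})
#'   with logical \code{is_annotated_positive}.
#' @param target_fpr false-positive rate at which the nomination threshold is
#'   placed (default 0.2).
#' @return list of class \code{mg_roc}: points (data.table threshold, fpr,
#'   tpr), auc, threshold_at_target_fpr (largest observed score with FPR <=
#'   target; NA if unattainable), target_fpr.
#' @export
roc_auc <- function(scores, target_fpr = 0.2) {
  sc <- data.table::as.data.table(scores)
  lab <- sc$is_annotated_positive
  if (all(lab) || !any(lab)) stop("need at least one positive and one negative")
  s <- sc$score
  np <- sum(lab); nn <- sum(!lab)

  # Mann-Whitney with ties one half: P(score_pos < score_neg) + 0.5 P(equal)
  r <- rank(s)
  auc <- (sum(r[!lab]) - nn * (nn + 1) / 2) / (np * nn)

  th <- sort(unique(s))
  tpr <- vapply(th, function(t) mean(s[lab] <= t), numeric(1))
  fpr <- vapply(th, function(t) mean(s[!lab] <= t), numeric(1))
  points <- data.table::data.table(threshold = c(-Inf, th),
                                   fpr = c(0, fpr), tpr = c(0, tpr))
  ok <- which(fpr <= target_fpr)
  threshold <- if (length(ok)) max(th[ok]) else NA_real_
  out <- list(points = points, auc = auc,
              threshold_at_target_fpr = threshold, target_fpr = target_fpr)
  class(out) <- "mg_roc"
  out
}

#' Nominate candidate positive regulators at the FPR threshold
#'
#' Completes the score table with each mutant's ratio of score to the
#' FPR-targeted distance threshold (ratio < 1 passes) and returns the
#' non-positive-annotated passers as candidates.
#'
#' @param scores an \code{mg_scores} table.
#' @param roc the matching \code{mg_roc} from \code{\link{roc_auc}}.
#' @return list: \code{scores} (completed table with ratio_to_threshold and
#'   pass), \code{candidates} (character vector), \code{threshold}.
#' @export
nominate_candidates <- function(scores, roc) {
  sc <- data.table::copy(data.table::as.data.table(scores))
  t0 <- roc$threshold_at_target_fpr
  if (is.na(t0)) {
    warning("no threshold attains FPR <= ", roc$target_fpr,
            "; empty candidate list")
    sc[, `:=`(ratio_to_threshold = NA_real_, pass = FALSE)]
    return(list(scores = sc[], candidates = character(0), threshold = NA_real_))
  }
  sc[, ratio_to_threshold := score / t0]
  sc[, pass := ratio_to_threshold < 1]
  cands <- sc[pass & !is_annotated_positive, mutant]
  list(scores = sc[], candidates = cands, threshold = t0)
}
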