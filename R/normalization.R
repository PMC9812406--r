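#' Remove outlier samples by biomass and total ion current
#'
#' Flags samples whose OD600 or log total ion current (TIC, the sum of all
#' ion intensities in the sample) deviates from the cohort median by more
#' than \code{k_mad} median absolute deviations, and removes them. The rule
#' is applied to convergence (median/MAD recomputed on the retained cohort
#' after each pass), so the operation is idempotent: no retained sample
#' deviates from the retained cohort's statistics by more than the cutoff.
#' With zero dispersion (MAD = 0) any nonzero deviation is flagged.
#'
#' @param intensities long-format intensity table (see
#'   \code{\link{generate_dataset}}); must carry \code{sample_id},
#'   \code{od600} and \code{intensity}.
#' @param k_mad MAD multiplier; \code{Inf} disables filtering.
#' @return list with \code{intensities} (retained rows) and \code{report}
#'   (list: \code{excluded} data.table with sample_id, od600, log_tic and the
#'   single rule that triggered exclusion; \code{n_retained};
#'   \code{k_mad}).
#' @export
filter_outlier_samples <- function(intensities, k_mad = 3) {
  dt <- data.table::as.data.table(intensities)
  per <- dt[, .(od600 = od600[1], log_tic = log(sum(intensity))),
            by = sample_id]
  if (nrow(per) < 3) stop("need at least 3 samples to assess outliers")

  flag <- function(x) {
    if (is.infinite(k_mad)) return(rep(FALSE, length(x)))
    dev <- abs(x - stats::median(x))
    dev > k_mad * stats::mad(x)   # mad = 0 => any nonzero deviation flagged
  }
  retained <- per
  excluded <- per[0][, rule := character(0)]
  repeat {
    bad_od <- flag(retained$od600)
    bad_tic <- flag(retained$log_tic)
    bad <- bad_od | bad_tic
    if (!any(bad)) break
    hit <- retained[bad]
    hit[, rule := data.table::fifelse(bad_od[bad], "od600",
                                      "total_ion_current")]
    excluded <- rbind(excluded, hit)
    retained <- retained[!bad]
    if (nrow(retained) == 0) stop("all samples excluded as outliers")
  }

  keep <- dt[!sample_id %in% excluded$sample_id]
  list(intensities = keep,
       report = list(excluded = excluded,
                     n_retained = nrow(per) - nrow(excluded),
                     k_mad = k_mad))
}

#' LOWESS detrending of intensities against a nuisance covariate
#'
#' Per metabolite, fits a LOWESS curve of natural-log intensity against the
#' chosen covariate (acquisition order or OD600) and replaces the log
#' intensity by its residual re-centred to the metabolite's original mean
#' log intensity. Intended to be applied sequentially: first
#' \code{injection_index}, then \code{od600}.
#'
#' @param intensities long-format intensity table.
#' @param covariate \code{"injection_index"} or \code{"od600"}.
#' @param span LOWESS smoother span in (0, 1].
#' @param iter number of robustifying iterations.
#' @return the intensity table with detrended \code{intensity}.
#' @export
lowess_detrend <- function(intensities,
                           covariate = c("injection_index", "od600"),
                           span = 0.3, iter = 3L) {
  covariate <- match.arg(covariate)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  dt <- data.table::as.data.table(intensities)
  if (any(dt$intensity <= 0)) stop("intensities must be positive")
  if (dt[, .N, by = metabolite_id][, min(N)] < 10) {
    stop("need at least 10 samples per metabolite for LOWESS detrending")
  }
  detrend_one <- function(y, x) {
    ly <- log(y)
    if (stats::var(x) == 0) {
      warning("constant covariate '", covariate, "': detrending skipped")
      return(y)
    }
    fit <- stats::lowess(x, ly, f = span, iter = iter)
    yhat <- stats::approx(fit$x, fit$y, xout = x, rule = 2, ties = mean)$y
    resid <- ly - yhat
    exp(resid - mean(resid) + mean(ly))
  }
  dt[, intensity := detrend_one(intensity, get(covariate)),
     by = metabolite_id]
  dt[]
}

#' Quantile normalization of a positive intensity matrix
#'
#' Forces every sample (column) to share one common distribution: the
#' across-sample mean of order statistics. Within-sample ranks are
#' preserved; ties receive the mean of the corresponding reference values
#' (average-rank interpolation). Rows are features, columns are samples.
#'
#' @param mat numeric matrix, features x samples, no missing values.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing values are not supported; impute or drop rows")
  if (ncol(mat) == 1) return(mat)
  sorted <- apply(mat, 2, sort)
  ref <- rowMeans(sorted)
  out <- apply(mat, 2, function(x) {
    r <- rank(x, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (ref[lo] + ref[hi]) / 2
  })
  dimnames(out) <- dimnames(mat)
  out
}
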