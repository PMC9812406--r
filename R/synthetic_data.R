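#' Simulation configuration for synthetic mutant-library metabolomics
#'
#' Bundles and validates every knob of the synthetic flow-injection dataset:
#' library composition, sampling design, the wild-type rapamycin response,
#' the planted class signal, and the nuisance structure (acquisition-order
#' drift, culture-density effect, replicate noise).
#'
#' The defaults describe a desk-scale version of a rapamycin time-course
#' screen: a wild-type reference plus 6 positive-regulator, 6
#' negative-regulator and 48 neutral deletion strains, profiled for 100
#' annotated ions at 0/5/30/60/90 min in 4 biological replicates.
#'
#' @param n_metabolites number of annotated ions.
#' @param n_positive,n_negative,n_neutral library composition by planted
#'   functional class (the wild-type reference "WT" is always added).
#' @param timepoints_min minutes since rapamycin addition; must contain 0
#'   (the untreated control condition).
#' @param n_replicates biological replicates per (strain, timepoint).
#' @param wt_response_amplitude log2-scale amplitude of the wild-type
#'   metabolome response to rapamycin; per-metabolite amplitudes are drawn
#'   uniformly in \code{[0.5, 1.5] * wt_response_amplitude}.
#' @param rising_fraction fraction of metabolites that accumulate under
#'   rapamycin (amino-acid-like); the rest deplete.
#' @param response_tau_min time constant (min) of the exponential-approach
#'   response curve \code{1 - exp(-t/tau)} shared by treatment responses and
#'   planted mutant effects.
#' @param shared_signature_sd log2 sd of the metabolite signature shared by
#'   all positive regulators (negated in negative regulators).
#' @param amplification_factor scaling of the wild-type response in positive
#'   regulators (1 = no amplification).
#' @param neutral_effect_sd log2 sd of independent per-mutant effects in
#'   neutral strains.
#' @param replicate_noise_sd natural-log sd of multiplicative replicate noise.
#' @param drift_amplitude log2 span of the smooth multiplicative intensity
#'   drift across the acquisition run (1 = doubling across the run).
#' @param od_effect_slope log2 intensity change per log2-fold change in OD600.
#' @param seed integer RNG seed.
#' @return an object of class \code{simulation_config} (a validated list).
#' @export
simulation_config <- function(n_metabolites = 100L,
                              n_positive = 6L,
                              n_negative = 6L,
                              n_neutral = 48L,
                              timepoints_min = c(0, 5, 30, 60, 90),
                              n_replicates = 4L,
                              wt_response_amplitude = 1.0,
                              rising_fraction = 0.5,
                              response_tau_min = 15,
                              shared_signature_sd = 0.5,
                              amplification_factor = 1.5,
                              neutral_effect_sd = 0.2,
                              replicate_noise_sd = 0.2,
                              drift_amplitude = 0.25,
                              od_effect_slope = 0.3,
                              seed = 1L) {
  counts <- c(n_metabolites = n_metabolites, n_positive = n_positive,
              n_negative = n_negative, n_neutral = n_neutral,
              n_replicates = n_replicates)
  if (any(counts < 0)) {
    stop("counts must be non-negative: ",
         paste(names(counts)[counts < 0], collapse = ", "))
  }
  sds <- c(wt_response_amplitude = wt_response_amplitude,
           shared_signature_sd = shared_signature_sd,
           neutral_effect_sd = neutral_effect_sd,
           replicate_noise_sd = replicate_noise_sd)
  if (any(sds < 0)) {
    stop("standard deviations/amplitudes must be non-negative: ",
         paste(names(sds)[sds < 0], collapse = ", "))
  }
  if (!0 %in% timepoints_min) stop("timepoints_min must include 0 (untreated)")
  if (any(timepoints_min < 0)) stop("timepoints_min must be non-negative")
  if (n_replicates == 0 && replicate_noise_sd > 0) {
    stop("zero replicates with nonzero replicate_noise_sd: profiles undefined")
  }
  if (rising_fraction < 0 || rising_fraction > 1) {
    stop("rising_fraction must be in [0, 1]")
  }
  if (response_tau_min <= 0) stop("response_tau_min must be positive")
  cfg <- list(n_metabolites = as.integer(n_metabolites),
              n_positive = as.integer(n_positive),
              n_negative = as.integer(n_negative),
              n_neutral = as.integer(n_neutral),
              timepoints_min = sort(unique(as.numeric(timepoints_min))),
              n_replicates = as.integer(n_replicates),
              wt_response_amplitude = wt_response_amplitude,
              rising_fraction = rising_fraction,
              response_tau_min = response_tau_min,
              shared_signature_sd = shared_signature_sd,
              amplification_factor = amplification_factor,
              neutral_effect_sd = neutral_effect_sd,
              replicate_noise_sd = replicate_noise_sd,
              drift_amplitude = drift_amplitude,
              od_effect_slope = od_effect_slope,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# smooth low-frequency drift on the log2 scale: linear term plus one slow
# sinusoid, scaled so the total log2 span across the run equals `amplitude`
drift_log2 <- function(injection_index, n_total, amplitude) {
  if (n_total <= 1) return(rep(0, length(injection_index)))
  frac <- (injection_index - 1) / (n_total - 1)
  amplitude * (frac + 0.3 * sin(3 * pi * frac)) / 1.3
}

response_curve <- function(t_min, tau) 1 - exp(-t_min / tau)

#' Generate a synthetic mutant x metabolite x timepoint intensity dataset
#'
#' Emits a long-format ion-intensity table with full sample metadata, a
#' mutant annotation table, and the planted ground truth. The generative
#' model on the log2 scale is
#' \deqn{\log_2 I = \log_2 b_j + f_j^{WT}(t) + \delta_{mj}(t) + d(i) +
#'   s \log_2(OD/OD_{ref}) + \epsilon/\ln 2}
#' where \eqn{b_j} is the metabolite baseline, \eqn{f_j^{WT}} the wild-type
#' rapamycin response (exponential approach, rising or falling),
#' \eqn{\delta_{mj}} the mutant-specific deviation from wild-type, \eqn{d}
#' the smooth acquisition drift, and \eqn{\epsilon \sim N(0,
#' \sigma_{rep})} replicate noise. Positive regulators share one metabolite
#' signature (plus an amplified wild-type response), negative regulators
#' carry the negated signature, and neutral strains carry independent small
#' effects; all mutant deviations scale with the treatment-response curve and
#' are therefore zero at t = 0.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a list of class \code{mg_dataset} with elements
#'   \code{intensities} (data.table: sample_id, mutant, timepoint_min,
#'   replicate, injection_index, od600, treatment, metabolite_id, intensity),
#'   \code{annotation} (data.table: mutant, class) and \code{truth} (list:
#'   class assignments, wild-type response matrix, signature, per-mutant
#'   effects, drift values, seed, config).
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  mutants <- c(
    sprintf("pos%02d", seq_len(config$n_positive)),
    sprintf("neg%02d", seq_len(config$n_negative)),
    sprintf("ntr%02d", seq_len(config$n_neutral))
  )
  classes <- rep(c("positive_regulator", "negative_regulator",
                   "tor_related_other"),
                 c(config$n_positive, config$n_negative, config$n_neutral))
  # neutral strains are split between generic TOR-related and receptor-related
  # annotations, mirroring a mixed screening collection
  if (config$n_neutral > 0) {
    idx <- which(classes == "tor_related_other")
    half <- idx[seq_len(floor(length(idx) / 2))]
    classes[setdiff(idx, half)] <- "receptor_related"
  }
  annotation <- data.table::data.table(mutant = mutants, class = classes)

  strains <- c(mutants, "WT")
  tps <- config$timepoints_min
  nm <- config$n_metabolites
  metabolites <- sprintf("ion%03d", seq_len(nm))

  # per-metabolite baselines and wild-type response
  baseline <- exp(stats::rnorm(nm, log(1e5), 1))
  n_rise <- round(config$rising_fraction * nm)
  direction <- rep(c(1, -1), c(n_rise, nm - n_rise))
  amp <- config$wt_response_amplitude * stats::runif(nm, 0.5, 1.5) * direction
  g <- response_curve(tps, config$response_tau_min)        # length |tps|
  fc_wt <- outer(amp, g)                                   # nm x |tps|, log2

  # planted class structure (log2 deviations from wild-type, scaled by g(t))
  signature <- stats::rnorm(nm, 0, config$shared_signature_sd)
  effect <- matrix(0, nrow = length(strains), ncol = nm,
                   dimnames = list(strains, metabolites))
  for (m in seq_along(mutants)) {
    effect[m, ] <- switch(classes[m],
      positive_regulator = signature,
      negative_regulator = -signature,
      stats::rnorm(nm, 0, config$neutral_effect_sd))
  }
  amp_extra <- (config$amplification_factor - 1) *
    (annotation$class == "positive_regulator")

  samples <- data.table::CJ(mutant = strains, timepoint_min = tps,
                            replicate = seq_len(config$n_replicates),
                            sorted = FALSE)
  n_samp <- nrow(samples)
  samples[, `:=`(
    treatment = data.table::fifelse(timepoint_min == 0, "control", "rapamycin"),
    injection_index = sample.int(n_samp)
  )]
  # one culture per (strain, replicate); mild residual growth under rapamycin
  od0 <- stats::rnorm(length(strains) * config$n_replicates, 0.5, 0.05)
  od0 <- pmax(od0, 0.1)
  cult <- match(paste(samples$mutant, samples$replicate),
                paste(rep(strains, each = config$n_replicates),
                      rep(seq_len(config$n_replicates), length(strains))))
  samples[, od600 := od0[cult] * exp(0.15 * timepoint_min / 60) *
                      exp(stats::rnorm(n_samp, 0, 0.02))]
  samples[, sample_id := sprintf("S%04d", seq_len(n_samp))]

  drift <- drift_log2(seq_len(n_samp), n_samp, config$drift_amplitude)

  long <- samples[rep(seq_len(n_samp), each = nm)]
  long[, metabolite_id := rep(metabolites, times = n_samp)]
  j <- rep(seq_len(nm), times = n_samp)
  t_idx <- match(long$timepoint_min, tps)
  m_idx <- match(long$mutant, strains)
  log2_fc_wt <- fc_wt[cbind(j, t_idx)]
  # mutant deviation from WT, zero pre-treatment, growing with g(t)
  extra <- ifelse(long$mutant == "WT", 0,
                  amp_extra[match(long$mutant, mutants)])
  gt <- g[t_idx]
  delta <- effect[cbind(m_idx, j)] * gt + extra * log2_fc_wt

  eps <- stats::rnorm(nrow(long), 0, config$replicate_noise_sd)
  log2_int <- log2(baseline[j]) + log2_fc_wt + delta +
    drift[long$injection_index] +
    config$od_effect_slope * log2(long$od600 / 0.5) +
    eps / log(2)
  long[, intensity := 2^log2_int]

  cols <- c("sample_id", "mutant", "timepoint_min", "replicate",
            "injection_index", "od600", "treatment", "metabolite_id",
            "intensity")
  intensities <- long[, cols, with = FALSE]

  truth <- list(
    classes = stats::setNames(classes, mutants),
    baseline = stats::setNames(baseline, metabolites),
    wt_response_log2 = `dimnames<-`(fc_wt, list(metabolites, as.character(tps))),
    signature = stats::setNames(signature, metabolites),
    effects = effect,
    drift_log2 = drift,
    seed = config$seed,
    config = config
  )
  out <- list(intensities = intensities, annotation = annotation, truth = truth)
  class(out) <- "mg_dataset"
  out
}

#' Generate synthetic growth curves with planted rate and lag
#'
#' Lag-then-exponential kinetics with optional logistic saturation and
#' multiplicative measurement noise:
#' OD(t) = OD0 for t < lag, then logistic growth at specific rate
#' \code{rate_per_h} towards \code{od_max} (pure exponential when
#' \code{od_max = Inf}).
#'
#' @param n_strains number of strains (curves).
#' @param sampling_interval_min sampling interval in minutes.
#' @param duration_h total observation span in hours.
#' @param rate_per_h specific growth rate (1/h); recycled across strains.
#' @param lag_h lag before growth starts (h); recycled across strains.
#' @param od0 starting OD600.
#' @param od_max carrying capacity (OD600); \code{Inf} for pure exponential.
#' @param noise_sd natural-log sd of multiplicative measurement noise.
#' @param seed RNG seed.
#' @return list of class \code{mg_growth_set}: \code{curves} (data.table:
#'   strain, time_h, od600) and \code{truth} (data.table: strain, rate_per_h,
#'   lag_h, od0, od_max).
#' @export
generate_growth_curves <- function(n_strains = 6L,
                                   sampling_interval_min = 5,
                                   duration_h = 12,
                                   rate_per_h = 0.3,
                                   lag_h = 2,
                                   od0 = 0.05,
                                   od_max = 2.0,
                                   noise_sd = 0.02,
                                   seed = 1L) {
  if (sampling_interval_min <= 0) stop("sampling interval must be positive")
  if (any(rate_per_h < 0)) stop("negative growth rate requested")
  if (any(od_max <= od0)) stop("od_max must exceed od0")
  set.seed(seed)
  rate <- rep_len(rate_per_h, n_strains)
  lag <- rep_len(lag_h, n_strains)
  K <- rep_len(od_max, n_strains)
  tt <- seq(0, duration_h, by = sampling_interval_min / 60)
  curves <- data.table::rbindlist(lapply(seq_len(n_strains), function(s) {
    te <- pmax(tt - lag[s], 0)
    od <- if (is.finite(K[s])) {
      K[s] * od0 * exp(rate[s] * te) / (K[s] - od0 + od0 * exp(rate[s] * te))
    } else {
      od0 * exp(rate[s] * te)
    }
    if (noise_sd > 0) od <- od * exp(stats::rnorm(length(od), 0, noise_sd))
    data.table::data.table(strain = sprintf("strain%02d", s),
                           time_h = tt, od600 = od)
  }))
  truth <- data.table::data.table(strain = sprintf("strain%02d",
                                                   seq_len(n_strains)),
                                  rate_per_h = rate, lag_h = lag,
                                  od0 = od0, od_max = K)
  out <- list(curves = curves, truth = truth)
  class(out) <- "mg_growth_set"
  out
}
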