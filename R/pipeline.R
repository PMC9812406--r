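#' Pipeline configuration
#'
#' One flat, JSON-serializable list holding every tunable of the end-to-end
#' analysis. Round-trips bit-exactly through \code{\link{write_pipeline_config}}
#' / \code{\link{read_pipeline_config}} (numbers are serialized at full
#' precision).
#'
#' @param simulation a \code{\link{simulation_config}} (used when no input
#'   paths are given).
#' @param k_mad outlier cutoff in median absolute deviations.
#' @param lowess_span,lowess_iter LOWESS detrending parameters.
#' @param fc_cut,p_cut significance thresholds for change counts.
#' @param summary distance-to-positive-set summary, "median" or "mean".
#' @param target_fpr false-positive rate for the nomination threshold.
#' @param B permutation count for empirical p-values.
#' @param exclude_self drop self coordinates from correlation-profile rows.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param intensities_csv,annotation_csv optional input paths; when NULL the
#'   dataset is simulated from \code{simulation}.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            k_mad = 3,
                            lowess_span = 0.3,
                            lowess_iter = 3L,
                            fc_cut = 0.5,
                            p_cut = 0.05,
                            summary = "median",
                            target_fpr = 0.2,
                            B = 10000L,
                            exclude_self = FALSE,
                            seed = 1L,
                            intensities_csv = NULL,
                            annotation_csv = NULL) {
  cfg <- list(simulation = unclass(simulation), k_mad = k_mad,
              lowess_span = lowess_span, lowess_iter = as.integer(lowess_iter),
              fc_cut = fc_cut, p_cut = p_cut, summary = summary,
              target_fpr = target_fpr, B = as.integer(B),
              exclude_self = exclude_self, seed = as.integer(seed),
              intensities_csv = intensities_csv,
              annotation_csv = annotation_csv)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- do.call(simulation_config, raw$simulation)
  do.call(pipeline_config, c(list(simulation = sim),
                             raw[setdiff(names(raw), "simulation")]))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full guilt-by-association pipeline
#'
#' Executes, in order: data acquisition (simulation or CSV input), outlier
#' filtering, sequential LOWESS detrending (acquisition order, then OD600),
#' fold-change profiles, and per timepoint: correlation matrix, Manhattan
#' distance matrix, Ward tree, distance-to-positive-set scores, permutation
#' p-value, ROC/AUC, and candidate nomination. All artifacts are written to
#' \code{out_dir} as CSV/JSON/Newick, together with the resolved
#' configuration and a summary JSON.
#'
#' Positive regulators are taken from the annotation table rows with class
#' \code{"positive_regulator"}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir artifact directory (created if needed).
#' @return (invisibly) the summary list: per-timepoint auc, empirical
#'   p-value, threshold and candidates, plus seeds and counts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pipeline_config(config, file.path(out_dir, "config.json"))

  if (is.null(config$intensities_csv)) {
    ds <- stage("simulate", {
      sim <- config$simulation
      if (!inherits(sim, "simulation_config")) {
        sim <- do.call(simulation_config, sim)
      }
      generate_dataset(sim)
    })
    intensities <- ds$intensities
    annotation <- ds$annotation
    write_intensity_csv(intensities, file.path(out_dir, "intensities_raw.csv"))
    write_annotation_csv(annotation, file.path(out_dir, "annotation.csv"))
  } else {
    intensities <- stage("read_input", read_intensity_csv(config$intensities_csv))
    if (is.null(config$annotation_csv)) {
      stop("pipeline stage 'read_input' failed: AnnotationTable path ",
           "(annotation_csv) is required when reading intensities from file",
           call. = FALSE)
    }
    annotation <- stage("read_input", read_annotation_csv(config$annotation_csv))
  }
  positives <- annotation$mutant[annotation$class == "positive_regulator"]
  if (length(positives) < 2) {
    stop("pipeline stage 'annotate' failed: AnnotationTable must provide at ",
         "least 2 positive_regulator mutants", call. = FALSE)
  }

  filt <- stage("filter_outliers",
                filter_outlier_samples(intensities, config$k_mad))
  jsonlite::write_json(
    list(excluded = filt$report$excluded, n_retained = filt$report$n_retained,
         k_mad = filt$report$k_mad),
    file.path(out_dir, "outlier_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")

  norm <- stage("detrend", {
    x <- lowess_detrend(filt$intensities, "injection_index",
                        config$lowess_span, config$lowess_iter)
    lowess_detrend(x, "od600", config$lowess_span, config$lowess_iter)
  })
  write_intensity_csv(norm, file.path(out_dir, "intensities_normalized.csv"))

  profiles <- stage("profiles", log2_fold_change_profiles(norm))
  data.table::fwrite(profiles, file.path(out_dir, "profiles.csv"))
  sig <- stage("significance",
               significant_changes(profiles, config$fc_cut, config$p_cut))
  data.table::fwrite(sig$counts, file.path(out_dir, "significant_counts.csv"))

  tps <- sort(unique(profiles$timepoint_min))
  per_tp <- lapply(seq_along(tps), function(i) {
    tp <- tps[i]
    tag <- sprintf("t%03d", as.integer(tp))
    corr <- stage("correlation", correlation_matrix(profiles, tp))
    D <- stage("distance",
               manhattan_distance_matrix(corr, config$exclude_self))
    tree <- stage("cluster", ward_cluster(D))
    write_matrix_csv(corr, file.path(out_dir, paste0("correlation_", tag, ".csv")))
    write_matrix_csv(D, file.path(out_dir, paste0("distance_", tag, ".csv")))
    writeLines(tree_newick(tree), file.path(out_dir, paste0("tree_", tag, ".nwk")))

    pos <- intersect(positives, rownames(D))
    scores <- stage("score", set_distance_scores(D, pos, config$summary))
    perm <- stage("permute",
                  permutation_pvalue(D, pos, config$B,
                                     seed = config$seed + 1000L + i))
    roc <- stage("roc", roc_auc(scores, config$target_fpr))
    nom <- stage("nominate", nominate_candidates(scores, roc))
    sc <- data.table::copy(nom$scores)
    sc[, timepoint_min := tp]
    data.table::fwrite(sc, file.path(out_dir, paste0("scores_", tag, ".csv")))
    data.table::fwrite(roc$points, file.path(out_dir, paste0("roc_", tag, ".csv")))
    list(timepoint_min = tp, auc = roc$auc,
         permutation_p = perm$p_value, observed_cohesion = perm$observed,
         threshold = nom$threshold, candidates = nom$candidates)
  })

  candidates_any <- sort(unique(unlist(lapply(per_tp, `[[`, "candidates"))))
  summary <- list(
    timepoints = lapply(per_tp, function(x) {
      x$candidates <- as.list(x$candidates); x
    }),
    aggregate_candidates = as.list(candidates_any),
    n_mutants = length(unique(intensities$mutant)) - 1L,
    n_metabolites = length(unique(intensities$metabolite_id)),
    positives = as.list(positives),
    summary_statistic = config$summary,
    target_fpr = config$target_fpr,
    B = config$B,
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
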