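#' Read / write pipeline interchange files
#'
#' Tidy-CSV readers and writers for the long-format intensity table, the
#' mutant annotation table, labeled square matrices, and growth curves.
#' All files are plain text so runs are fully reproducible from the artifact
#' directory.
#'
#' @param path file path.
#' @param intensities,annotation,mat,curves objects to write.
#' @name mg_io
NULL

#' @rdname mg_io
#' @export
write_intensity_csv <- function(intensities, path) {
  data.table::fwrite(data.table::as.data.table(intensities), path)
  invisible(path)
}

#' @rdname mg_io
#' @export
read_intensity_csv <- function(path) {
  dt <- data.table::fread(path)
  need <- c("sample_id", "mutant", "timepoint_min", "replicate",
            "injection_index", "od600", "treatment", "metabolite_id",
            "intensity")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("intensity table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(dt$intensity <= 0)) stop("intensity table contains non-positive values")
  if (anyDuplicated(dt[, .(sample_id, metabolite_id)])) {
    stop("duplicate (sample, metabolite) records")
  }
  dt
}

#' @rdname mg_io
#' @export
write_annotation_csv <- function(annotation, path) {
  data.table::fwrite(data.table::as.data.table(annotation), path)
  invisible(path)
}

#' @rdname mg_io
#' @export
read_annotation_csv <- function(path) {
  dt <- data.table::fread(path)
  if (!all(c("mutant", "class") %in% names(dt))) {
    stop("annotation table needs columns: mutant, class")
  }
  if (anyDuplicated(dt$mutant)) stop("duplicated mutants in annotation")
  dt
}

#' @rdname mg_io
#' @export
write_matrix_csv <- function(mat, path) {
  df <- data.table::as.data.table(as.matrix(mat), keep.rownames = "mutant")
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname mg_io
#' @export
read_matrix_csv <- function(path) {
  dt <- data.table::fread(path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' @rdname mg_io
#' @param profiles an \code{mg_profiles} table.
#' @param wide write metabolites x (mutant, timepoint) fold-change columns
#'   instead of the tidy long format.
#' @export
write_profiles_csv <- function(profiles, path, wide = FALSE) {
  dt <- data.table::as.data.table(profiles)
  if (wide) {
    dt <- data.table::dcast(dt, metabolite_id ~ mutant + timepoint_min,
                            value.var = "mean_log2_fc")
  }
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname mg_io
#' @export
write_growth_csv <- function(curves, path) {
  data.table::fwrite(data.table::as.data.table(curves)[,
    .(time_h, od600, strain)], path)
  invisible(path)
}
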