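#' Mutant x mutant Pearson correlation matrix at one timepoint
#'
#' Correlates every pair of mutants' log2 fold-change profiles over the
#' metabolites non-missing in both (pairwise-complete Pearson). Mutants with
#' zero-variance or all-missing profiles are dropped with a warning.
#'
#' @param profiles an \code{mg_profiles} table
#'   (\code{\link{log2_fold_change_profiles}}).
#' @param timepoint timepoint (minutes) to use.
#' @param min_shared minimum shared metabolites required per pair.
#' @return square correlation matrix (mutants x mutants) with attributes
#'   \code{timepoint_min} and \code{metabolites}.
#' @export
correlation_matrix <- function(profiles, timepoint, min_shared = 3L) {
  dt <- data.table::as.data.table(profiles)
  sub <- dt[timepoint_min == timepoint]
  if (nrow(sub) == 0) stop("no profiles at timepoint ", timepoint)
  wide <- data.table::dcast(sub, metabolite_id ~ mutant,
                            value.var = "mean_log2_fc")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$metabolite_id

  sdv <- apply(mat, 2, stats::sd, na.rm = TRUE)
  bad <- is.na(sdv) | sdv == 0
  if (any(bad)) {
    warning("dropping mutants with undefined correlations: ",
            paste(colnames(mat)[bad], collapse = ", "))
    mat <- mat[, !bad, drop = FALSE]
  }
  ok <- !is.na(mat)
  shared <- crossprod(ok)
  if (min(shared) < min_shared) {
    stop("some mutant pairs share fewer than ", min_shared, " metabolites")
  }
  r <- stats::cor(mat, use = "pairwise.complete.obs")
  diag(r) <- 1
  attr(r, "timepoint_min") <- timepoint
  attr(r, "metabolites") <- rownames(mat)
  r
}

#' Manhattan distances between correlation profiles
#'
#' Each mutant's correlation profile is its row of the correlation matrix;
#' the distance between two mutants is the sum of absolute differences of
#' their rows. By default the full rows enter the sum (including the unit
#' diagonal and the pair's mutual entries); \code{exclude_self = TRUE} drops
#' the two coordinates belonging to the pair itself.
#'
#' @param corr square correlation matrix from
#'   \code{\link{correlation_matrix}}.
#' @param exclude_self drop the pair's own coordinates from the sum.
#' @return symmetric distance matrix with zero diagonal; carries the
#'   \code{timepoint_min} attribute through.
#' @export
manhattan_distance_matrix <- function(corr, exclude_self = FALSE) {
  if (anyNA(corr)) stop("correlation matrix contains missing values")
  D <- as.matrix(stats::dist(corr, method = "manhattan"))
  if (exclude_self) {
    # coordinates a and b of the pair: |r[a,a]-r[b,a]| + |r[a,b]-r[b,b]|
    adj <- abs(1 - t(corr)) + abs(1 - corr)
    D <- D - adj
    diag(D) <- 0
    D[D < 0] <- 0   # numerical guard
  }
  dimnames(D) <- dimnames(corr)
  attr(D, "timepoint_min") <- attr(corr, "timepoint_min")
  D
}

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering by Lance-Williams updates with Ward's
#' coefficients applied directly to the supplied dissimilarities
#' (the classical \code{ward.D} scheme; the input is not squared). Ties at
#' the minimal dissimilarity are broken by the lexicographically smallest
#' pair of cluster labels, where a cluster is labelled by its
#' lexicographically smallest leaf, which makes the merge sequence invariant
#' to leaf input order.
#'
#' Note: Ward's criterion assumes squared Euclidean input; applying it to
#' Manhattan distances between correlation profiles is a deliberate,
#' documented convention of this pipeline, not a geometric guarantee.
#'
#' @param dist symmetric dissimilarity matrix with zero diagonal and row
#'   names.
#' @return an object of class \code{c("mg_tree", "hclust")} (standard
#'   \code{merge}/\code{height}/\code{order}/\code{labels} slots).
#' @export
ward_cluster <- function(dist) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 leaves")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("dissimilarity matrix must be symmetric")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  size <- rep(1L, n)
  id <- -seq_len(n)                 # hclust convention: negative = leaf
  rep_label <- labels               # lexicographically smallest member
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  members <- as.list(seq_len(n))    # leaf indices, for the order slot
  work <- D
  diag(work) <- Inf
  work[!active, ] <- Inf

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- work[idx, idx, drop = FALSE]
    mn <- min(sub)
    hits <- which(sub == mn, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # lexicographic tie-break on (sorted) representative label pairs
    a_lab <- rep_label[idx[hits[, 1]]]
    b_lab <- rep_label[idx[hits[, 2]]]
    lo <- pmin(a_lab, b_lab); hi <- pmax(a_lab, b_lab)
    pick <- order(lo, hi)[1]
    i <- idx[hits[pick, 1]]; j <- idx[hits[pick, 2]]

    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- mn
    # Lance-Williams Ward update for every other active cluster k:
    # d(ij,k) = ((n_i+n_k) d_ik + (n_j+n_k) d_jk - n_k d_ij) / (n_i+n_j+n_k)
    k <- setdiff(which(active), c(i, j))
    if (length(k)) {
      nk <- size[k]
      dnew <- ((size[i] + nk) * work[i, k] + (size[j] + nk) * work[j, k] -
                 nk * mn) / (size[i] + size[j] + nk)
      work[i, k] <- dnew
      work[k, i] <- dnew
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    rep_label[i] <- min(rep_label[i], rep_label[j])
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    work[j, ] <- Inf
    work[, j] <- Inf
  }

  order_leaves <- function(node) {
    if (node < 0) return(-node)
    c(order_leaves(merge[node, 1]), order_leaves(merge[node, 2]))
  }
  tree <- list(merge = merge, height = height,
               order = order_leaves(n - 1L), labels = labels,
               method = "ward.D", call = match.call(),
               dist.method = "manhattan")
  class(tree) <- c("mg_tree", "hclust")
  tree
}

#' Export a cluster tree as a Newick string
#'
#' Branch lengths place each node at its merge height (leaves at height 0).
#'
#' @param tree an \code{mg_tree}/\code{hclust} object.
#' @return single-element character vector (Newick, semicolon-terminated).
#' @export
tree_newick <- function(tree) {
  merge <- tree$merge; height <- tree$height; labels <- tree$labels
  node_h <- function(node) if (node < 0) 0 else height[node]
  render <- function(node) {
    if (node < 0) return(labels[-node])
    h <- height[node]
    kids <- vapply(merge[node, ], function(ch) {
      sprintf("%s:%g", render(ch), h - node_h(ch))
    }, character(1))
    sprintf("(%s)", paste(kids, collapse = ","))
  }
  paste0(render(nrow(merge)), ";")
}

#' Compare metabolome distances with an external pairwise score table
#'
#' Matches unordered mutant pairs of the distance matrix against an external
#' table of pairwise scores (e.g. genetic-interaction scores) and reports
#' Pearson and Spearman correlations with p-values.
#'
#' @param dist distance matrix with dimnames.
#' @param pair_scores data.frame with columns \code{mutant1},
#'   \code{mutant2}, \code{score}.
#' @return list: n, pearson_r, pearson_p, spearman_rho, spearman_p.
#' @export
compare_to_external_scores <- function(dist, pair_scores) {
  ps <- as.data.frame(pair_scores)
  stopifnot(all(c("mutant1", "mutant2", "score") %in% names(ps)))
  lbl <- rownames(dist)
  keep <- ps$mutant1 %in% lbl & ps$mutant2 %in% lbl & ps$mutant1 != ps$mutant2
  ps <- ps[keep, ]
  if (nrow(ps) < 3) stop("fewer than 3 overlapping mutant pairs")
  d <- dist[cbind(ps$mutant1, ps$mutant2)]
  pear <- stats::cor.test(d, ps$score, method = "pearson")
  spea <- suppressWarnings(stats::cor.test(d, ps$score, method = "spearman"))
  list(n = nrow(ps),
       pearson_r = unname(pear$estimate), pearson_p = pear$p.value,
       spearman_rho = unname(spea$estimate), spearman_p = spea$p.value)
}
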