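# Independent brute-force oracles; deliberately naive implementations that
# share no code with the package internals.

# Manhattan distance between correlation-profile rows, plain double loop
naive_manhattan <- function(corr, exclude_self = FALSE) {
  n <- nrow(corr)
  D <- matrix(0, n, n, dimnames = dimnames(corr))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      ks <- seq_len(n)
      if (exclude_self) ks <- setdiff(ks, c(a, b))
      D[a, b] <- sum(abs(corr[a, ks] - corr[b, ks]))
    }
  }
  D
}

# step-by-step Lance-Williams Ward agglomeration; clusters tracked as plain
# member lists, minima found by exhaustive scan
naive_ward <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  d <- D
  merges <- list()
  heights <- numeric(0)
  sizes <- rep(1, n)
  alive <- rep(TRUE, n)
  for (s in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    for (i in which(alive)) for (j in which(alive)) {
      if (i < j && d[i, j] < bestd) { bestd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merges[[s]] <- sort(c(clusters[[i]][1], clusters[[j]][1]))
    heights[s] <- bestd
    for (k in which(alive)) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <-
        ((sizes[i] + sizes[k]) * d[i, k] + (sizes[j] + sizes[k]) * d[j, k] -
           sizes[k] * bestd) / (sizes[i] + sizes[j] + sizes[k])
    }
    clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
    sizes[i] <- sizes[i] + sizes[j]
    alive[j] <- FALSE
  }
  list(heights = heights)
}

# AUC by explicit enumeration of all positive-negative pairs, ties one half
brute_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p < q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Spearman correlation as rank-then-Pearson, from first principles
rank_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# random symmetric dissimilarity matrix with zero diagonal
random_dist <- function(n, seed = NULL, labels = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  D <- (m + t(m)) / 2
  diag(D) <- 0
  if (labels) dimnames(D) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  D
}

# small fast simulation config for tests
tiny_config <- function(...) {
  simulation_config(n_metabolites = 30L, n_positive = 4L, n_negative = 4L,
                    n_neutral = 12L, n_replicates = 3L, ...)
}
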