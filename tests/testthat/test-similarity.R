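profiles_from_matrix <- function(fc, timepoint = 30) {
  # fc: metabolites x mutants
  data.table::data.table(
    mutant = rep(colnames(fc), each = nrow(fc)),
    timepoint_min = timepoint,
    metabolite_id = rep(rownames(fc), ncol(fc)),
    mean_log2_fc = as.vector(fc),
    p_value = 0.5, n_mutant_reps = 4L, n_wt_reps = 4L)
}

test_that("correlation_matrix computes pairwise-complete Pearson", {
  x <- c(1, 2, 3, 4)
  fc <- cbind(a = x, b = 2 * x, c = -x, d = c(1, 2, 3, 100))
  rownames(fc) <- paste0("i", 1:4)
  r <- correlation_matrix(profiles_from_matrix(fc), 30)
  expect_equal(r["a", "b"], 1.0)
  expect_equal(r["a", "c"], -1.0)
  # textbook formula evaluated by hand-rolled sums
  y <- fc[, "d"]
  rd <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r["a", "d"], rd, tolerance = 1e-12)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 4))
})

test_that("correlation is invariant under positive affine transforms", {
  set.seed(5)
  fc <- matrix(rnorm(40), 10, 4,
               dimnames = list(paste0("i", 1:10), letters[1:4]))
  r1 <- correlation_matrix(profiles_from_matrix(fc), 30)
  fc2 <- fc; fc2[, "a"] <- 3.7 * fc2[, "a"] + 2
  r2 <- correlation_matrix(profiles_from_matrix(fc2), 30)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("zero-variance mutants are dropped with a warning", {
  fc <- cbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3), flat = rep(1, 4))
  rownames(fc) <- paste0("i", 1:4)
  expect_warning(r <- correlation_matrix(profiles_from_matrix(fc), 30), "flat")
  expect_equal(colnames(r), c("a", "b"))
})

test_that("manhattan distances match the naive double loop", {
  # hand example on explicit rows
  corr <- rbind(c(1, 0, 0.5), c(0, 1, 0.5), c(0.5, 0.5, 1))
  dimnames(corr) <- list(c("a", "b", "c"), c("a", "b", "c"))
  D <- manhattan_distance_matrix(corr)
  expect_equal(D["a", "b"], 2.0)
  expect_equal(unname(diag(D)), rep(0, 3))

  for (s in 1:5) {
    n <- sample(3:20, 1)
    R <- random_dist(max(n, 3), seed = s)  # reuse symmetric generator
    R <- stats::cov2cor(R + n * diag(nrow(R)))
    expect_equal(manhattan_distance_matrix(R), naive_manhattan(R),
                 tolerance = 1e-12)
    expect_equal(manhattan_distance_matrix(R, exclude_self = TRUE),
                 naive_manhattan(R, exclude_self = TRUE), tolerance = 1e-12)
  }
})

test_that("manhattan distances satisfy the triangle inequality", {
  for (s in 1:100) {
    set.seed(s)
    R <- stats::cov2cor(crossprod(matrix(rnorm(100), 10, 10)))
    dimnames(R) <- list(letters[1:10], letters[1:10])
    D <- manhattan_distance_matrix(R)
    # all triples at once: min_k (D[a,k] + D[k,b]) >= D[a,b]
    viol <- 0
    for (k in 1:10) viol <- viol + sum(outer(D[, k], D[k, ], "+") < D - 1e-10)
    expect_equal(viol, 0)
  }
})

test_that("ward_cluster reproduces naive Lance-Williams agglomeration", {
  # two leaves: one merge at the given distance
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- ward_cluster(D2)
  expect_equal(t2$height, 3)
  expect_equal(t2$merge, matrix(c(-2L, -1L), 1))

  # unique minimum merges first
  D3 <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- ward_cluster(D3)
  expect_equal(sort(t3$merge[1, ]), c(-2L, -1L))

  for (s in 1:20) {
    D <- random_dist(6, seed = 100 + s)
    got <- ward_cluster(D)
    ora <- naive_ward(D)
    expect_equal(got$height, ora$heights, tolerance = 1e-12)
  }
})

test_that("ward_cluster agrees with hclust ward.D on tie-free instances", {
  for (s in 1:10) {
    D <- random_dist(12, seed = 200 + s)
    got <- ward_cluster(D)
    ref <- stats::hclust(stats::as.dist(D), method = "ward.D")
    expect_equal(got$height, ref$height, tolerance = 1e-10)
    for (k in c(2, 4, 6)) {
      a <- stats::cutree(got, k)
      b <- stats::cutree(ref, k)
      # same partition up to cluster relabeling
      expect_equal(length(unique(paste(a, b))), k)
    }
  }
})

test_that("ward_cluster partitions are invariant to leaf input order", {
  D <- random_dist(10, seed = 33)
  t1 <- ward_cluster(D)
  perm <- sample(10)
  t2 <- ward_cluster(D[perm, perm])
  expect_equal(t1$height, t2$height, tolerance = 1e-12)
  for (k in c(2, 3, 5)) {
    a <- stats::cutree(t1, k)
    b <- stats::cutree(t2, k)[t1$labels]
    expect_equal(length(unique(paste(a, b))), k)
  }
  expect_error(ward_cluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("tree_newick renders merge heights as branch lengths", {
  D3 <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nwk <- tree_newick(ward_cluster(D3))
  expect_match(nwk, "^\\(.*\\);$")
  expect_match(nwk, "a:1")
  skip_if_not_installed("ape")
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, c("a", "b", "c"))
})

test_that("external score comparison matches rank-based oracles", {
  D <- random_dist(8, seed = 44)
  pairs <- t(combn(rownames(D), 2))
  ps <- data.frame(mutant1 = pairs[, 1], mutant2 = pairs[, 2],
                   score = D[pairs])
  res <- compare_to_external_scores(D, ps)
  expect_equal(res$pearson_r, 1.0, tolerance = 1e-12)
  ps$score <- -ps$score
  expect_equal(compare_to_external_scores(D, ps)$pearson_r, -1.0,
               tolerance = 1e-12)

  set.seed(9)
  ps$score <- rnorm(nrow(ps))
  res2 <- compare_to_external_scores(D, ps)
  expect_equal(res2$spearman_rho, rank_spearman(D[pairs], ps$score),
               tolerance = 1e-12)
  expect_error(compare_to_external_scores(D,
    data.frame(mutant1 = "zz", mutant2 = "yy", score = 1)), "overlapping")
})
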