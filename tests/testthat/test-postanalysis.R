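# construct a gene-block matrix with controlled correlation structure:
# genes in a block share a latent factor, giving within-block |r| ~ w
block_matrix <- function(sizes, n = 27, within = 0.9, between = 0.05,
                         seed = 1) {
  set.seed(seed)
  g <- rnorm(n)
  rows <- list()
  for (b in seq_along(sizes)) {
    f <- rnorm(n)
    for (j in seq_len(sizes[b])) {
      e <- rnorm(n)
      rows[[length(rows) + 1L]] <-
        sqrt(between) * g + sqrt(within - between) * f +
        sqrt(1 - within) * e
    }
  }
  v <- do.call(rbind, rows)
  mat_fix(v, probes = sprintf("gene%02d", seq_len(nrow(v))))
}

test_that("off-diagonal means are exact averages of the triangle", {
  set.seed(61)
  z <- matrix(rnorm(36), 6)
  r <- cov2cor(crossprod(z) / 5)
  vals <- r[upper.tri(r)]
  expect_equal(mean_offdiag(r), sum(vals) / 15)
  expect_error(mean_offdiag(matrix(1, 2, 3)), "square")
})

test_that("correlation t-tests match direct arithmetic", {
  r <- matrix(c(1, 0.445, 0.445, 1), 2)
  sig <- correlation_significance(r, n = 25)
  expect_equal(sig$df, 23)
  expect_equal(sig$p[1, 2], 0.0258, tolerance = 1e-3)
  expect_equal(correlation_significance(matrix(c(1, 0, 0, 1), 2), 25)$p[1, 2],
               1)
  expect_equal(correlation_significance(matrix(c(1, 1, 1, 1), 2), 25)$p[1, 2],
               0)
  expect_error(correlation_significance(r, n = 2), "at least 3")
})

test_that("BH flags are monotone in |r| for fixed n", {
  for (i in 1:10) {
    # mixed structure: one tight 3-gene block plus independent genes, so
    # both significant and non-significant pairs occur
    x <- block_matrix(c(3, 1, 1, 1), within = 0.85, between = 0.02,
                      seed = 600 + i)
    r <- cor(t(x))
    sig <- correlation_significance(r, n = ncol(x))
    up <- upper.tri(r)
    rv <- abs(r[up])
    fl <- sig$significant[up]
    expect_true(any(fl))
    expect_true(any(!fl))
    expect_gt(min(rv[fl]), max(rv[!fl]) - 1e-12)
  }
})

test_that("correlations with and without removals behave as contracts say", {
  x <- block_matrix(c(3, 3), seed = 63)
  rep0 <- correlation_with_without(x, rownames(x))
  expect_identical(rep0$r_reduced, rep0$r_full)
  expect_equal(rep0$n_full, 27L)

  # identical gene rows stay perfectly correlated after any removal
  v <- rbind(a = rnorm(27), b = 0)
  v["b", ] <- v["a", ]
  m <- mat_fix(v, probes = c("a", "b"))
  rep1 <- correlation_with_without(m, c("a", "b"),
                                   removed_samples = colnames(m)[1:2])
  expect_equal(rep1$r_full["a", "b"], 1)
  expect_equal(rep1$r_reduced["a", "b"], 1)
  expect_equal(rep1$n_reduced, 25L)

  flat <- mat_fix(rbind(rep(1, 27), rnorm(27)), probes = c("f", "g"))
  expect_error(correlation_with_without(flat, c("f", "g")), "zero variance")
  expect_error(correlation_with_without(x, rownames(x),
                                        removed_samples = "ghost"), "ghost")
  expect_error(correlation_with_without(x, rownames(x),
                                        removed_samples = colnames(x)[1:25]),
               "fewer than 3")
})

test_that("complete linkage on 1 - |r| merges as constructed", {
  # two genes with known correlation merge at 1 - |r|
  set.seed(64)
  a <- rnorm(40)
  b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(40)
  m <- mat_fix(rbind(a, b), probes = c("gA", "gB"))
  r <- cor(a, b)
  fit <- hierarchical_cluster(m, c("gA", "gB"))
  expect_equal(fit$hclust$height, 1 - abs(r), tolerance = 1e-12)

  # perfect anti-correlation merges at height 0
  m2 <- mat_fix(rbind(a, -a), probes = c("gA", "gB"))
  fit2 <- hierarchical_cluster(m2, c("gA", "gB"))
  expect_equal(fit2$hclust$height, 0, tolerance = 1e-12)

  expect_error(hierarchical_cluster(m, "gA"), "at least 2")
})

test_that("four planted correlation blocks are recovered by the cut", {
  x <- block_matrix(c(6, 3, 2, 3), seed = 65)
  truth <- rep(1:4, c(6, 3, 2, 3))
  names(truth) <- rownames(x)
  fit <- hierarchical_cluster(x, rownames(x))
  expect_true(all(diff(fit$hclust$height) >= -1e-12))  # ultrametric heights
  cut <- cutree(fit$hclust, k = 4)
  # same partition as planted (labels may permute)
  expect_equal(length(unique(paste(cut, truth[names(cut)]))), 4L)
})

test_that("bootstrap support is high for well-separated blocks", {
  x <- block_matrix(c(4, 4), within = 0.95, between = 0.02, seed = 66)
  bs <- bootstrap_support(x, rownames(x), n_boot = 100, seed = 5)
  blocks <- c(paste(sort(rownames(x)[1:4]), collapse = ","),
              paste(sort(rownames(x)[5:8]), collapse = ","))
  got <- bs$nodes$bp[bs$nodes$members %in% blocks]
  expect_equal(length(got), 2L)
  expect_true(all(got >= 0.95))
  # root contains everything in every replicate
  expect_equal(bs$nodes$bp[which.max(nchar(bs$nodes$members))], 1)

  bs2 <- bootstrap_support(x, rownames(x), n_boot = 100, seed = 5)
  expect_identical(bs$nodes, bs2$nodes)
})

test_that("dendrograms export to valid Newick", {
  x <- block_matrix(c(3, 3), seed = 67)
  fit <- hierarchical_cluster(x, rownames(x))
  nwk <- cluster_newick(fit)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(x))
})
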