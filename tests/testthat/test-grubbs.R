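test_that("the Grubbs statistic matches direct arithmetic", {
  expect_error(grubbs_statistic(c(5, 5, 5, 5)), "zero variance")
  expect_error(grubbs_statistic(c(1, 2)), "at least 3")

  r <- grubbs_statistic(c(-1, 0, 1), side = "max")
  expect_equal(r$G, 1)
  expect_equal(r$index, 3L)

  r2 <- grubbs_statistic(c(1, 2, 3, 10), side = "two_sided")
  expect_equal(r2$G, (10 - 4) / sd(c(1, 2, 3, 10)), tolerance = 1e-12)
  expect_equal(r2$G, 1.4697, tolerance = 1e-4)
  expect_equal(r2$index, 4L)

  r3 <- grubbs_statistic(c(10, 3, 2, 1), side = "min")
  expect_equal(r3$index, 4L)
  expect_gt(r3$G, 0)
})

test_that("G is invariant under positive affine transforms", {
  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(sample(4:30, 1))
    a <- rnorm(1, 0, 10)
    b <- runif(1, 0.1, 50)
    for (side in c("max", "min", "two_sided")) {
      g1 <- grubbs_statistic(x, side)
      g2 <- grubbs_statistic(a + b * x, side)
      expect_equal(g1$G, g2$G, tolerance = 1e-10)
      expect_identical(g1$index, g2$index)
    }
  }
})

test_that("critical values agree with t-derived tables to 3 dp", {
  # two-sided 5% reference values as printed in t-quantile-based tables
  expect_equal(round(grubbs_critical(c(5, 10, 20), 0.05, "two"), 3),
               c(1.715, 2.290, 2.708))
  # independent recomputation from the Student-t quantile
  for (n in c(5, 10, 20, 24)) {
    t <- qt(1 - 0.05 / (2 * n), df = n - 2)
    expect_equal(grubbs_critical(n, 0.05, "two"),
                 (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2)),
                 tolerance = 1e-12)
  }
  # n = 3 sits just below the attainable bound (n-1)/sqrt(n)
  g3 <- grubbs_critical(3, 0.05, "two")
  expect_equal(g3, 1.154, tolerance = 5e-4)
  expect_lt(g3, 2 / sqrt(3))
  # analytic bound holds everywhere
  n <- 3:50
  expect_true(all(grubbs_critical(n, 0.05, "one") < (n - 1) / sqrt(n)))
  expect_error(grubbs_critical(2, 0.05), "n >= 3")
  expect_error(grubbs_critical(10, 1.5), "alpha")
})

test_that("sequential scan finds planted extreme sublines in order", {
  sheet <- canonical_sheet()
  inb <- sheet$sample_id[sheet$role == "inbred"]
  set.seed(21)
  base <- matrix(rnorm(3 * 27, 0, 0.3), 3, 27,
                 dimnames = list(c("flat", "one", "two"), sheet$sample_id))
  base["flat", ] <- 5
  base["one", inb[5]] <- -10
  base["two", inb[7]] <- -10
  base["two", inb[11]] <- -9
  m <- expression_matrix(base)

  calls <- sequential_outlier_scan(m, sheet, alpha = 0.05, direction = "down")
  expect_false("flat" %in% calls$probe_id)
  one <- calls[calls$probe_id == "one", ]
  expect_equal(nrow(one), 1L)
  expect_equal(one$sample_id, inb[5])
  expect_equal(one$order, 1L)
  expect_equal(one$n_at_test, 24L)
  two <- calls[calls$probe_id == "two", ]
  expect_equal(two$order, 1:2)
  expect_equal(two$sample_id, inb[c(7, 11)])
  expect_true(all(calls$G >= calls$G_crit))
})

test_that("the scan agrees with an independent per-row oracle", {
  sheet <- canonical_sheet()
  inb <- sheet$sample_id[sheet$role == "inbred"]
  set.seed(31)
  v <- matrix(rnorm(40 * 27, 8, 0.25), 40, 27,
              dimnames = list(sprintf("g%02d", 1:40), sheet$sample_id))
  # salt some rows with shifts of varying size so 0, 1, 2, 3 calls occur
  for (i in 1:15) v[i, inb[seq_len(i %% 3 + 1)]] <- v[i, inb[seq_len(i %% 3 + 1)]] - (i %% 5)
  m <- expression_matrix(v)
  for (dir in c("down", "up")) {
    calls <- sequential_outlier_scan(m, sheet, alpha = 0.05,
                                     max_outliers = 3, direction = dir)
    for (g in rownames(v)) {
      ora <- oracle_seq_scan(v[g, inb], 0.05, 3, dir)
      got <- calls[calls$probe_id == g, ]
      expect_equal(nrow(got), length(ora), info = paste(g, dir))
      if (length(ora)) {
        expect_equal(got$sample_id,
                     inb[vapply(ora, `[[`, numeric(1), "index")])
        expect_equal(got$G, vapply(ora, `[[`, numeric(1), "G"),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("a single-step scan equals the one-shot Grubbs test", {
  set.seed(41)
  v <- matrix(rnorm(30 * 10), 30, 10)
  m <- mat_fix(v)
  calls <- sequential_outlier_scan(m, alpha = 0.1, max_outliers = 1,
                                   direction = "up")
  for (i in seq_len(nrow(v))) {
    g <- grubbs_statistic(v[i, ], "max")
    crit <- grubbs_critical(10, 0.1, "one")
    in_calls <- rownames(m)[i] %in% calls$probe_id
    expect_equal(in_calls, g$G >= crit)
    if (in_calls)
      expect_equal(calls$sample_id[calls$probe_id == rownames(m)[i]],
                   colnames(m)[g$index])
  }
})

test_that("call sets are nested across decreasing alpha", {
  sim <- simulate_expression(sim_config(n_probes = 600, seed = 5))
  keys <- lapply(c(0.1, 0.05, 0.01), function(a)
    call_key(sequential_outlier_scan(sim$matrix, sim$sheet, alpha = a,
                                     direction = "down")))
  expect_true(all(keys[[3]] %in% keys[[2]]))
  expect_true(all(keys[[2]] %in% keys[[1]]))
  expect_lt(length(keys[[3]]), length(keys[[1]]))
})

test_that("eligibility is inbred-only by default and checked for size", {
  sheet <- canonical_sheet()
  set.seed(51)
  m <- expression_matrix(matrix(rnorm(2 * 27), 2, 27,
                                dimnames = list(c("g1", "g2"),
                                                sheet$sample_id)))
  calls <- sequential_outlier_scan(m, sheet, alpha = 0.5, direction = "down")
  expect_true(all(calls$sample_id %in%
                    sheet$sample_id[sheet$role == "inbred"]))
  expect_error(
    sequential_outlier_scan(m, eligible_samples = sheet$sample_id[1:4],
                            alpha = 0.05, max_outliers = 3),
    "too few eligible")
  expect_error(
    sequential_outlier_scan(m, eligible_samples = c("nope", sheet$sample_id),
                            alpha = 0.05),
    "not a matrix column")
})
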