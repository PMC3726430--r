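mk_calls <- function(samples, probe = "p1", direction = "down",
                     alpha = 0.05) {
  data.frame(probe_id = probe, sample_id = samples, direction = direction,
             order = seq_along(samples), G = 5, G_crit = 2, alpha = alpha,
             n_at_test = 24L - seq_along(samples) + 1L,
             stringsAsFactors = FALSE)
}

test_that("SL-LD classification needs coincident line and level", {
  sheet <- canonical_sheet()
  hit <- classify_slld(mk_calls(c("b_most_1", "b_most_2")), sheet, 2)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$line, "b")
  expect_equal(hit$level, "most_depressed")
  expect_equal(hit$n_outliers, 2L)

  expect_equal(nrow(classify_slld(mk_calls(c("b_most_1", "c_most_1")),
                                  sheet, 2)), 0L)
  expect_equal(nrow(classify_slld(mk_calls(c("b_most_1", "b_least_1")),
                                  sheet, 2)), 0L)
  # a control among the top outliers can never be SL-LD
  expect_equal(nrow(classify_slld(mk_calls(c("b_most_1", "control_1")),
                                  sheet, 2)), 0L)
  # three-outlier classification
  hit3 <- classify_slld(mk_calls(c("d_least_1", "d_least_2", "d_least_3")),
                        sheet, 3)
  expect_equal(hit3$level, "least_depressed")
})

test_that("at_least vs exactly matching controls eligibility", {
  sheet <- canonical_sheet()
  calls3 <- mk_calls(c("a_most_1", "a_most_2", "b_least_1"))
  # first two calls share a cell; the third is elsewhere
  expect_equal(nrow(classify_slld(calls3, sheet, 2, match = "at_least")), 1L)
  expect_equal(nrow(classify_slld(calls3, sheet, 2, match = "exactly")), 0L)
})

test_that("classification validates its inputs", {
  sheet <- canonical_sheet()
  expect_error(classify_slld(mk_calls(c("b_most_1", "ghost")), sheet, 2),
               "ghost")
  mixed <- rbind(mk_calls("b_most_1", alpha = 0.05),
                 mk_calls("b_most_2", probe = "p2", alpha = 0.1))
  expect_error(classify_slld(mixed, sheet, 2), "single alpha")
})

test_that("toy 2x2x2 randomization converges to the exact 1/7", {
  sheet <- toy_sheet_222()
  calls <- mk_calls(c("s1", "s2"))   # both outliers in cell (a, most)
  rt <- randomization_test(calls, sheet, n_outliers = 2,
                           n_replicates = 10000, seed = 7)
  # second outlier lands in the first's 2-subline cell w.p. 1/7
  mc_sd <- sqrt((1 / 7) * (6 / 7) / 10000)
  expect_lt(abs(rt$expected_mean - 1 / 7), 3 * mc_sd)
  expect_lt(abs(rt$p_total - 1 / 7), 3 * mc_sd)
  expect_equal(rt$observed_total, 1L)
})

test_that("no eligible probes gives observed 0 and p = 1", {
  sheet <- canonical_sheet()
  rt <- randomization_test(mk_calls("b_most_1"), sheet, n_outliers = 2,
                           n_replicates = 200, seed = 1)
  expect_equal(rt$observed_total, 0L)
  expect_equal(rt$p_total, 1)
  expect_equal(sum(rt$observed_by_level), 0L)
})

test_that("randomization is reproducible and design-validated", {
  sheet <- canonical_sheet()
  calls <- rbind(mk_calls(c("b_most_1", "b_most_2")),
                 mk_calls(c("a_least_1", "c_most_3"), probe = "p2"))
  a <- randomization_test(calls, sheet, 2, n_replicates = 500, seed = 99)
  b <- randomization_test(calls, sheet, 2, n_replicates = 500, seed = 99)
  expect_identical(a[c("p_total", "p_most_only", "expected_mean")],
                   b[c("p_total", "p_most_only", "expected_mean")])
  # a design with 1-subline cells cannot be shuffled meaningfully
  thin <- sample_sheet(data.frame(
    sample_id = paste0("t", 1:4), role = "inbred",
    line = c("a", "a", "b", "b"),
    level = rep(c("most_depressed", "least_depressed"), 2),
    subline_index = 1L))
  expect_error(randomization_test(calls, thin, 2), "at least 2 sublines")
})

test_that("null simulations are self-consistent with the shuffle null", {
  # equal group variances make the (line, level) codes exchangeable, the
  # regime in which the shuffle test's expectation is exact
  sim <- simulate_expression(
    sim_config(planted = default_planted()[0, ], var_control = 0.044,
               var_least = 0.044, var_most = 0.044, seed = 77))
  calls <- sequential_outlier_scan(sim$matrix, sim$sheet, alpha = 0.05,
                                   direction = "down")
  rt <- randomization_test(calls, sim$sheet, 2, n_replicates = 2000,
                           seed = 78)
  expect_lt(abs(rt$observed_total - rt$expected_mean), 3 * rt$expected_sd)
  # permutation symmetry of the two depression levels under the null
  expect_lt(abs(rt$mean_by_level[["most_depressed"]] -
                  rt$mean_by_level[["least_depressed"]]),
            0.1 * rt$expected_mean)
  expect_equal(rt$expected_by_level, rt$expected_mean / 2)
})

test_that("SL-LD counts are bounded by eligible probes everywhere", {
  sim <- simulate_expression(sim_config(n_probes = 1500, seed = 13))
  lad <- alpha_ladder(sim$matrix, sim$sheet, alphas = c(0.1, 0.05, 0.01),
                      n_replicates = 200, seed = 3)
  expect_true(all(lad$observed_total <= lad$n_probes_with_outliers))
  expect_true(all(lad$observed_most + lad$observed_least ==
                    lad$observed_total))
  expect_true(all(lad$p_total >= 0 & lad$p_total <= 1))
  # counts weakly decrease as alpha decreases, per direction
  for (d in unique(lad$direction)) {
    sub <- lad[lad$direction == d, ]
    expect_true(all(order(sub$alpha, decreasing = TRUE) == seq_len(nrow(sub))))
    expect_true(all(diff(sub$n_probes_with_outliers) <= 0))
    expect_true(all(diff(sub$observed_total) <= 0))
  }
})

test_that("planted line-specific effects surface as down/most SL-LD", {
  sim <- simulate_expression(sim_config(seed = 3))
  calls <- sequential_outlier_scan(sim$matrix, sim$sheet, alpha = 0.05,
                                   direction = "down")
  sl <- classify_slld(calls, sim$sheet, 2)
  hits <- sl[sl$level == "most_depressed", ]
  recovered <- intersect(hits$probe_id, sim$truth$probe_id)
  expect_gte(length(recovered), 0.8 * nrow(sim$truth))
  # recovered calls sit in the planted line
  tr <- sim$truth[match(recovered, sim$truth$probe_id), ]
  expect_equal(hits$line[match(recovered, hits$probe_id)], tr$line)
  rt <- randomization_test(calls, sim$sheet, 2, n_replicates = 2000,
                           seed = 4)
  expect_lt(rt$p_total, 0.05)
  expect_lt(rt$p_most_only, 0.05)
})
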