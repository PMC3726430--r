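# SL-LD classification and the code-shuffling randomization test.
#
# A probe is a single line-level of depression (SL-LD) outlier when its
# detected outlier sublines all belong to one inbred line AND one
# depression level. Significance of the SL-LD count comes from shuffling
# the (line, level) codes of the inbred sublines while keeping every
# probe's outlier identities fixed, so the correlation structure across
# probes is conserved (the Westfall-Young rationale). Controls are never
# randomized.

.cell_codes <- function(sheet) {
  inb <- sheet[sheet$role == "inbred", , drop = FALSE]
  cell <- paste(inb$line, inb$level, sep = "|")
  ucell <- unique(cell)
  list(sample_id = inb$sample_id,
       code = match(cell, ucell),
       cell = ucell,
       cell_level = sub("^.*\\|", "", ucell))
}

.top_outlier_sets <- function(calls, n_outliers, match_mode) {
  if (!nrow(calls))
    return(list(probe_id = character(),
                S = matrix(character(), 0, n_outliers)))
  cnt <- table(factor(calls$probe_id, levels = unique(calls$probe_id)))
  ok <- if (match_mode == "exactly") names(cnt)[cnt == n_outliers]
    else names(cnt)[cnt >= n_outliers]
  top <- calls[calls$probe_id %in% ok & calls$order <= n_outliers, ,
               drop = FALSE]
  top <- top[order(match(top$probe_id, ok), top$order), ]
  S <- matrix(top$sample_id, ncol = n_outliers, byrow = TRUE)
  list(probe_id = ok, S = S)
}

#' Classify SL-LD outlier probes
#'
#' A probe qualifies when it has `n_outliers` outlier calls (at least that
#' many by default, exactly that many with `match = "exactly"`) and the
#' calls of order 1..`n_outliers` all fall in sublines of one (line, level)
#' cell.
#'
#' @param calls outlier calls from [sequential_outlier_scan()], produced at
#'   a single alpha and direction.
#' @param sheet the [sample_sheet()].
#' @param n_outliers number of coincident outliers required (2 or 3).
#' @param match `"at_least"` (default: probes with more calls remain
#'   eligible, judged on their first `n_outliers`) or `"exactly"`.
#' @return data.frame of SL-LD calls: `probe_id`, `line`, `level`,
#'   `direction`, `n_outliers`, `alpha`.
#' @export
classify_slld <- function(calls, sheet, n_outliers = 2L,
                          match = c("at_least", "exactly")) {
  match <- match.arg(match)
  if (!n_outliers %in% 2:3)
    stop("n_outliers must be 2 or 3")
  empty <- data.frame(probe_id = character(), line = character(),
                      level = character(), direction = character(),
                      n_outliers = integer(), alpha = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(calls)) return(empty)
  if (length(unique(calls$alpha)) > 1L || length(unique(calls$direction)) > 1L)
    stop("calls must come from a single alpha and a single direction")
  unknown <- setdiff(calls$sample_id, sheet$sample_id)
  if (length(unknown))
    stop(sprintf("outlier call references sample '%s' absent from sheet",
                 unknown[1L]))
  sets <- .top_outlier_sets(calls, n_outliers, match)
  if (!length(sets$probe_id)) return(empty)
  line_of <- setNames(sheet$line, sheet$sample_id)
  level_of <- setNames(sheet$level, sheet$sample_id)
  role_of <- setNames(sheet$role, sheet$sample_id)
  L <- matrix(line_of[sets$S], nrow = nrow(sets$S))
  V <- matrix(level_of[sets$S], nrow = nrow(sets$S))
  R <- matrix(role_of[sets$S], nrow = nrow(sets$S))
  same <- function(m) apply(m, 1L, function(r) !anyNA(r) && all(r == r[1L]))
  hit <- same(L) & same(V) & apply(R == "inbred", 1L, all)
  if (!any(hit)) return(empty)
  data.frame(probe_id = sets$probe_id[hit],
             line = L[hit, 1L],
             level = V[hit, 1L],
             direction = calls$direction[1L],
             n_outliers = as.integer(n_outliers),
             alpha = calls$alpha[1L],
             stringsAsFactors = FALSE)
}

#' Randomization significance test for the SL-LD count
#'
#' Holds every probe's detected outlier sublines fixed and, in each
#' replicate, assigns the (line, level) codes of the inbred sublines by a
#' uniform random permutation (controls are not randomized), then recounts
#' how many probes are SL-LD under the shuffled codes. Because the codes --
#' never the expression values -- are shuffled, and identically for all
#' probes, the between-probe correlation of the outlier list is conserved.
#'
#' `p_total` is the proportion of replicates with a count at least the
#' observed total. `p_most_only` compares the count observed in
#' most-depressed cells against the replicate distribution of the total
#' count (conservative by construction); the alternative reading
#' `most_comparison = "half"` compares it against half the replicate total.
#' The reading used is recorded in the result.
#'
#' @inheritParams classify_slld
#' @param n_replicates number of random permutations.
#' @param seed integer seed; identical seeds give identical p-values.
#' @param most_comparison `"total"` (default) or `"half"`, see above.
#' @param plus_one use the (count + 1)/(replicates + 1) small-sample
#'   correction (off by default: p-values are plain replicate proportions).
#' @return an object of class `randomization_result`: observed totals and
#'   per-level counts, `expected_mean` (mean replicate count),
#'   `p_total`, `p_most_only`, replicate bookkeeping and the seed.
#' @export
randomization_test <- function(calls, sheet, n_outliers = 2L,
                               n_replicates = 10000L, seed = 1L,
                               match = c("at_least", "exactly"),
                               most_comparison = c("total", "half"),
                               plus_one = FALSE) {
  match <- match.arg(match)
  most_comparison <- match.arg(most_comparison)
  cc <- .cell_codes(sheet)
  cell_sizes <- tabulate(cc$code, nbins = length(cc$cell))
  if (any(cell_sizes < n_outliers))
    stop(sprintf("every (line, level) cell needs at least %d sublines",
                 n_outliers))
  direction <- if (nrow(calls)) calls$direction[1L] else NA_character_
  alpha <- if (nrow(calls)) calls$alpha[1L] else NA_real_
  sets <- .top_outlier_sets(calls, n_outliers, match)
  # probes whose top outliers include a non-inbred sample can never be
  # SL-LD under any labelling; drop them from the matching set
  inbred_only <- apply(matrix(sets$S %in% cc$sample_id,
                              nrow = nrow(sets$S)), 1L, all)
  S <- matrix(match(sets$S, cc$sample_id),
              nrow = nrow(sets$S))[inbred_only, , drop = FALSE]
  m <- nrow(S)
  n_inb <- length(cc$sample_id)
  count_match <- function(code) {
    if (!m) return(list(total = 0L, most = 0L, least = 0L))
    c1 <- code[S[, 1L]]
    eq <- c1 == code[S[, 2L]]
    if (ncol(S) >= 3L) eq <- eq & c1 == code[S[, 3L]]
    lev <- cc$cell_level[c1[eq]]
    list(total = sum(eq),
         most = sum(lev == "most_depressed"),
         least = sum(lev == "least_depressed"))
  }
  obs <- count_match(cc$code)
  cnt <- cnt_most <- cnt_least <- integer(n_replicates)
  set.seed(as.integer(seed))
  for (r in seq_len(n_replicates)) {
    code <- cc$code[sample.int(n_inb)]
    z <- count_match(code)
    cnt[r] <- z$total
    cnt_most[r] <- z$most
    cnt_least[r] <- z$least
  }
  prop <- function(k) if (plus_one) (k + 1) / (n_replicates + 1)
    else k / n_replicates
  p_total <- prop(sum(cnt >= obs$total))
  p_most <- if (most_comparison == "total")
    prop(sum(cnt >= obs$most)) else prop(sum(cnt / 2 >= obs$most))
  structure(list(
    direction = direction,
    alpha = alpha,
    n_outliers = as.integer(n_outliers),
    n_probes_tested = m,
    observed_total = obs$total,
    observed_by_level = c(most_depressed = obs$most,
                          least_depressed = obs$least),
    expected_mean = mean(cnt),
    expected_sd = sd(cnt),
    expected_by_level = mean(cnt) / 2,
    mean_by_level = c(most_depressed = mean(cnt_most),
                      least_depressed = mean(cnt_least)),
    p_total = p_total,
    p_most_only = p_most,
    most_comparison = most_comparison,
    match = match,
    plus_one = plus_one,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)),
    class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "SL-LD randomization test (%s-regulation, %d outliers, alpha = %s)\n",
    x$direction, x$n_outliers, format(x$alpha)))
  cat(sprintf("  probes with %d outliers tested: %d\n", x$n_outliers,
              x$n_probes_tested))
  cat(sprintf("  observed SL-LD: %d (most %d / least %d); expected %.3f\n",
              x$observed_total, x$observed_by_level[["most_depressed"]],
              x$observed_by_level[["least_depressed"]], x$expected_mean))
  cat(sprintf("  p_total = %.4g, p_most_only = %.4g (%d replicates)\n",
              x$p_total, x$p_most_only, x$n_replicates))
  invisible(x)
}

#' Alpha-ladder summary of SL-LD counts
#'
#' Repeats scan, SL-LD classification and randomization over a descending
#' ladder of Grubbs test levels and both regulation directions -- the
#' machine-readable equivalent of the observed-vs-expected bar summary of
#' the study design.
#'
#' @param x probe-by-sample expression matrix.
#' @param sheet the [sample_sheet()].
#' @param alphas descending vector of Grubbs levels.
#' @param n_outliers coincident outliers required (2 or 3).
#' @param directions directions to scan.
#' @param n_replicates randomization replicates per cell.
#' @param seed integer seed (each ladder cell uses a distinct derived seed).
#' @param max_outliers passed to [sequential_outlier_scan()].
#' @param ... further arguments to [randomization_test()].
#' @return data.frame with one row per (alpha, direction): probes carrying
#'   `n_outliers` calls, observed SL-LD totals split by level, expected
#'   mean and both empirical p-values.
#' @export
alpha_ladder <- function(x, sheet, alphas = c(0.10, 0.05, 0.025, 0.01),
                         n_outliers = 2L, directions = c("down", "up"),
                         n_replicates = 10000L, seed = 1L,
                         max_outliers = 3L, ...) {
  alphas <- sort(alphas, decreasing = TRUE)
  rows <- list()
  i <- 0L
  for (dir in directions) {
    for (a in alphas) {
      i <- i + 1L
      calls <- sequential_outlier_scan(x, sheet, alpha = a,
                                       max_outliers = max_outliers,
                                       direction = dir)
      rt <- randomization_test(calls, sheet, n_outliers = n_outliers,
                               n_replicates = n_replicates,
                               seed = seed + i, ...)
      rows[[i]] <- data.frame(
        alpha = a,
        direction = dir,
        n_probes_with_outliers = rt$n_probes_tested,
        observed_total = rt$observed_total,
        observed_most = rt$observed_by_level[["most_depressed"]],
        observed_least = rt$observed_by_level[["least_depressed"]],
        expected_mean = rt$expected_mean,
        p_total = rt$p_total,
        p_most_only = rt$p_most_only,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
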