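# Synthetic data with the statistical structure the analysis assumes:
# Gaussian log2 expression with group-specific within-line variances,
# optional block-exchangeable correlation between probes, planted
# line-specific down-regulation in most-depressed sublines, and a
# productivity table whose control/inbred means match the study's printed
# values.

#' Default planted-effect table
#'
#' Fourteen down-regulated probes distributed over most-depressed cells as
#' 6/3/2/3 across lines b, c, d and a -- the headline candidate pattern.
#' Each line's planted probes start at the beginning of a distinct
#' correlation block so planted probes of one line are mutually correlated
#' (like co-regulated genes) but independent of other lines' probes.
#'
#' @param delta additive log2 shift (negative = down-regulation).
#' @param n_affected affected sublines per planted probe (2 exercises the
#'   two-outlier SL-LD case; 3 shifts the whole cell).
#' @param block_size probe correlation-block size used to space the groups.
#' @return data.frame with columns `probe`, `line`, `level`, `direction`,
#'   `delta`, `n_affected`.
#' @export
default_planted <- function(delta = -2.0, n_affected = 2L, block_size = 50L) {
  counts <- c(b = 6L, c = 3L, d = 2L, a = 3L)
  starts <- (seq_along(counts) - 1L) * block_size + 1L
  data.frame(
    probe = unlist(Map(function(s, k) seq(s, length.out = k),
                       starts, counts), use.names = FALSE),
    line = rep(names(counts), counts),
    level = "most_depressed",
    direction = ifelse(delta < 0, "down", "up"),
    delta = delta,
    n_affected = as.integer(n_affected),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults emulate the analysed study design: 4 inbred lines x 2
#' depression levels x 3 sublines plus 3 outbred controls (27 arrays),
#' 9000 probes, within-line variances 0.028 (controls), 0.044 (least
#' depressed) and 0.086 (most depressed) on the log2 scale, probes
#' correlated in exchangeable blocks, and 14 planted down-regulated probes
#' in most-depressed cells. Productivity defaults reproduce the printed
#' control and inbred means (W_O = 101.97, W_I = 34.28).
#'
#' @param n_probes number of probe sets.
#' @param lines inbred line labels.
#' @param sublines_per_cell sublines per (line, level) cell.
#' @param n_controls outbred control arrays.
#' @param baseline_mean,baseline_sd per-probe baseline log2 expression
#'   distribution.
#' @param var_control,var_least,var_most within-line expression variances
#'   by sample group.
#' @param block_size,block_rho probes are correlated in consecutive blocks
#'   of `block_size` with exchangeable correlation `block_rho`
#'   (`block_rho = 0` disables).
#' @param planted data.frame as returned by [default_planted()]; use a
#'   zero-row frame for pure null data.
#' @param w_o,w_i control and inbred mean productivities.
#' @param subline_sd spread of subline mean productivities around `w_i`.
#' @param productivity_cv replicate coefficient of variation.
#' @param n_sublines_per_line sublines per line in the productivity table.
#' @param n_control_vials replicate control vials.
#' @param n_replicates_per_subline replicate vials per subline.
#' @param seed integer seed; all outputs are deterministic given the seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 9000L,
                       lines = c("a", "b", "c", "d"),
                       sublines_per_cell = 3L,
                       n_controls = 3L,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       var_control = 0.028,
                       var_least = 0.044,
                       var_most = 0.086,
                       block_size = 50L,
                       block_rho = 0.3,
                       planted = default_planted(block_size = block_size),
                       w_o = 101.97,
                       w_i = 34.28,
                       subline_sd = 15,
                       productivity_cv = 0.10,
                       n_sublines_per_line = 25L,
                       n_control_vials = 70L,
                       n_replicates_per_subline = 3L,
                       seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), lines = lines,
              sublines_per_cell = as.integer(sublines_per_cell),
              n_controls = as.integer(n_controls),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              var_control = var_control, var_least = var_least,
              var_most = var_most, block_size = as.integer(block_size),
              block_rho = block_rho, planted = planted, w_o = w_o,
              w_i = w_i, subline_sd = subline_sd,
              productivity_cv = productivity_cv,
              n_sublines_per_line = as.integer(n_sublines_per_line),
              n_control_vials = as.integer(n_control_vials),
              n_replicates_per_subline = as.integer(n_replicates_per_subline),
              seed = as.integer(seed))
  if (any(c(cfg$var_control, cfg$var_least, cfg$var_most) <= 0))
    stop("within-line variances must be positive")
  if (abs(cfg$block_rho) >= 1)
    stop("block_rho must satisfy |rho| < 1")
  if (nrow(cfg$planted)) {
    p <- cfg$planted
    if (any(p$probe < 1L | p$probe > cfg$n_probes))
      stop("planted probe index out of range")
    if (anyDuplicated(p$probe))
      stop("planted probe indices must be unique")
    if (any(!p$line %in% cfg$lines) || any(!p$level %in% .levels_vocab))
      stop("planted effect references an unknown (line, level) cell")
    if (any(p$delta == 0))
      stop("planted effects need delta != 0")
    if (any(p$n_affected < 1L | p$n_affected > cfg$sublines_per_cell))
      stop("n_affected must lie in 1..sublines_per_cell")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Canonical sample sheet of the simulated design
#'
#' @param config a [sim_config()].
#' @return a [sample_sheet()] with one row per array: all (line, level)
#'   cells with `sublines_per_cell` sublines each, then the controls.
#' @export
sim_sample_sheet <- function(config) {
  cells <- expand.grid(subline = seq_len(config$sublines_per_cell),
                       level = .levels_vocab, line = config$lines,
                       stringsAsFactors = FALSE)
  short <- c(most_depressed = "most", least_depressed = "least")
  inb <- data.frame(
    sample_id = paste(cells$line, short[cells$level], cells$subline,
                      sep = "_"),
    role = "inbred", line = cells$line, level = cells$level,
    subline_index = cells$subline, stringsAsFactors = FALSE)
  ctl <- data.frame(
    sample_id = paste0("control_", seq_len(config$n_controls)),
    role = "control", line = NA_character_, level = NA_character_,
    subline_index = seq_len(config$n_controls), stringsAsFactors = FALSE)
  sample_sheet(rbind(inb, ctl))
}

#' Simulate an expression matrix with planted line-specific effects
#'
#' Null probes are Gaussian on the log2 scale: probe baseline plus noise
#' whose variance is the sample group's within-line variance. Probes in
#' the same block of `block_size` consecutive rows share an exchangeable
#' correlation `block_rho` (one latent factor per block and sample), which
#' makes conserving the correlation structure in the randomization test a
#' non-trivial feature. Planted probes additionally receive the additive
#' shift `delta` in the first `n_affected` sublines of their target
#' (line, level) cell.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (probe-by-sample, see
#'   [expression_matrix()]), `sheet` (the [sample_sheet()]) and `truth`
#'   (data.frame of planted effects with affected sample ids).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sheet <- sim_sample_sheet(config)
  n <- nrow(sheet)
  p <- config$n_probes
  grp_var <- ifelse(sheet$role == "control", config$var_control,
                    ifelse(sheet$level == "most_depressed",
                           config$var_most, config$var_least))
  set.seed(config$seed)
  baseline <- rnorm(p, config$baseline_mean, config$baseline_sd)
  z <- matrix(rnorm(p * n), p, n)
  if (config$block_rho != 0) {
    blk <- ((seq_len(p) - 1L) %/% config$block_size) + 1L
    f <- matrix(rnorm(max(blk) * n), max(blk), n)
    z <- sqrt(config$block_rho) * f[blk, , drop = FALSE] +
      sqrt(1 - config$block_rho) * z
  }
  values <- baseline + sweep(z, 2L, sqrt(grp_var), `*`)
  probe_ids <- sprintf("probe_%05d", seq_len(p))
  rownames(values) <- probe_ids
  colnames(values) <- sheet$sample_id
  truth <- data.frame(probe_id = character(), line = character(),
                      level = character(), direction = character(),
                      delta = numeric(), affected_samples = character(),
                      stringsAsFactors = FALSE)
  if (nrow(config$planted)) {
    pl <- config$planted
    affected <- character(nrow(pl))
    for (i in seq_len(nrow(pl))) {
      cell <- sheet$sample_id[sheet$role == "inbred" &
                                sheet$line == pl$line[i] &
                                sheet$level == pl$level[i]]
      tgt <- cell[seq_len(pl$n_affected[i])]
      values[pl$probe[i], tgt] <- values[pl$probe[i], tgt] + pl$delta[i]
      affected[i] <- paste(tgt, collapse = ",")
    }
    truth <- data.frame(probe_id = probe_ids[pl$probe], line = pl$line,
                        level = pl$level, direction = pl$direction,
                        delta = pl$delta, affected_samples = affected,
                        stringsAsFactors = FALSE)
  }
  list(matrix = expression_matrix(values), sheet = sheet, truth = truth)
}

#' Simulate a productivity table
#'
#' Subline mean productivities are placed at variance-controlled normal
#' quantiles around `w_i` (standardized to mean exactly `w_i` and standard
#' deviation `subline_sd`, then randomly assigned to subline ids), so the
#' per-subline depression rates span roughly the printed study range while
#' the grand inbred mean stays at `w_i`. Replicate vial counts add
#' mean-proportional Gaussian noise (`productivity_cv`), truncated at 0;
#' control vials are drawn around `w_o` the same way.
#'
#' @param config a [sim_config()].
#' @return list with `productivity` (inbred replicate rows: `line`,
#'   `subline_id`, `replicate_id`, `pupae_per_female`) and `control`
#'   (replicate rows `replicate_id`, `pupae_per_female`).
#' @export
simulate_productivity <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 10007L)
  rows <- list()
  for (ln in config$lines) {
    ns <- config$n_sublines_per_line
    q <- qnorm(ppoints(ns))
    dev <- config$subline_sd * (q - mean(q)) / sd(q)
    dev <- dev[sample.int(ns)]             # random assignment to sublines
    means <- pmax(config$w_i + dev, 0.5)
    nr <- config$n_replicates_per_subline
    rows[[ln]] <- data.frame(
      line = ln,
      subline_id = rep(seq_len(ns), each = nr),
      replicate_id = rep(seq_len(nr), ns),
      pupae_per_female = pmax(rnorm(ns * nr, rep(means, each = nr),
                                    config$productivity_cv *
                                      rep(means, each = nr)), 0),
      stringsAsFactors = FALSE)
  }
  control <- data.frame(
    replicate_id = seq_len(config$n_control_vials),
    pupae_per_female = pmax(rnorm(config$n_control_vials, config$w_o,
                                  config$productivity_cv * config$w_o), 0))
  list(productivity = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       control = control)
}
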