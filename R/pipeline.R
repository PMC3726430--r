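# End-to-end orchestration: simulate (or load) -> depression summary ->
# sequential scan -> SL-LD classification -> randomization -> alpha ladder
# -> candidate post-analysis -> report bundle.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with defaults equal to the
#' documented analysis decisions. Either point `matrix_path`/`sheet_path`
#' (and optionally `productivity_path`) at TSV inputs, or leave them NULL
#' to analyse a synthetic data set drawn from `sim`.
#'
#' @param out_dir output directory for the report bundle.
#' @param matrix_path,sheet_path,productivity_path optional TSV inputs.
#' @param sim a [sim_config()] used when no matrix is supplied.
#' @param alphas descending Grubbs-level ladder.
#' @param alpha_candidates the level at which candidate SL-LD probes are
#'   taken for post-analysis.
#' @param n_outliers coincident outliers required for SL-LD (2 or 3).
#' @param directions regulation directions to scan.
#' @param max_outliers per-probe cap of the sequential scan.
#' @param n_replicates randomization replicates.
#' @param n_boot bootstrap replicates for cluster support.
#' @param seed master seed for every stochastic stage.
#' @param include_controls include controls in the Grubbs test sample.
#' @param match SL-LD eligibility, `"at_least"` or `"exactly"`.
#' @param most_comparison reading of the most-depressed-only test.
#' @param plus_one small-sample correction of randomization p-values.
#' @param f_coef inbreeding coefficient for depression rates.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       matrix_path = NULL, sheet_path = NULL,
                       productivity_path = NULL,
                       sim = sim_config(),
                       alphas = c(0.10, 0.05, 0.025, 0.01),
                       alpha_candidates = 0.05,
                       n_outliers = 2L,
                       directions = c("down", "up"),
                       max_outliers = 3L,
                       n_replicates = 10000L,
                       n_boot = 1000L,
                       seed = 1L,
                       include_controls = FALSE,
                       match = "at_least",
                       most_comparison = "total",
                       plus_one = FALSE,
                       f_coef = 0.7) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Rebuild a run configuration from its serialized JSON
#'
#' Inverse of the `run_config.json` written by [run_pipeline()], so a
#' bundle can be reproduced exactly from its own provenance record.
#'
#' @param path path to a `run_config.json`.
#' @return a [run_config()].
#' @export
run_config_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  sim_args <- x$sim
  sim_args$planted <- as.data.frame(x$sim$planted,
                                    stringsAsFactors = FALSE)
  x$sim <- do.call(sim_config, sim_args)
  x[vapply(x, is.null, logical(1L))] <- NULL
  do.call(run_config, x)
}

.serialize_config <- function(cfg) {
  x <- unclass(cfg)
  x$sim <- unclass(x$sim)
  x$sim$planted <- as.list(x$sim$planted)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

#' Run the full SL-LD analysis pipeline
#'
#' Executes every stage, writes the report bundle into
#' `config$out_dir`, and logs each stage with its parameters to stderr and
#' `run.log`. The bundle is deterministic given the seed: outlier calls,
#' SL-LD calls, ladder table, randomization JSON, depression summary,
#' correlation report, dendrogram (Newick + merge table + bootstrap
#' support), a plain-text summary, and the serialized configuration whose
#' MD5 hash stamps every table.
#'
#' @param config a [run_config()].
#' @return invisible list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "run.log")
  cat("", file = logfile)
  log_stage <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[slldscan] ", msg)
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg, "\n",
        file = logfile, sep = "", append = TRUE)
  }
  fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e) fail(name, e))

  cfg_json <- .serialize_config(config)
  cfg_path <- file.path(out, "run_config.json")
  writeLines(cfg_json, cfg_path)
  # hash the analysis parameters only, not the output location, so two
  # runs of the same analysis into different directories share a hash
  cfg_nodir <- config
  cfg_nodir$out_dir <- NULL
  hash_path <- tempfile(fileext = ".json")
  writeLines(.serialize_config(cfg_nodir), hash_path)
  cfg_hash <- unname(tools::md5sum(hash_path))
  unlink(hash_path)
  stamp <- c(sprintf("slldscan %s", as.character(packageVersion("slldscan"))),
             sprintf("seed %d", config$seed),
             sprintf("config_hash %s", cfg_hash))

  # ---- inputs -------------------------------------------------------
  simulated <- is.null(config$matrix_path)
  res <- list(config = config, config_hash = cfg_hash)
  if (simulated) {
    log_stage("simulate: %d probes, seed %d, %d planted effects",
              config$sim$n_probes, config$sim$seed,
              nrow(config$sim$planted))
    sim <- stage("simulate", simulate_expression(config$sim))
    prod <- stage("simulate", simulate_productivity(config$sim))
    x <- sim$matrix
    sheet <- sim$sheet
    dir.create(file.path(out, "inputs"), showWarnings = FALSE)
    write_expression_matrix(x, file.path(out, "inputs", "expression.tsv"))
    write_table(sim$sheet, file.path(out, "inputs", "sample_sheet.tsv"))
    write_table(sim$truth, file.path(out, "inputs", "truth.tsv"))
    write_table(prod$productivity,
                file.path(out, "inputs", "productivity.tsv"))
    write_table(prod$control, file.path(out, "inputs", "control_vials.tsv"))
    productivity <- prod$productivity
    w_o <- mean(prod$control$pupae_per_female)
    res$truth <- sim$truth
  } else {
    log_stage("load: %s", config$matrix_path)
    x <- stage("load", read_expression_matrix(config$matrix_path))
    sheet <- stage("load", read_sample_sheet(config$sheet_path, expr = x))
    productivity <- NULL
    w_o <- NULL
    if (!is.null(config$productivity_path)) {
      productivity <- stage("load",
                            read_productivity(config$productivity_path))
    }
  }
  res$matrix <- x
  res$sheet <- sheet

  # ---- depression summary ------------------------------------------
  if (!is.null(productivity) && !is.null(w_o)) {
    log_stage("depression: F = %.2f", config$f_coef)
    dep <- stage("depression",
                 depression_summary(productivity, w_o, config$f_coef))
    jsonlite::write_json(
      list(provenance = stamp, w_o = dep$w_o, w_i = dep$w_i, f = dep$f,
           overall_idr = dep$overall_idr),
      file.path(out, "depression.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    write_table(dep$per_subline, file.path(out, "subline_idr.tsv"),
                comments = stamp)
    res$depression <- dep
  }

  # ---- scan + SL-LD at the candidate level -------------------------
  all_calls <- list()
  rand <- list()
  slld <- list()
  for (dir in config$directions) {
    log_stage("scan: direction %s, alpha %.3g, max %d outliers", dir,
              config$alpha_candidates, config$max_outliers)
    calls <- stage("scan", sequential_outlier_scan(
      x, sheet, alpha = config$alpha_candidates,
      max_outliers = config$max_outliers, direction = dir,
      include_controls = config$include_controls))
    all_calls[[dir]] <- calls
    slld[[dir]] <- stage("classify", classify_slld(
      calls, sheet, n_outliers = config$n_outliers, match = config$match))
    log_stage("randomize: %s, %d replicates", dir, config$n_replicates)
    rand[[dir]] <- stage("randomize", randomization_test(
      calls, sheet, n_outliers = config$n_outliers,
      n_replicates = config$n_replicates, seed = config$seed,
      match = config$match, most_comparison = config$most_comparison,
      plus_one = config$plus_one))
  }
  calls_df <- do.call(rbind, all_calls)
  slld_df <- do.call(rbind, slld)
  rownames(calls_df) <- rownames(slld_df) <- NULL
  write_table(calls_df, file.path(out, "outlier_calls.tsv"),
              comments = stamp)
  write_table(slld_df, file.path(out, "slld_calls.tsv"), comments = stamp)
  jsonlite::write_json(
    c(list(provenance = stamp),
      lapply(rand, function(r) unclass(r))),
    file.path(out, "randomization.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  res$calls <- calls_df
  res$slld <- slld_df
  res$randomization <- rand

  # ---- alpha ladder -------------------------------------------------
  log_stage("ladder: alphas %s", paste(config$alphas, collapse = ", "))
  ladder <- stage("ladder", alpha_ladder(
    x, sheet, alphas = config$alphas, n_outliers = config$n_outliers,
    directions = config$directions, n_replicates = config$n_replicates,
    seed = config$seed, max_outliers = config$max_outliers,
    match = config$match, most_comparison = config$most_comparison,
    plus_one = config$plus_one))
  write_table(ladder, file.path(out, "ladder.tsv"), comments = stamp)
  res$ladder <- ladder

  # ---- post-analysis of down/most candidates -----------------------
  cand <- slld_df[slld_df$direction == "down" &
                    slld_df$level == "most_depressed", , drop = FALSE]
  if (nrow(cand) >= 2L) {
    genes <- cand$probe_id
    log_stage("postanalysis: %d candidate probes", length(genes))
    fit <- stage("postanalysis", hierarchical_cluster(x, genes))
    bs <- stage("postanalysis", bootstrap_support(
      x, genes, n_boot = config$n_boot, seed = config$seed))
    cluster_newick(fit, file.path(out, "dendrogram.nwk"))
    merge_df <- data.frame(step = seq_len(nrow(fit$hclust$merge)),
                           left = fit$hclust$merge[, 1L],
                           right = fit$hclust$merge[, 2L],
                           height = fit$hclust$height)
    write_table(merge_df, file.path(out, "cluster_merges.tsv"),
                comments = stamp)
    write_table(bs$nodes, file.path(out, "cluster_support.tsv"),
                comments = stamp)
    # mirror the with/without-outlier correlation table on the largest
    # cluster: remove the outlier sublines its probes were called in
    k <- min(4L, length(genes))
    memb <- cutree(fit$hclust, k = k)
    big <- names(memb)[memb == which.max(tabulate(memb))]
    rep_cor <- NULL
    if (length(big) >= 2L) {
      down_calls <- all_calls[["down"]]
      rem <- unique(down_calls$sample_id[
        down_calls$probe_id %in% big &
          down_calls$order <= config$n_outliers])
      if (ncol(x) - length(rem) >= 3L)
        rep_cor <- stage("postanalysis",
                         correlation_with_without(x, big, rem))
    }
    if (!is.null(rep_cor)) {
      jsonlite::write_json(
        list(provenance = stamp, genes = rep_cor$genes,
             removed_samples = rep_cor$removed_samples,
             n_full = rep_cor$n_full, n_reduced = rep_cor$n_reduced,
             mean_r_full = rep_cor$mean_r_full,
             mean_r_reduced = rep_cor$mean_r_reduced,
             r_full = rep_cor$r_full, r_reduced = rep_cor$r_reduced,
             p_full = rep_cor$sig_full$p, p_reduced = rep_cor$sig_reduced$p,
             significant_reduced = rep_cor$sig_reduced$significant),
        file.path(out, "correlation_report.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE, matrix = "rowmajor")
      res$correlation <- rep_cor
    }
    res$cluster <- fit
    res$cluster_support <- bs
  } else {
    log_stage("postanalysis: skipped (%d candidate probes)", nrow(cand))
  }

  # ---- summary ------------------------------------------------------
  sm <- c(
    stamp,
    sprintf("samples: %d (%d inbred, %d control)", nrow(sheet),
            sum(sheet$role == "inbred"), sum(sheet$role == "control")),
    sprintf("probes: %d", nrow(x)),
    sprintf("outlier calls at alpha = %.3g: %d", config$alpha_candidates,
            nrow(calls_df)),
    sprintf("SL-LD probes (n_outliers = %d): %d", config$n_outliers,
            nrow(slld_df)),
    vapply(names(rand), function(d) sprintf(
      "%s: observed %d (most %d / least %d), expected %.2f, p_total %.4g",
      d, rand[[d]]$observed_total,
      rand[[d]]$observed_by_level[["most_depressed"]],
      rand[[d]]$observed_by_level[["least_depressed"]],
      rand[[d]]$expected_mean, rand[[d]]$p_total), character(1L)))
  writeLines(sm, file.path(out, "summary.txt"))
  log_stage("done: %s", out)
  invisible(res)
}
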