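# Shared fixtures and independent oracles.

# canonical 27-sample design sheet (4 lines x 2 levels x 3 sublines + 3 ctrl)
canonical_sheet <- function()
  sim_sample_sheet(sim_config(n_probes = 10L,
                              planted = default_planted()[0, ]))

# minimal 2 lines x 2 levels x 2 sublines design (8 inbred samples)
toy_sheet_222 <- function() {
  sample_sheet(data.frame(
    sample_id = paste0("s", 1:8),
    role = "inbred",
    line = rep(c("a", "b"), each = 4),
    level = rep(c("most_depressed", "least_depressed"), each = 2, times = 2),
    subline_index = rep(1:2, 4),
    stringsAsFactors = FALSE))
}

# build an expression matrix from a numeric matrix with default ids
mat_fix <- function(values, probes = sprintf("p%02d", seq_len(nrow(values))),
                    samples = sprintf("s%02d", seq_len(ncol(values)))) {
  expression_matrix(values, probes, samples)
}

# independent sequential Grubbs oracle: plain loop, explicit arithmetic,
# critical value recomputed from the Student-t quantile
oracle_seq_scan <- function(row, alpha, max_outliers, direction) {
  idx <- seq_along(row)
  out <- list()
  for (k in seq_len(max_outliers)) {
    n <- length(row)
    if (n < 3) break
    t <- qt(1 - alpha / n, df = n - 2)
    gcrit <- (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
    m <- sum(row) / n
    s <- sqrt(sum((row - m)^2) / (n - 1))
    if (s == 0) break
    i <- if (direction == "down") which.min(row) else which.max(row)
    G <- abs(row[i] - m) / s
    if (G < gcrit) break
    out[[k]] <- list(index = idx[i], G = G, n = n)
    row <- row[-i]
    idx <- idx[-i]
  }
  out
}

# outlier-call identity key for set comparisons
call_key <- function(calls)
  paste(calls$probe_id, calls$sample_id, calls$order, sep = "/")
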