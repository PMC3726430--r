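# Productivity summaries, inbreeding depression rate, extreme-subline
# selection and the full-sib inbreeding-coefficient recurrence.

#' Inbreeding depression rate
#'
#' \eqn{IDR = (W_O - W_I)/(F \cdot W_O)}: the proportional fitness loss per
#' unit increase in the inbreeding coefficient. Read as % per 1% increase
#' in inbreeding (an IDR of 0.95 means about 1% loss per 1% inbreeding).
#'
#' @param w_o outbred control mean productivity (> 0).
#' @param w_i inbred mean productivity.
#' @param f inbreeding coefficient in (0, 1]; default 0.7, the study-design
#'   value after eight generations of sib mating.
#' @return the depression rate per unit F (vectorized over `w_i`).
#' @export
idr <- function(w_o, w_i, f = 0.7) {
  if (any(w_o <= 0)) stop("control productivity w_o must be positive")
  if (f <= 0 || f > 1) stop("inbreeding coefficient f must lie in (0, 1]")
  (w_o - w_i) / (f * w_o)
}

#' Summarize productivity and per-subline depression rates
#'
#' Averages replicate vial counts per subline, takes the inbred mean
#' \eqn{W_I} as the mean of subline means, and computes the overall and
#' per-subline inbreeding depression rates.
#'
#' @param productivity data.frame with columns `line`, `subline_id`,
#'   `replicate_id`, `pupae_per_female` (see [read_productivity()]).
#' @param w_o control mean productivity, e.g. from the control vials of
#'   [simulate_productivity()].
#' @param f inbreeding coefficient used in the rate.
#' @return list of class `depression_summary`: `w_o`, `w_i`, `f`,
#'   `overall_idr`, and `per_subline` (data.frame with subline means and
#'   rates).
#' @export
depression_summary <- function(productivity, w_o, f = 0.7) {
  means <- aggregate(pupae_per_female ~ line + subline_id,
                     data = productivity, FUN = mean)
  names(means)[names(means) == "pupae_per_female"] <- "mean_productivity"
  means <- means[order(means$line, means$subline_id), ]
  means$idr <- idr(w_o, means$mean_productivity, f)
  w_i <- mean(means$mean_productivity)
  rownames(means) <- NULL
  structure(list(w_o = w_o, w_i = w_i, f = f,
                 overall_idr = idr(w_o, w_i, f),
                 per_subline = means),
            class = "depression_summary")
}

#' @export
print.depression_summary <- function(x, ...) {
  cat(sprintf("W_O = %.2f, W_I = %.2f, F = %.2f\n", x$w_o, x$w_i, x$f))
  cat(sprintf("overall IDR = %.4f per unit F (%.2f%% per 1%% inbreeding)\n",
              x$overall_idr, x$overall_idr))
  cat(sprintf("%d sublines, per-subline IDR range [%.3f, %.3f]\n",
              nrow(x$per_subline), min(x$per_subline$idr),
              max(x$per_subline$idr)))
  invisible(x)
}

#' Select the most and least depressed sublines of each line
#'
#' Ranks sublines within each line by mean productivity across replicates
#' and returns the `k` lowest-productivity (most depressed) and `k`
#' highest-productivity (least depressed) sublines. The most-depressed set
#' may exclude sublines whose mean falls below `min_viable` -- the "enough
#' individuals to be further analysed" filter; by default no filter is
#' applied. Ties at rank `k` are broken by subline id, deterministically.
#'
#' @inheritParams depression_summary
#' @param k sublines to select per extreme, per line.
#' @param min_viable optional lower bound on mean productivity for the
#'   most-depressed set.
#' @return data.frame with columns `line`, `subline_id`,
#'   `mean_productivity`, `group` (`"most_depressed"`/`"least_depressed"`).
#' @export
select_extreme_sublines <- function(productivity, k = 3L,
                                    min_viable = NULL) {
  means <- aggregate(pupae_per_female ~ line + subline_id,
                     data = productivity, FUN = mean)
  names(means)[names(means) == "pupae_per_female"] <- "mean_productivity"
  out <- lapply(split(means, means$line), function(d) {
    d <- d[order(d$mean_productivity, d$subline_id), ]
    pool <- if (is.null(min_viable)) d
      else d[d$mean_productivity >= min_viable, , drop = FALSE]
    if (nrow(pool) < k || nrow(d) < 2L * k)
      stop(sprintf("line '%s': fewer than %d sublines available per extreme",
                   d$line[1L], k))
    most <- pool[seq_len(k), , drop = FALSE]
    least <- d[order(-d$mean_productivity, d$subline_id), ][seq_len(k), ,
                                                            drop = FALSE]
    if (length(intersect(most$subline_id, least$subline_id)))
      stop(sprintf("line '%s': extreme sets overlap; too few sublines",
                   d$line[1L]))
    most$group <- "most_depressed"
    least$group <- "least_depressed"
    rbind(most, least)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Inbreeding coefficient under repeated full-sib mating
#'
#' Full-sib recurrence \eqn{F_t = (1 + 2F_{t-1} + F_{t-2})/4} with
#' \eqn{F_0 = F_{-1} = 0}. Optionally, after generation `g_switch` the
#' scheme relaxes to mating several pairs per vial, approximated by the
#' idealized-population increment \eqn{\Delta F = 1/(2N_e)} so that
#' \eqn{F_t = F_{t-1} + (1 - F_{t-1})/(2N_e)}.
#'
#' @param t generation (non-negative integer; vectorized).
#' @param g_switch optional generation after which the \eqn{\Delta F}
#'   approximation applies.
#' @param n_e effective size of the relaxed phase (default 4: two males
#'   and two females).
#' @return \eqn{F_t}.
#' @export
sib_mating_F <- function(t, g_switch = NULL, n_e = 4) {
  if (any(t < 0)) stop("generation t must be non-negative")
  tmax <- max(t)
  f <- numeric(tmax + 1L)   # f[i + 1] = F_i
  fm1 <- 0                  # F_{-1}
  if (tmax >= 1) {
    for (i in seq_len(tmax)) {
      prev <- f[i]
      prev2 <- if (i == 1L) fm1 else f[i - 1L]
      f[i + 1L] <- if (!is.null(g_switch) && i > g_switch)
        f[i] + (1 - f[i]) / (2 * n_e)
      else (1 + 2 * prev + prev2) / 4
    }
  }
  f[t + 1L]
}
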