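# Grubbs (extreme studentized deviate) test and the sequential per-probe
# outlier scan: test the one-sided extreme among the remaining eligible
# samples, remove it if significant, recompute mean/sd, repeat.

#' Grubbs statistic of a sample
#'
#' The studentized deviation of the extreme value from the sample mean,
#' \eqn{G = (x_{extreme} - \bar x)/s} (sign arranged so that G is positive
#' on the requested side), with `s` the usual n-1-denominator standard
#' deviation. `side = "min"` tests the smallest value, `"max"` the largest,
#' `"two_sided"` the largest absolute deviation.
#'
#' @param values numeric vector, length at least 3, non-constant.
#' @param side `"max"`, `"min"` or `"two_sided"`.
#' @return list with `G` (the statistic) and `index` (position of the
#'   extreme value; ties broken by first position).
#' @export
grubbs_statistic <- function(values, side = c("max", "min", "two_sided")) {
  side <- match.arg(side)
  values <- as.numeric(values)
  if (length(values) < 3L)
    stop("Grubbs test requires at least 3 values")
  m <- mean(values)
  s <- sd(values)
  if (s == 0)
    stop("degenerate input: zero variance")
  res <- switch(side,
    max = {
      i <- which.max(values)
      list(G = (values[i] - m) / s, index = i)
    },
    min = {
      i <- which.min(values)
      list(G = (m - values[i]) / s, index = i)
    },
    two_sided = {
      d <- abs(values - m)
      i <- which.max(d)
      list(G = d[i] / s, index = i)
    })
  res
}

#' Grubbs critical value
#'
#' Closed form via the Student-t quantile:
#' \deqn{G_{crit} = \frac{n-1}{\sqrt n}\sqrt{\frac{t^2}{n-2+t^2}}}
#' with \eqn{t} the upper-tail quantile of the t distribution with
#' \eqn{n-2} degrees of freedom at level \eqn{\alpha/n} (one-sided) or
#' \eqn{\alpha/(2n)} (two-sided). Always strictly below the attainable
#' maximum \eqn{(n-1)/\sqrt n}.
#'
#' @param n sample size (at least 3).
#' @param alpha test level in (0, 1).
#' @param sidedness `"one"` or `"two"`.
#' @return the critical value (vectorized over `n`).
#' @export
grubbs_critical <- function(n, alpha, sidedness = c("one", "two")) {
  sidedness <- match.arg(sidedness)
  if (any(n < 3))
    stop("Grubbs critical value requires n >= 3")
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  tail <- alpha / (n * if (sidedness == "two") 2 else 1)
  t <- qt(tail, df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Sequential Grubbs outlier scan of an expression matrix
#'
#' For every probe (row), repeatedly applies a one-sided Grubbs test to the
#' remaining eligible samples in the requested direction: if the extreme is
#' significant at `alpha` it is recorded as an outlier call (order 1, 2,
#' ...), removed, and the test repeated with recomputed mean and standard
#' deviation, until a non-significant extreme or `max_outliers` calls.
#' By default only inbred sublines are eligible; outbred controls are
#' excluded from the test sample unless `include_controls = TRUE`.
#'
#' Constant (zero-variance) rows yield no calls. Ties at the extreme are
#' broken by first column order, deterministically.
#'
#' @param x probe-by-sample numeric matrix (see [expression_matrix()]).
#' @param sheet optional [sample_sheet()]; used to derive the default
#'   eligible samples.
#' @param alpha per-test level of the Grubbs test.
#' @param max_outliers maximum outliers to remove per probe and direction.
#' @param direction `"down"` (under-expression) or `"up"`.
#' @param eligible_samples explicit character vector of sample ids to test;
#'   overrides `sheet`.
#' @param include_controls when deriving eligibility from `sheet`, also
#'   test control samples (off by default).
#' @param sidedness level interpretation for the critical value; the scan
#'   itself is always directional.
#' @return data.frame of outlier calls: `probe_id`, `sample_id`,
#'   `direction`, `order`, `G`, `G_crit`, `alpha`, `n_at_test`; zero rows
#'   when nothing is significant.
#' @export
sequential_outlier_scan <- function(x, sheet = NULL, alpha = 0.05,
                                    max_outliers = 3L,
                                    direction = c("down", "up"),
                                    eligible_samples = NULL,
                                    include_controls = FALSE,
                                    sidedness = c("one", "two")) {
  direction <- match.arg(direction)
  sidedness <- match.arg(sidedness)
  if (is.null(eligible_samples)) {
    if (!is.null(sheet)) {
      eligible_samples <- if (include_controls) sheet$sample_id
        else sheet$sample_id[sheet$role == "inbred"]
    } else {
      eligible_samples <- colnames(x)
    }
  }
  missing <- setdiff(eligible_samples, colnames(x))
  if (length(missing))
    stop(sprintf("eligible sample '%s' is not a matrix column", missing[1L]))
  n0 <- length(eligible_samples)
  if (n0 < 3L + max_outliers - 1L)
    stop(sprintf("too few eligible samples (%d) for max_outliers = %d",
                 n0, max_outliers))
  v <- x[, eligible_samples, drop = FALSE]
  w <- if (direction == "down") -v else v   # always hunt the maximum of w
  p <- nrow(w)
  keep <- matrix(TRUE, p, n0)
  active <- seq_len(p)
  out <- vector("list", max_outliers)
  for (k in seq_len(max_outliers)) {
    nk <- n0 - k + 1L
    if (nk < 3L || !length(active)) break
    gcrit <- grubbs_critical(nk, alpha, sidedness)
    wa <- w[active, , drop = FALSE]
    ka <- keep[active, , drop = FALSE]
    wna <- wa
    wna[!ka] <- NA_real_
    mu <- rowMeans(wna, na.rm = TRUE)
    ss <- rowSums(wna * wna, na.rm = TRUE)
    va <- pmax((ss - nk * mu^2) / (nk - 1), 0)
    sdv <- sqrt(va)
    wm <- wa
    wm[!ka] <- -Inf
    j <- max.col(wm, ties.method = "first")
    ext <- wm[cbind(seq_along(active), j)]
    G <- (ext - mu) / sdv
    hit <- is.finite(G) & G >= gcrit
    if (!any(hit)) break
    rows <- active[hit]
    out[[k]] <- data.frame(
      probe_id = rownames(v)[rows],
      sample_id = colnames(v)[j[hit]],
      direction = direction,
      order = k,
      G = G[hit],
      G_crit = gcrit,
      alpha = alpha,
      n_at_test = nk,
      stringsAsFactors = FALSE)
    keep[cbind(rows, j[hit])] <- FALSE
    active <- rows
  }
  calls <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(calls))
    calls <- data.frame(probe_id = character(), sample_id = character(),
                        direction = character(), order = integer(),
                        G = numeric(), G_crit = numeric(), alpha = numeric(),
                        n_at_test = integer(), stringsAsFactors = FALSE)
  calls <- calls[order(match(calls$probe_id, rownames(v)), calls$order), ]
  rownames(calls) <- NULL
  calls
}
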