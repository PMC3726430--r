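# Candidate characterization: pairwise correlations with/without the
# outlier sublines, Student-t significance with Benjamini-Hochberg
# correction, complete-linkage clustering on 1 - |r|, and bootstrap
# support for the clusters.

.check_gene_rows <- function(x, genes) {
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop(sprintf("gene '%s' is not a matrix row", missing[1L]))
  sub <- x[genes, , drop = FALSE]
  sds <- apply(sub, 1L, sd)
  if (any(sds == 0))
    stop(sprintf("gene '%s' has zero variance over the selected samples",
                 genes[which(sds == 0)[1L]]))
  sub
}

#' Mean of the off-diagonal correlations
#'
#' The exact average of the upper-triangle (off-diagonal) entries of a
#' symmetric correlation matrix -- 15 values for 6 genes.
#'
#' @param r square symmetric correlation matrix.
#' @return the mean off-diagonal correlation.
#' @export
mean_offdiag <- function(r) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("correlation matrix must be square")
  mean(r[upper.tri(r)])
}

#' Significance of a correlation matrix with BH correction
#'
#' For each unordered gene pair, \eqn{t = r\sqrt{(n-2)/(1-r^2)}} is
#' referred to a two-sided Student-t distribution with `n - 2` degrees of
#' freedom; the Benjamini-Hochberg step-up correction is applied over the
#' family of unordered pairs. \eqn{|r| = 1} is treated as p = 0.
#'
#' @param r correlation matrix.
#' @param n number of samples the correlations were computed from.
#' @param alpha significance level applied to the adjusted p-values.
#' @return list with matrices `p` (raw two-sided p), `p_adj`
#'   (BH-adjusted) and `significant` (logical), plus `df = n - 2`.
#' @export
correlation_significance <- function(r, n, alpha = 0.05) {
  if (n < 3) stop("need at least 3 samples for a correlation t-test")
  r <- as.matrix(r)
  up <- upper.tri(r)
  rv <- r[up]
  p <- numeric(length(rv))
  exact <- abs(rv) >= 1
  p[exact] <- 0
  t <- rv[!exact] * sqrt((n - 2) / (1 - rv[!exact]^2))
  p[!exact] <- 2 * pt(-abs(t), df = n - 2)
  padj <- p.adjust(p, method = "BH")
  mk <- function(v, diag_val) {
    m <- matrix(diag_val, nrow(r), ncol(r), dimnames = dimnames(r))
    m[up] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  list(p = mk(p, 0), p_adj = mk(padj, 0),
       significant = mk(padj <= alpha, TRUE) > 0,
       df = n - 2, alpha = alpha)
}

#' Pairwise correlations before and after removing outlier sublines
#'
#' Pearson correlations between the expression profiles of a set of genes
#' computed over all samples (`r_full`) and over the samples that remain
#' after removing the specified outlier sublines (`r_reduced`), with
#' two-sided t-tests (df = n - 2 in each sample set) and BH correction,
#' plus exact means of the off-diagonal halves. A common regulation signal
#' that survives removal of the outlier sublines (high `mean_r_reduced`)
#' is evidence the correlation is not generated by the outliers alone.
#'
#' @param x probe-by-sample expression matrix.
#' @param genes probe ids to correlate (at least 2).
#' @param removed_samples sample ids excluded from the reduced
#'   computation; any number may be removed as long as at least 3 samples
#'   remain.
#' @param alpha significance level for the BH-corrected flags.
#' @return list of class `correlation_report`: `r_full`, `r_reduced`,
#'   `n_full`, `n_reduced`, `sig_full`, `sig_reduced` (each a
#'   [correlation_significance()] result), `mean_r_full`,
#'   `mean_r_reduced`, `removed_samples`.
#' @export
correlation_with_without <- function(x, genes, removed_samples = character(),
                                     alpha = 0.05) {
  if (length(genes) < 2L) stop("need at least 2 genes")
  unknown <- setdiff(removed_samples, colnames(x))
  if (length(unknown))
    stop(sprintf("removed sample '%s' is not a matrix column", unknown[1L]))
  keep <- setdiff(colnames(x), removed_samples)
  if (length(keep) < 3L)
    stop("fewer than 3 samples remain after removal")
  full <- .check_gene_rows(x, genes)
  red <- .check_gene_rows(x[, keep, drop = FALSE], genes)
  r_full <- cor(t(full))
  r_red <- cor(t(red))
  structure(list(
    genes = genes,
    r_full = r_full,
    r_reduced = r_red,
    n_full = ncol(full),
    n_reduced = ncol(red),
    sig_full = correlation_significance(r_full, ncol(full), alpha),
    sig_reduced = correlation_significance(r_red, ncol(red), alpha),
    mean_r_full = mean_offdiag(r_full),
    mean_r_reduced = mean_offdiag(r_red),
    removed_samples = removed_samples),
    class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlations over %d genes: mean r = %.3f (n = %d)",
              length(x$genes), x$mean_r_full, x$n_full))
  cat(sprintf(", mean r' = %.3f after removing %d sample(s) (n = %d)\n",
              x$mean_r_reduced, length(x$removed_samples), x$n_reduced))
  invisible(x)
}

#' Complete-linkage clustering on absolute-correlation distance
#'
#' Distance \eqn{d(i, j) = 1 - |r_{ij}|} between gene expression profiles
#' (all samples), agglomerated with complete linkage via [stats::hclust()].
#' Genes are ordered lexicographically beforehand so ties break
#' deterministically.
#'
#' @param x probe-by-sample expression matrix.
#' @param genes probe ids to cluster (at least 2, no zero-variance gene).
#' @return list of class `slld_hclust`: `hclust` (the merge tree), `dist`,
#'   and `cor` (the signed correlation matrix).
#' @export
hierarchical_cluster <- function(x, genes) {
  if (length(genes) < 2L) stop("need at least 2 genes to cluster")
  genes <- sort(genes)
  sub <- .check_gene_rows(x, genes)
  r <- cor(t(sub))
  d <- as.dist(1 - abs(r))
  structure(list(hclust = hclust(d, method = "complete"), dist = d, cor = r),
            class = "slld_hclust")
}

# leaf label sets of every internal node (merge row) of an hclust tree
.node_leaf_sets <- function(hc) {
  labs <- hc$labels
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    grab <- function(j) if (j < 0) labs[-j] else sets[[j]]
    sets[[i]] <- sort(c(grab(hc$merge[i, 1L]), grab(hc$merge[i, 2L])))
  }
  sets
}

#' Bootstrap support for dendrogram clusters
#'
#' Resamples samples (matrix columns) with replacement `n_boot` times,
#' reclusters with [hierarchical_cluster()], and reports for each internal
#' node of the original tree the bootstrap proportion (BP): the fraction
#' of replicate trees containing exactly that node's gene set as a
#' cluster. Single-gene leaves have BP = 1 by convention. Replicates in
#' which a gene becomes constant (so its correlations are undefined) are
#' redrawn.
#'
#' @inheritParams hierarchical_cluster
#' @param n_boot bootstrap replicates.
#' @param seed integer seed; identical seeds give identical BP vectors.
#' @return list of class `bootstrap_support`: the original `slld_hclust`
#'   fit, and `nodes`, a data.frame with one row per internal node
#'   (`node`, `members`, `bp`), plus `n_boot` and `seed`.
#' @export
bootstrap_support <- function(x, genes, n_boot = 1000L, seed = 1L) {
  fit <- hierarchical_cluster(x, genes)
  sets0 <- .node_leaf_sets(fit$hclust)
  keys0 <- vapply(sets0, paste, character(1L), collapse = "\r")
  counts <- numeric(length(keys0))
  nsamp <- ncol(x)
  set.seed(as.integer(seed))
  for (b in seq_len(n_boot)) {
    for (attempt in seq_len(100L)) {
      idx <- sample.int(nsamp, replace = TRUE)
      xb <- x[fit$hclust$labels, idx, drop = FALSE]
      colnames(xb) <- sprintf("bs_%d", seq_len(nsamp))
      ok <- all(apply(xb, 1L, sd) > 0)
      if (ok) break
    }
    if (!ok) stop("could not draw a bootstrap replicate with non-constant genes")
    hb <- hclust(as.dist(1 - abs(cor(t(xb)))), method = "complete")
    hb$labels <- fit$hclust$labels
    keys_b <- vapply(.node_leaf_sets(hb), paste, character(1L),
                     collapse = "\r")
    counts <- counts + (keys0 %in% keys_b)
  }
  nodes <- data.frame(
    node = seq_along(keys0),
    members = vapply(sets0, paste, character(1L), collapse = ","),
    bp = counts / n_boot,
    stringsAsFactors = FALSE)
  structure(list(fit = fit, nodes = nodes, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "bootstrap_support")
}

#' Export a dendrogram as Newick text
#'
#' @param fit an `slld_hclust` result (or a plain `hclust`).
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to `path`.
#' @export
cluster_newick <- function(fit, path = NULL) {
  hc <- if (inherits(fit, "slld_hclust")) fit$hclust else fit
  tree <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}
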