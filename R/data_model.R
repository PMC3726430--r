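# Core containers and TSV/JSON plumbing.
#
# An expression matrix is a plain numeric matrix (probes in rows, samples in
# columns, both with unique dimnames) validated by expression_matrix(); a
# sample sheet is a data.frame with the design labels of each array. Keeping
# base containers means cor(), hclust() etc. apply directly.

.levels_vocab <- c("most_depressed", "least_depressed")
.roles_vocab <- c("inbred", "control")

#' Construct and validate an expression matrix
#'
#' Validates a numeric probe-by-sample matrix of log2-scale expression values
#' (e.g. RMA summaries). All values must be finite, probe and sample
#' identifiers unique, and at least 3 samples present (the Grubbs test is
#' undefined below n = 3). Missing values are rejected rather than imputed:
#' the normalized matrices this package consumes are complete.
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#' @param probe_ids,sample_ids optional dimnames; taken from `values` if
#'   already set.
#' @return the validated matrix with dimnames set.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must form a numeric matrix")
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("probe and sample identifiers are required")
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(probe_ids))
    stop(sprintf("duplicated probe id: '%s'",
                 probe_ids[duplicated(probe_ids)][1L]))
  if (anyDuplicated(sample_ids))
    stop(sprintf("duplicated sample id: '%s'",
                 sample_ids[duplicated(sample_ids)][1L]))
  if (ncol(values) < 3L)
    stop("at least 3 samples are required")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at probe '%s', sample '%s'",
                 probe_ids[bad[1L]], sample_ids[bad[2L]]))
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  values
}

#' Read an expression matrix from TSV
#'
#' Expects a GEO series-matrix-like layout: first column probe identifiers,
#' header row sample identifiers, numeric body, tab-separated. Malformed
#' input (ragged rows, duplicated identifiers, non-numeric cells) is a
#' format error naming the offending row or cell.
#'
#' @param path path to a tab-separated file.
#' @return a validated probe-by-sample numeric matrix.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read expression matrix: '%s' does not exist", path))
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged TSV in '%s': row %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1L]))
  }
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", colClasses = "character",
                   check.names = FALSE)
  if (ncol(df) < 2L)
    stop("expression matrix needs a probe-id column plus sample columns")
  probe_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-numeric expression value '%s' at row %d (probe '%s'), column '%s'",
      body[bad[1L], bad[2L]], bad[1L], probe_ids[bad[1L]],
      sample_ids[bad[2L]]))
  }
  expression_matrix(num, probe_ids, sample_ids)
}

#' Construct and validate a sample sheet
#'
#' A sample sheet assigns each array to the study design: `role` is
#' `"inbred"` or `"control"`; inbred samples carry a `line` (e.g. a--d), a
#' depression `level` (`"most_depressed"` or `"least_depressed"`) and a
#' `subline_index`; controls carry neither line nor level. Tokens outside
#' the controlled vocabulary are errors, not warnings.
#'
#' @param df data.frame with columns `sample_id`, `role`, `line`, `level`,
#'   `subline_index`. Empty strings or `"none"`/`"NA"` in `line`/`level`
#'   are normalized to `NA`.
#' @param expr optional expression matrix; when supplied, the sheet and the
#'   matrix must reference exactly the same samples.
#' @return a validated `data.frame` (class `sample_sheet`).
#' @export
sample_sheet <- function(df, expr = NULL) {
  need <- c("sample_id", "role", "line", "level", "subline_index")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(sprintf("sample sheet is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  df <- as.data.frame(df)[, need]
  df$sample_id <- as.character(df$sample_id)
  df$role <- as.character(df$role)
  norm <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "" | tolower(x) %in% c("none", "na"))] <- NA_character_
    x
  }
  df$line <- norm(df$line)
  df$level <- norm(df$level)
  df$subline_index <- suppressWarnings(as.integer(df$subline_index))
  if (anyDuplicated(df$sample_id))
    stop(sprintf("duplicated sample id in sheet: '%s'",
                 df$sample_id[duplicated(df$sample_id)][1L]))
  bad_role <- setdiff(unique(df$role), .roles_vocab)
  if (length(bad_role))
    stop(sprintf("unknown role token '%s' (expected %s)", bad_role[1L],
                 paste(.roles_vocab, collapse = "/")))
  bad_level <- setdiff(unique(df$level[!is.na(df$level)]), .levels_vocab)
  if (length(bad_level))
    stop(sprintf("unknown depression level token '%s'", bad_level[1L]))
  ctrl <- df$role == "control"
  if (any(ctrl & (!is.na(df$line) | !is.na(df$level))))
    stop(sprintf("control sample '%s' must not carry a line or level",
                 df$sample_id[ctrl & (!is.na(df$line) | !is.na(df$level))][1L]))
  inb <- !ctrl
  if (any(inb & (is.na(df$line) | is.na(df$level))))
    stop(sprintf("inbred sample '%s' lacks a line and/or depression level",
                 df$sample_id[inb & (is.na(df$line) | is.na(df$level))][1L]))
  if (any(inb & is.na(df$subline_index)))
    stop("inbred samples need an integer subline_index")
  if (!is.null(expr)) {
    only_sheet <- setdiff(df$sample_id, colnames(expr))
    only_mat <- setdiff(colnames(expr), df$sample_id)
    if (length(only_sheet) || length(only_mat))
      stop(sprintf(
        "sample sheet and matrix disagree: %s%s",
        if (length(only_sheet))
          sprintf("'%s' only in sheet", only_sheet[1L]) else "",
        if (length(only_mat))
          sprintf("%s'%s' only in matrix",
                  if (length(only_sheet)) "; " else "", only_mat[1L]) else ""))
  }
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from TSV
#'
#' @inheritParams sample_sheet
#' @param path path to a tab-separated file with columns `sample_id`,
#'   `role`, `line`, `level`, `subline_index`.
#' @return a validated `sample_sheet` data.frame.
#' @export
read_sample_sheet <- function(path, expr = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read sample sheet: '%s' does not exist", path))
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "#", colClasses = "character",
                   check.names = FALSE)
  sample_sheet(df, expr = expr)
}

#' Read a productivity table from TSV
#'
#' Rows are replicate vial counts: columns `line`, `subline_id`,
#' `replicate_id`, `pupae_per_female` (non-negative reals).
#'
#' @param path path to a tab-separated file.
#' @return a data.frame with the four columns above.
#' @export
read_productivity <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read productivity table: '%s' does not exist", path))
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "#", check.names = FALSE)
  need <- c("line", "subline_id", "replicate_id", "pupae_per_female")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(sprintf("productivity table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  df <- df[, need]
  df$pupae_per_female <- as.numeric(df$pupae_per_female)
  if (anyNA(df$pupae_per_female) || any(df$pupae_per_female < 0))
    stop("pupae_per_female must be non-negative and numeric")
  df
}

#' Write a result table to TSV or JSON
#'
#' TSV numeric fields are written with `%.17g` so that reading them back
#' reproduces the doubles bit-identically; lines starting with `#` carry
#' optional provenance comments and are skipped by [read_result_table()].
#'
#' @param rows a data.frame (may have zero rows; the header is still
#'   written).
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @param comments optional character vector written as leading `#` lines
#'   (TSV only).
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("tsv", "json"),
                        comments = NULL) {
  format <- match.arg(format)
  rows <- as.data.frame(rows)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "json") {
    jsonlite::write_json(rows, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(path))
  }
  out <- rows
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path input path.
#' @param format `"tsv"` or `"json"`.
#' @return a data.frame.
#' @export
read_result_table <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("cannot read table: '%s' does not exist", path))
  if (format == "json")
    return(as.data.frame(jsonlite::fromJSON(path)))
  read.delim(path, header = TRUE, sep = "\t", quote = "",
             comment.char = "#", check.names = FALSE)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: first column `probe_id`, one
#' column per sample.
#'
#' @param x probe-by-sample numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  write_table(df, path, "tsv")
}
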