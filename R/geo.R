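# Optional convenience loader for a GEO series-matrix text file, so the
# pipeline can be pointed at a user-downloaded real data set. Headline
# real-data results additionally require the upstream RMA/present-call
# preprocessing, which this package deliberately does not implement.

#' Load an expression matrix from a GEO series-matrix file
#'
#' Parses the plain-text `*_series_matrix.txt` layout: `!`-prefixed
#' metadata lines, then a tab-separated expression table between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`. The user
#' must supply the downloaded file; nothing is fetched. Sample titles (if
#' present) are returned so a sample sheet can be assembled, but design
#' labels are study-specific and are not guessed.
#'
#' @param path path to an uncompressed series-matrix text file.
#' @return list with `matrix` (validated probe-by-sample matrix) and
#'   `sample_titles` (named character vector, possibly empty).
#' @export
read_geo_series_matrix <- function(path) {
  if (!file.exists(path))
    stop(sprintf(paste0(
      "series-matrix file '%s' does not exist; download the accession's ",
      "series matrix from GEO and pass its local path"), path))
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
    stop("no series-matrix expression table found in file")
  tab <- lines[(begin + 1L):(end - 1L)]
  tc <- textConnection(tab)
  on.exit(close(tc))
  df <- read.delim(tc, header = TRUE, sep = "\t", check.names = FALSE)
  df[[1L]] <- gsub('^"|"$', "", as.character(df[[1L]]))
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  titles <- character()
  tl <- grep("^!Sample_title\t", lines, value = TRUE)
  if (length(tl)) {
    titles <- gsub('^"|"$', "", strsplit(tl[1L], "\t")[[1L]][-1L])
    names(titles) <- colnames(m)[seq_along(titles)]
  }
  list(matrix = expression_matrix(m), sample_titles = titles)
}
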