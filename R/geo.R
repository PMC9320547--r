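# Series-matrix import/export: the key-value header block plus the
# delimited matrix-table block used by expression-omnibus deposits.

#' Import an expression study from a series-matrix file
#'
#' Parses the `!Sample_title` header line and the block between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`. Cell line
#' and condition are inferred from sample titles through a user-supplied
#' mapping table; samples with unmapped titles are dropped with a warning.
#'
#' @param path path to a series-matrix file (plain text).
#' @param mapping data.frame with columns `title`, `line`, `condition`.
#' @return an [expression_study()].
#' @export
geo_import <- function(path, mapping) {
  stopifnot(all(c("title", "line", "condition") %in% colnames(mapping)))
  lines <- readLines(path)
  unq <- function(x) gsub('^"|"$', "", x)
  title_line <- grep("^!Sample_title\t", lines, value = TRUE)
  if (!length(title_line)) stop("no !Sample_title header line")
  titles <- unq(strsplit(title_line[1L], "\t", fixed = TRUE)[[1L]][-1L])
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("missing or malformed series-matrix table delimiters")
  tab <- utils::read.delim(text = lines[(beg + 1L):(end - 1L)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- unq(as.character(tab[[1L]]))
  if (ncol(mat) != length(titles))
    stop("matrix columns do not match sample titles")
  colnames(mat) <- titles
  hit <- match(titles, mapping$title)
  if (anyNA(hit)) {
    warning(sum(is.na(hit)), " unmapped sample title(s) dropped: ",
            paste(titles[is.na(hit)], collapse = ", "))
    mat <- mat[, !is.na(hit), drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  if (!ncol(mat)) stop("no mapped samples remain")
  expression_study(
    mat,
    data.frame(sample = colnames(mat), line = mapping$line[hit],
               condition = mapping$condition[hit],
               stringsAsFactors = FALSE))
}

#' Export an expression study as a series-matrix file
#'
#' Writes a minimal series-matrix: a `!Sample_title` header naming the
#' samples and the quoted matrix-table block. [geo_import()] on the result
#' (with an identity title mapping) reproduces the study.
#'
#' @param study an [expression_study()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_series_matrix <- function(study, path) {
  stopifnot(inherits(study, "expression_study"))
  q <- function(x) paste0('"', x, '"')
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("!Sample_title", q(colnames(study$matrix))),
                   collapse = "\t"), con)
  writeLines("!series_matrix_table_begin", con)
  header <- paste(c("ID_REF", q(colnames(study$matrix))), collapse = "\t")
  writeLines(header, con)
  body <- apply(study$matrix, 1L, function(row)
    paste(row, collapse = "\t"))
  writeLines(paste(q(rownames(study$matrix)), body, sep = "\t"), con)
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}
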