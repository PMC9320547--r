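# Containers for expression studies (probe/gene x sample intensity matrix
# plus sample annotations) and gene-set collections.

#' Construct an expression study
#'
#' @param matrix numeric matrix of positive normalized intensities, rows are
#'   probes or genes (rownames required), columns are samples.
#' @param samples data.frame with columns `sample`, `line`, `condition`;
#'   one row per matrix column, in column order. Conditions are typically
#'   `"adhesion"` and `"suspension"`.
#' @param probe_map optional data.frame with columns `probe`, `gene`
#'   mapping matrix rownames to gene symbols; `NULL` means rows already are
#'   gene symbols.
#' @return object of class `expression_study`.
#' @export
expression_study <- function(matrix, samples, probe_map = NULL) {
  stopifnot(is.matrix(matrix), is.numeric(matrix),
            !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  stopifnot(all(c("sample", "line", "condition") %in% colnames(samples)))
  if (nrow(samples) != ncol(matrix) ||
      !identical(as.character(samples$sample), colnames(matrix)))
    stop("sample annotations must match matrix columns, in order")
  if (anyDuplicated(samples$sample)) stop("duplicate sample names")
  if (!is.null(probe_map))
    stopifnot(all(c("probe", "gene") %in% colnames(probe_map)))
  structure(list(matrix = matrix,
                 samples = as.data.frame(samples, stringsAsFactors = FALSE),
                 probe_map = probe_map),
            class = "expression_study")
}

#' Construct a gene-set collection
#'
#' @param sets list of sets, each a list with `name`, `description`,
#'   `genes` (character vector of member symbols).
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  nm <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("gene-set names must be unique")
  for (s in sets)
    if (length(s$genes) < 1L) stop("gene set '", s$name, "' is empty")
  structure(list(sets = sets), class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x$sets), "sets\n")
  invisible(x)
}

#' Names of the sets in a collection
#' @param collection a `gene_set_collection`.
#' @return character vector of set names.
#' @export
set_names <- function(collection) {
  vapply(collection$sets, `[[`, "", "name")
}
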