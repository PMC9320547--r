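# Keyword-driven gene-set mining and the cross-cell-line consistent-direction
# differential-expression screen: GMT I/O, keyword selection, probe
# aggregation, suspension/adhesion relative expression, and the screen itself.

#' Read and write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member gene symbols. Duplicate member symbols within
#' a set are removed on read, with a warning giving the count.
#'
#' @param path file path.
#' @return `read_gmt()` returns a [gene_set_collection()]; `write_gmt()`
#'   returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  n_dup <- 0L
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    dup <- sum(duplicated(genes))
    if (dup > 0L) {
      n_dup <- n_dup + dup
      genes <- genes[!duplicated(genes)]
    }
    sets[[i]] <- list(name = fields[1L], description = fields[2L],
                      genes = genes)
  }
  if (n_dup > 0L)
    warning(n_dup, " duplicated member symbol(s) removed")
  gene_set_collection(sets)
}

#' @rdname read_gmt
#' @param collection a [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection$sets, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Select gene sets by case-insensitive keyword match
#'
#' @param collection a [gene_set_collection()].
#' @param keyword non-empty substring to look for, case-insensitively.
#' @param fields which fields to search: any of `"name"`, `"description"`.
#'   The default searches both, since curated collections often carry the
#'   topic only in the description.
#' @return a [gene_set_collection()] with the matching sets, original
#'   order preserved (possibly empty).
#' @export
select_gene_sets <- function(collection, keyword,
                             fields = c("name", "description")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!is.character(keyword) || !nzchar(keyword))
    stop("keyword must be a non-empty string")
  fields <- match.arg(fields, c("name", "description"), several.ok = TRUE)
  hit <- vapply(collection$sets, function(s) {
    any(vapply(fields, function(f)
      grepl(keyword, s[[f]], ignore.case = TRUE, fixed = FALSE), logical(1)))
  }, logical(1))
  structure(list(sets = collection$sets[hit]),
            class = "gene_set_collection")
}

#' Union of all member genes of a collection
#'
#' @param collection a [gene_set_collection()].
#' @return character vector of unique member symbols, in order of first
#'   appearance.
#' @export
union_genes <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(collection$sets)) stop("collection is empty")
  unique(unlist(lapply(collection$sets, `[[`, "genes"), use.names = FALSE))
}

#' Collapse a probe-level study to gene level
#'
#' Averages (arithmetic mean on the normalized-intensity scale) the probes
#' mapping to each gene, per sample. Probes absent from the map are dropped
#' with a message giving the count.
#'
#' @param study an [expression_study()] with a `probe_map`.
#' @return a gene-level [expression_study()] (`probe_map = NULL`).
#' @export
aggregate_probes <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  map <- study$probe_map
  if (is.null(map) || !nrow(map)) stop("study has no probe map")
  idx <- match(rownames(study$matrix), map$probe)
  dropped <- sum(is.na(idx))
  if (dropped > 0L)
    message(dropped, " unmapped probe(s) dropped")
  keep <- !is.na(idx)
  gene <- map$gene[idx[keep]]
  sub <- study$matrix[keep, , drop = FALSE]
  agg <- rowsum(sub, group = gene, reorder = TRUE) /
    as.vector(table(gene)[sort(unique(gene))])
  expression_study(as.matrix(agg), study$samples, probe_map = NULL)
}

#' Relative expression of suspension versus adhesion, per gene and line
#'
#' For every gene and cell line, replicate intensities are averaged per
#' condition and the relative expression is
#' `r = (mean_suspension - mean_adhesion) / mean_adhesion`, the fractional
#' change under detachment (report as a percentage via `100 * r`). Entries
#' with a zero adhesion mean are `NaN` and flagged in the `undefined`
#' column.
#'
#' @param study a gene-level [expression_study()] whose annotations use
#'   conditions `"adhesion"` and `"suspension"`.
#' @return data.frame with columns `gene`, `line`, `r`, `undefined`, class
#'   `relative_expression_table`.
#' @export
relative_expression_table <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  ann <- study$samples
  if (!all(c("adhesion", "suspension") %in% ann$condition))
    stop("study must contain both adhesion and suspension samples")
  lines <- unique(ann$line)
  out <- list()
  for (ln in lines) {
    a_cols <- ann$sample[ann$line == ln & ann$condition == "adhesion"]
    s_cols <- ann$sample[ann$line == ln & ann$condition == "suspension"]
    if (!length(a_cols) || !length(s_cols))
      stop("line '", ln, "' lacks one of the conditions")
    a_mean <- rowMeans(study$matrix[, a_cols, drop = FALSE])
    s_mean <- rowMeans(study$matrix[, s_cols, drop = FALSE])
    r <- ifelse(a_mean == 0, NaN, (s_mean - a_mean) / a_mean)
    out[[ln]] <- data.frame(gene = rownames(study$matrix), line = ln,
                            r = as.numeric(r),
                            undefined = a_mean == 0,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("relative_expression_table", "data.frame")
  res
}

#' Screen for genes changing in the same direction in every cell line
#'
#' A gene is called down when its relative expression is below `-tau` in
#' every line, up when above `+tau` in every line (strict inequalities).
#' The default `tau = 0` demands only sign agreement. Genes of the
#' universe lacking a measurement in any line are excluded from the
#' screen, with a message.
#'
#' @param table a [relative_expression_table()].
#' @param universe candidate gene symbols (non-empty).
#' @param tau non-negative relative-expression threshold.
#' @return object of class `screen_result`: list with alphabetically
#'   sorted `down` and `up` gene vectors, the screened `universe`, `tau`,
#'   and the per-gene per-line `r_table` restricted to the universe.
#' @export
consistent_direction_screen <- function(table, universe, tau = 0) {
  stopifnot(inherits(table, "relative_expression_table"), tau >= 0)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe is empty")
  tab <- table[table$gene %in% universe, , drop = FALSE]
  lines <- unique(table$line)
  counts <- table(tab$gene[is.finite(tab$r)])
  complete <- names(counts)[counts == length(lines)]
  excluded <- setdiff(universe, complete)
  if (length(excluded))
    message(length(excluded),
            " universe gene(s) lacking complete measurements excluded")
  keep <- universe[universe %in% complete]
  sub <- tab[tab$gene %in% keep, , drop = FALSE]
  dn <- tapply(sub$r < -tau, sub$gene, all)
  up <- tapply(sub$r > tau, sub$gene, all)
  structure(
    list(down = sort(names(dn)[dn]), up = sort(names(up)[up]),
         universe = keep, tau = tau, r_table = sub),
    class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("consistent-direction screen (tau = ", x$tau, "): ",
      length(x$down), " down, ", length(x$up), " up of ",
      length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Transporter panel report
#'
#' Formats the relative expression of a small gene panel (by default the
#' monocarboxylate transporters MCT1/MCT2/MCT4 and the glucose importer
#' GLUT1) per cell line as signed percentages, marking entries whose
#' magnitude reaches `bold_threshold` (the "strong change" flag). Panel
#' genes missing from the table yield blank cells with a warning.
#'
#' @param table a [relative_expression_table()].
#' @param panel named character vector: display name -> gene symbol.
#' @param bold_threshold absolute relative expression at or above which an
#'   entry is marked (default 0.35).
#' @return data.frame with columns `name`, `gene`, `line`, `r`,
#'   `percent` (formatted, e.g. `"-62.7%"`), `marked`.
#' @export
transporter_panel <- function(table,
                              panel = c(MCT1 = "SLC16A1", MCT2 = "SLC16A7",
                                        MCT4 = "SLC16A3", GLUT1 = "SLC2A1"),
                              bold_threshold = 0.35) {
  stopifnot(inherits(table, "relative_expression_table"))
  lines <- unique(table$line)
  out <- list()
  for (i in seq_along(panel)) {
    gene <- panel[[i]]
    for (ln in lines) {
      row <- table[table$gene == gene & table$line == ln, , drop = FALSE]
      if (!nrow(row)) {
        warning("panel gene '", gene, "' missing for line '", ln, "'")
        out[[length(out) + 1L]] <- data.frame(
          name = names(panel)[i], gene = gene, line = ln, r = NA_real_,
          percent = "", marked = NA, stringsAsFactors = FALSE)
      } else {
        r <- row$r[1L]
        out[[length(out) + 1L]] <- data.frame(
          name = names(panel)[i], gene = gene, line = ln, r = r,
          percent = sprintf("%+.1f%%", 100 * r),
          marked = abs(r) >= bold_threshold, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
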