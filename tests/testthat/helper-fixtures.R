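# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data files.

# segment_levels object straight from plateau values (bypasses tracing)
make_levels <- function(assay_kind, values) {
  labels <- canonical_segments(assay_kind)
  stopifnot(length(values) == length(labels))
  out <- data.frame(segment = labels, level = as.numeric(values),
                    n_points = 3L, sd = 0, stringsAsFactors = FALSE)
  attr(out, "assay_kind") <- assay_kind
  class(out) <- c("segment_levels", "data.frame")
  out
}

# relative-expression table from a genes x lines matrix of r values
make_r_table <- function(r_matrix) {
  out <- data.frame(
    gene = rep(rownames(r_matrix), times = ncol(r_matrix)),
    line = rep(colnames(r_matrix), each = nrow(r_matrix)),
    r = as.vector(r_matrix), undefined = FALSE,
    stringsAsFactors = FALSE)
  class(out) <- c("relative_expression_table", "data.frame")
  out
}

# exhaustive per-gene scan: the independent oracle for the screen
brute_force_screen <- function(r_matrix, tau) {
  down <- character(0); up <- character(0)
  for (g in rownames(r_matrix)) {
    row <- r_matrix[g, ]
    if (all(row < -tau)) down <- c(down, g)
    if (all(row > tau)) up <- c(up, g)
  }
  list(down = sort(down), up = sort(up))
}

# tiny two-condition expression study built by hand
tiny_study <- function(adh, susp, lines = c("L1", "L2")) {
  n_rep <- ncol(adh)
  mats <- list(); samp <- list()
  for (ln in lines) {
    for (cond in c("adhesion", "suspension")) {
      m <- if (cond == "adhesion") adh else susp
      colnames(m) <- sprintf("%s_%s_r%d", ln, cond, seq_len(n_rep))
      mats[[length(mats) + 1L]] <- m
      samp[[length(samp) + 1L]] <- data.frame(
        sample = colnames(m), line = ln, condition = cond,
        stringsAsFactors = FALSE)
    }
  }
  expression_study(do.call(cbind, mats), do.call(rbind, samp))
}
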