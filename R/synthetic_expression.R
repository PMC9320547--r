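# Seeded simulation of a multi-line adhesion/suspension expression study
# with planted, sign-consistent condition effects, and of keyword-named
# gene-set collections over the same gene universe.

#' Specification of a simulated expression study
#'
#' Baseline per-gene intensities are log-normal (shared across lines up to a
#' line factor); the suspension condition multiplies a planted gene's
#' intensity by `1 + effect`, with `effect` negative for `planted_down`
#' genes and positive for `planted_up` genes, drawn once per (gene, line)
#' from `effect_range` unless overridden by `planted_effects`. Measurement
#' noise is multiplicative log-normal so intensities stay strictly
#' positive.
#'
#' @param genes character vector: the gene universe (unique symbols).
#' @param lines character vector of cell-line labels.
#' @param replicates_per_condition replicates per (line, condition), >= 1.
#' @param baseline_log_mean,baseline_log_sd meanlog/sdlog of the baseline
#'   intensity distribution.
#' @param planted_down,planted_up gene symbols with planted negative /
#'   positive suspension effects; must be disjoint subsets of `genes`.
#' @param effect_range length-2 vector: min/max absolute relative change
#'   for planted genes, within (0, 1).
#' @param planted_effects optional data.frame (`gene`, `line`, `effect`)
#'   giving exact relative changes that override the drawn ones (e.g. to
#'   plant a printed reference table); effects must be > -1.
#' @param background_noise_sd SD of the multiplicative measurement noise,
#'   as a fraction (log-normal sdlog).
#' @param seed integer seed.
#' @return object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(genes, lines,
                                replicates_per_condition = 3L,
                                baseline_log_mean = log(1000),
                                baseline_log_sd = 0.6,
                                planted_down = character(0),
                                planted_up = character(0),
                                effect_range = c(0.3, 0.7),
                                planted_effects = NULL,
                                background_noise_sd = 0.05,
                                seed = 1L) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene universe has duplicates")
  if (length(intersect(planted_down, planted_up)))
    stop("planted_down and planted_up overlap")
  missing <- setdiff(c(planted_down, planted_up), genes)
  if (length(missing))
    stop("planted genes not in universe: ", paste(missing, collapse = ", "))
  if (!(length(effect_range) == 2L && effect_range[1] > 0 &&
        effect_range[1] <= effect_range[2] && effect_range[2] < 1))
    stop("effect_range must satisfy 0 < min <= max < 1")
  if (!is.null(planted_effects)) {
    stopifnot(all(c("gene", "line", "effect") %in% colnames(planted_effects)))
    if (any(planted_effects$effect <= -1))
      stop("planted effects must be > -1 (intensities are positive)")
    bad <- setdiff(planted_effects$gene, genes)
    if (length(bad)) stop("planted_effects gene not in universe: ",
                          paste(bad, collapse = ", "))
  }
  replicates_per_condition <- as.integer(replicates_per_condition)
  if (replicates_per_condition < 1L) stop("need >= 1 replicate")
  if (background_noise_sd < 0) stop("background_noise_sd must be >= 0")
  structure(
    list(genes = genes, lines = as.character(lines),
         replicates_per_condition = replicates_per_condition,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         planted_down = as.character(planted_down),
         planted_up = as.character(planted_up),
         effect_range = as.numeric(effect_range),
         planted_effects = planted_effects,
         background_noise_sd = background_noise_sd,
         seed = as.integer(seed)),
    class = "expression_sim_spec")
}

#' Simulate an expression study with planted condition effects
#'
#' @param spec an [expression_sim_spec()].
#' @return list with `study` (an [expression_study()]) and `truth`
#'   (data.frame `gene`, `line`, `effect`: the planted true relative
#'   expression of every gene in every line; 0 for non-planted genes).
#' @export
generate_expression_study <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  genes <- spec$genes; lines <- spec$lines
  nrep <- spec$replicates_per_condition
  with_rng(derive_seed(spec$seed, "expression_study"), {
    base <- stats::rlnorm(length(genes), spec$baseline_log_mean,
                          spec$baseline_log_sd)
    names(base) <- genes
    # planted effect per (gene, line): sign from the lists, magnitude drawn
    effect <- matrix(0, nrow = length(genes), ncol = length(lines),
                     dimnames = list(genes, lines))
    draw <- function(n) stats::runif(n, spec$effect_range[1],
                                     spec$effect_range[2])
    for (g in spec$planted_down) effect[g, ] <- -draw(length(lines))
    for (g in spec$planted_up) effect[g, ] <- draw(length(lines))
    if (!is.null(spec$planted_effects)) {
      pe <- spec$planted_effects
      for (i in seq_len(nrow(pe)))
        effect[pe$gene[i], pe$line[i]] <- pe$effect[i]
    }
    conditions <- c("adhesion", "suspension")
    n_samp <- length(lines) * length(conditions) * nrep
    mat <- matrix(NA_real_, nrow = length(genes), ncol = n_samp)
    rownames(mat) <- genes
    samp_names <- character(n_samp); samp_line <- character(n_samp)
    samp_cond <- character(n_samp)
    j <- 0L
    for (ln in lines) {
      line_factor <- stats::rlnorm(1, 0, 0.1)  # mild line-level scale
      for (cond in conditions) {
        mult <- if (cond == "suspension") 1 + effect[, ln] else
          rep(1, length(genes))
        for (r in seq_len(nrep)) {
          j <- j + 1L
          noise <- stats::rlnorm(length(genes), 0, spec$background_noise_sd)
          mat[, j] <- base * line_factor * mult * noise
          samp_names[j] <- sprintf("%s_%s_r%d", ln, cond, r)
          samp_line[j] <- ln; samp_cond[j] <- cond
        }
      }
    }
    colnames(mat) <- samp_names
    truth <- data.frame(
      gene = rep(genes, times = length(lines)),
      line = rep(lines, each = length(genes)),
      effect = as.vector(effect), stringsAsFactors = FALSE)
    list(study = expression_study(
           mat,
           data.frame(sample = samp_names, line = samp_line,
                      condition = samp_cond, stringsAsFactors = FALSE)),
         truth = truth)
  })
}

#' Simulate a gene-set collection with keyword-matching names
#'
#' Generates `n_sets` sets over `universe`; exactly
#' `round(n_sets * fraction_keyword_sets)` of the set names contain
#' `keyword` (upper-cased, GO-style naming). Member counts are drawn
#' uniformly from `membership_range` and members are sampled without
#' replacement within each set. With `cover_universe = TRUE` the keyword
#' sets are additionally guaranteed to jointly cover the whole universe
#' (every gene belongs to at least one keyword set), which requires
#' `membership_range` to admit the implied minimum set size.
#'
#' @param universe character vector of gene symbols.
#' @param n_sets number of sets.
#' @param keyword keyword embedded in matching set names.
#' @param fraction_keyword_sets fraction of sets whose name matches.
#' @param membership_range length-2 integer vector: min/max members.
#' @param seed integer seed.
#' @param cover_universe logical; see above.
#' @return a [gene_set_collection()].
#' @export
generate_gene_sets <- function(universe, n_sets, keyword = "glucose",
                               fraction_keyword_sets = 1,
                               membership_range = c(5L, 155L),
                               seed = 1L, cover_universe = FALSE) {
  universe <- as.character(universe)
  if (!length(universe)) stop("universe is empty")
  if (fraction_keyword_sets < 0 || fraction_keyword_sets > 1)
    stop("fraction_keyword_sets must be in [0, 1]")
  membership_range <- as.integer(membership_range)
  if (membership_range[2] > length(universe))
    stop("membership max exceeds universe size")
  if (membership_range[1] < 1L || membership_range[1] > membership_range[2])
    stop("invalid membership_range")
  n_sets <- as.integer(n_sets)
  n_kw <- as.integer(round(n_sets * fraction_keyword_sets))
  with_rng(derive_seed(seed, "gene_sets"), {
    kw <- toupper(keyword)
    names_kw <- sprintf("GOBP_%s_RELATED_PROCESS_%02d", kw, seq_len(n_kw))
    names_bg <- sprintf("GOBP_CONTROL_PROCESS_%02d",
                        seq_len(n_sets - n_kw))
    all_names <- c(names_kw, names_bg)
    sizes <- sample(seq.int(membership_range[1], membership_range[2]),
                    n_sets, replace = TRUE)
    members <- vector("list", n_sets)
    if (cover_universe && n_kw > 0L) {
      # deal the shuffled universe into the keyword sets, then pad each set
      # with extra random genes up to its drawn size
      chunks <- split(sample(universe),
                      rep_len(seq_len(n_kw), length(universe)))
      need <- max(lengths(chunks))
      if (membership_range[1] < need)
        sizes[seq_len(n_kw)] <- pmax(sizes[seq_len(n_kw)], need)
      if (max(sizes) > length(universe))
        stop("universe too small to cover with these set sizes")
      for (i in seq_len(n_kw)) {
        core <- chunks[[i]]
        extra <- sample(setdiff(universe, core), sizes[i] - length(core))
        members[[i]] <- sample(c(core, extra))
      }
    }
    for (i in seq_len(n_sets))
      if (is.null(members[[i]]))
        members[[i]] <- sample(universe, sizes[i])
    gene_set_collection(lapply(seq_len(n_sets), function(i)
      list(name = all_names[i],
           description = sprintf("synthetic gene set %02d", i),
           genes = members[[i]])))
  })
}
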