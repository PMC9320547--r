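# Seeded generators for the supporting assay tables: qPCR Ct values with
# planted fold changes, four-parameter logistic dose-response viability,
# ROS fluorescence with planted relative levels, glucose-titration cell
# counts, and lactate concentrations.

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Generates `test` and `control` groups such that the noise-free
#' 2^-ddCt of each gene (test vs control, referenced to `reference_gene`)
#' equals its planted fold: the test group's target Ct is shifted by
#' `-log2(fold)` relative to the control group's.
#'
#' @param planted_folds named numeric vector: gene symbol -> fold (> 0).
#' @param ct_ref_mean mean Ct of the reference gene (default 18).
#' @param ct_offset mean target-minus-reference Ct in the control group.
#' @param noise_sd_ct SD of additive Gaussian Ct noise.
#' @param replicates replicates per (group, gene).
#' @param reference_gene housekeeping gene label.
#' @param seed integer seed.
#' @return data.frame with columns `group`, `gene`, `replicate`, `ct`.
#' @export
generate_qpcr_table <- function(planted_folds, ct_ref_mean = 18,
                                ct_offset = 5, noise_sd_ct = 0,
                                replicates = 3L, reference_gene = "GAPDH",
                                seed = 1L) {
  if (is.null(names(planted_folds)) || any(planted_folds <= 0))
    stop("planted_folds must be a named vector of positive folds")
  if (noise_sd_ct < 0) stop("noise_sd_ct must be >= 0")
  replicates <- as.integer(replicates)
  with_rng(derive_seed(seed, "qpcr"), {
    rows <- list()
    add <- function(group, gene, mu) {
      ct <- mu + stats::rnorm(replicates, 0, noise_sd_ct)
      rows[[length(rows) + 1L]] <<- data.frame(
        group = group, gene = gene, replicate = seq_len(replicates),
        ct = ct, stringsAsFactors = FALSE)
    }
    for (grp in c("control", "test")) add(grp, reference_gene, ct_ref_mean)
    for (g in names(planted_folds)) {
      add("control", g, ct_ref_mean + ct_offset)
      add("test", g, ct_ref_mean + ct_offset - log2(planted_folds[[g]]))
    }
    do.call(rbind, rows)
  })
}

#' Simulate four-parameter logistic dose-response viability
#'
#' Mean viability at dose `d` is
#' `bottom + (top - bottom) / (1 + (d / ic50)^hill)`, so dose 0 gives
#' `top` and dose `ic50` the midpoint; replicates add Gaussian noise.
#'
#' @param doses numeric vector of doses (>= 0; include 0 for vehicle).
#' @param top,bottom asymptotic viabilities (top at dose 0).
#' @param ic50 dose of half-maximal effect, > 0.
#' @param hill Hill slope, > 0.
#' @param noise_sd SD of additive viability noise.
#' @param replicates replicates per dose.
#' @param condition,compound labels stamped on the rows.
#' @param seed integer seed.
#' @return data.frame with columns `condition`, `compound`, `dose`,
#'   `replicate`, `viability`.
#' @export
generate_dose_response <- function(doses, top = 1, bottom = 0, ic50,
                                   hill = 1, noise_sd = 0,
                                   replicates = 3L,
                                   condition = "condition",
                                   compound = "compound", seed = 1L) {
  if (!length(doses)) stop("dose list is empty")
  if (any(doses < 0)) stop("doses must be >= 0")
  if (!(ic50 > 0)) stop("ic50 must be > 0")
  if (!(hill > 0)) stop("hill must be > 0")
  replicates <- as.integer(replicates)
  mu <- bottom + (top - bottom) / (1 + (doses / ic50)^hill)
  with_rng(derive_seed(seed, paste0("dose:", condition, ":", compound)), {
    rows <- lapply(seq_along(doses), function(i) data.frame(
      condition = condition, compound = compound, dose = doses[i],
      replicate = seq_len(replicates),
      viability = mu[i] + stats::rnorm(replicates, 0, noise_sd),
      stringsAsFactors = FALSE))
    do.call(rbind, rows)
  })
}

#' Simulate a ROS fluorescence table with planted relative levels
#'
#' Control fluorescences anchor the scale (negative control at
#' `f_neg`, positive at `f_pos`); each sample's mean fluorescence is
#' placed at its planted fraction of the control span.
#'
#' @param planted_percent named numeric vector: sample -> planted relative
#'   ROS percentage.
#' @param f_neg,f_pos control mean fluorescences (arbitrary units).
#' @param noise_sd SD of additive fluorescence noise.
#' @param replicates replicate rows per sample.
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `replicate`, `fluorescence`,
#'   including `NAC` and `antimycin_A` control rows.
#' @export
generate_ros_table <- function(planted_percent, f_neg = 100, f_pos = 1100,
                               noise_sd = 0, replicates = 3L, seed = 1L) {
  if (is.null(names(planted_percent)))
    stop("planted_percent must be named by sample")
  if (f_pos == f_neg) stop("control fluorescences must differ")
  replicates <- as.integer(replicates)
  mus <- c(NAC = f_neg, antimycin_A = f_pos,
           f_neg + (f_pos - f_neg) * planted_percent / 100)
  with_rng(derive_seed(seed, "ros"), {
    rows <- lapply(names(mus), function(s) data.frame(
      sample = s, replicate = seq_len(replicates),
      fluorescence = mus[[s]] + stats::rnorm(replicates, 0, noise_sd),
      stringsAsFactors = FALSE))
    do.call(rbind, rows)
  })
}

#' Simulate glucose-titration cell counts with planted proliferation ratios
#'
#' @param planted_ratios data.frame with columns `condition`, `glucose`,
#'   `ratio`: the planted proliferation ratio at each concentration (the
#'   reference concentration should carry ratio 1).
#' @param reference_cells mean cell count at the reference concentration.
#' @param noise_sd SD of additive count noise (cells).
#' @param replicates replicates per (condition, glucose).
#' @param seed integer seed.
#' @return data.frame with columns `condition`, `glucose`, `replicate`,
#'   `cells`.
#' @export
generate_count_table <- function(planted_ratios, reference_cells = 4e5,
                                 noise_sd = 0, replicates = 3L, seed = 1L) {
  stopifnot(all(c("condition", "glucose", "ratio") %in%
                  colnames(planted_ratios)))
  if (any(planted_ratios$ratio < 0)) stop("planted ratios must be >= 0")
  replicates <- as.integer(replicates)
  with_rng(derive_seed(seed, "counts"), {
    rows <- lapply(seq_len(nrow(planted_ratios)), function(i) data.frame(
      condition = planted_ratios$condition[i],
      glucose = planted_ratios$glucose[i],
      replicate = seq_len(replicates),
      cells = pmax(0, planted_ratios$ratio[i] * reference_cells +
                     stats::rnorm(replicates, 0, noise_sd)),
      stringsAsFactors = FALSE))
    do.call(rbind, rows)
  })
}

#' Simulate replicate lactate concentrations
#'
#' @param planted_means data.frame with columns `condition`, `pH`, `mean`:
#'   planted mean concentration per cell.
#' @param noise_sd SD of additive concentration noise.
#' @param replicates replicates per (condition, pH).
#' @param seed integer seed.
#' @return data.frame with columns `condition`, `pH`, `replicate`,
#'   `concentration`.
#' @export
generate_lactate_table <- function(planted_means, noise_sd = 0,
                                   replicates = 3L, seed = 1L) {
  stopifnot(all(c("condition", "pH", "mean") %in% colnames(planted_means)))
  replicates <- as.integer(replicates)
  with_rng(derive_seed(seed, "lactate"), {
    rows <- lapply(seq_len(nrow(planted_means)), function(i) data.frame(
      condition = planted_means$condition[i], pH = planted_means$pH[i],
      replicate = seq_len(replicates),
      concentration = planted_means$mean[i] +
        stats::rnorm(replicates, 0, noise_sd),
      stringsAsFactors = FALSE))
    do.call(rbind, rows)
  })
}
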