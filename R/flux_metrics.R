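# Stress-test metric derivation from estimated segment levels, per-cell
# normalisation, the OCR/ECAR ratio, and condition comparisons.

GLYCO_RATE_FIELDS <- c("non_glycolytic_acidification", "basal_glycolysis",
                       "glycolytic_capacity", "glycolytic_reserve")
MITO_RATE_FIELDS <- c("non_mitochondrial_ocr", "basal_respiration",
                      "atp_linked_respiration", "proton_leak",
                      "maximal_respiration", "spare_capacity")

#' Glycolysis stress-test metrics from segment levels
#'
#' Derives, from the four ECAR plateau levels (glucose-free baseline, after
#' glucose, after oligomycin, after 2-deoxyglucose):
#' non-glycolytic acidification (baseline), basal glycolysis
#' (glucose - baseline), glycolytic capacity (oligomycin - baseline),
#' glycolytic reserve (capacity - basal) and the utilization fraction
#' (basal / capacity). Negative derived values are reported as computed and
#' flagged, never clamped: a negative rate is an assay-quality signal.
#'
#' @param levels a `segment_levels` object from a glycolysis stress trace.
#' @return object of class `glycolysis_metrics`: named list of rates
#'   (mpH/min), `utilization_fraction`, and a character vector `flags`.
#' @export
glycolysis_stress_metrics <- function(levels) {
  if (!identical(attr(levels, "assay_kind"), "glycolysis_stress"))
    stop("levels are not from a glycolysis stress test")
  baseline <- seg_level(levels, "baseline")
  glucose <- seg_level(levels, "glucose")
  oligo <- seg_level(levels, "oligomycin")
  basal <- glucose - baseline
  capacity <- oligo - baseline
  flags <- character(0)
  m <- list(
    non_glycolytic_acidification = baseline,
    basal_glycolysis = basal,
    glycolytic_capacity = capacity,
    glycolytic_reserve = capacity - basal,
    utilization_fraction = if (capacity > 0) basal / capacity else NaN)
  if (any(unlist(m[GLYCO_RATE_FIELDS]) < 0))
    flags <- c(flags, "negative_derived_rate")
  if (capacity <= 0) flags <- c(flags, "utilization_undefined")
  m$flags <- flags
  structure(m, class = "glycolysis_metrics")
}

#' Mitochondrial stress-test metrics from segment levels
#'
#' Derives, from the four OCR plateau levels (baseline, after oligomycin,
#' after FCCP, after rotenone/antimycin A): non-mitochondrial OCR (the
#' rotenone/antimycin level), basal respiration (baseline - non-mito),
#' ATP-linked respiration (baseline - oligomycin), proton leak
#' (oligomycin - non-mito), maximal respiration (FCCP - non-mito), spare
#' capacity (maximal - basal) and the utilization fraction
#' (basal / maximal). By construction ATP-linked + proton leak = basal and
#' spare = maximal - basal, exactly.
#'
#' @param levels a `segment_levels` object from a mitochondrial stress trace.
#' @return object of class `mito_metrics`: named list of rates
#'   (pmol O2/min), `utilization_fraction`, and `flags`.
#' @export
mito_stress_metrics <- function(levels) {
  if (!identical(attr(levels, "assay_kind"), "mito_stress"))
    stop("levels are not from a mitochondrial stress test")
  baseline <- seg_level(levels, "baseline")
  oligo <- seg_level(levels, "oligomycin")
  fccp <- seg_level(levels, "FCCP")
  non_mito <- seg_level(levels, "rotenone_antimycin")
  basal <- baseline - non_mito
  maximal <- fccp - non_mito
  flags <- character(0)
  m <- list(
    non_mitochondrial_ocr = non_mito,
    basal_respiration = basal,
    atp_linked_respiration = baseline - oligo,
    proton_leak = oligo - non_mito,
    maximal_respiration = maximal,
    spare_capacity = maximal - basal,
    utilization_fraction = if (maximal != 0) basal / maximal else NaN)
  if (any(unlist(m[MITO_RATE_FIELDS]) < 0))
    flags <- c(flags, "negative_derived_rate")
  if (maximal == 0) flags <- c(flags, "utilization_undefined")
  m$flags <- flags
  structure(m, class = "mito_metrics")
}

#' Normalize stress-test metrics per a fixed number of cells
#'
#' Rescales every rate field by `unit_cells / cell_count`; the utilization
#' fraction is a ratio of rates and is left untouched (it is invariant
#' under any uniform rescaling).
#'
#' @param metrics a `glycolysis_metrics` or `mito_metrics` object.
#' @param cell_count post-run cell count of the well, > 0.
#' @param unit_cells reference cell number (default 1e4).
#' @return metrics of the same class, per `unit_cells` cells.
#' @export
normalize_per_cells <- function(metrics, cell_count, unit_cells = 1e4) {
  if (!(is.numeric(cell_count) && length(cell_count) == 1L && cell_count > 0))
    stop("cell_count must be a single positive number")
  fields <- if (inherits(metrics, "glycolysis_metrics")) GLYCO_RATE_FIELDS
            else if (inherits(metrics, "mito_metrics")) MITO_RATE_FIELDS
            else stop("not a stress-test metrics object")
  f <- unit_cells / cell_count
  for (fl in fields) metrics[[fl]] <- metrics[[fl]] * f
  metrics
}

#' OCR/ECAR ratio: mitochondrial versus glycolytic pathway preference
#'
#' The ratio of basal respiration to basal glycolysis, both cell-normalized
#' with the same unit; higher values indicate reliance on oxidative
#' phosphorylation over glycolysis.
#'
#' @param mito a `mito_metrics` object.
#' @param glyco a `glycolysis_metrics` object from the paired well/condition.
#' @return a single number, or `NaN` (with a warning) when basal glycolysis
#'   is not positive.
#' @export
ocr_ecar_ratio <- function(mito, glyco) {
  stopifnot(inherits(mito, "mito_metrics"),
            inherits(glyco, "glycolysis_metrics"))
  if (!(glyco$basal_glycolysis > 0)) {
    warning("basal glycolysis <= 0; OCR/ECAR ratio undefined")
    return(NaN)
  }
  mito$basal_respiration / glyco$basal_glycolysis
}

# flatten one metrics object to a long data.frame
metrics_rows <- function(metrics, well, condition) {
  fields <- setdiff(names(metrics), "flags")
  data.frame(condition = condition, well = well, metric = fields,
             value = unlist(metrics[fields], use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Compare stress-test metrics between conditions
#'
#' Summarises a long per-well metric table (columns `condition`, `well`,
#' `metric`, `value`) per condition: arithmetic mean, sample SD, fold over
#' the reference condition's mean, and a two-sided Welch t-test against the
#' reference. Conditions with fewer than two wells get no SD or p-value
#' (with a warning).
#'
#' @param per_well long data.frame of per-well metric values.
#' @param reference reference condition label (default: first condition in
#'   order of appearance).
#' @return data.frame with columns `metric`, `condition`, `n`, `mean`,
#'   `sd`, `fold`, `p_value`.
#' @export
compare_conditions <- function(per_well, reference = NULL) {
  stopifnot(all(c("condition", "well", "metric", "value") %in%
                  colnames(per_well)))
  conds <- unique(per_well$condition)
  if (is.null(reference)) reference <- conds[1L]
  if (!reference %in% conds) stop("reference condition not present")
  out <- list()
  for (met in unique(per_well$metric)) {
    sub <- per_well[per_well$metric == met, , drop = FALSE]
    ref_vals <- sub$value[sub$condition == reference]
    for (cond in conds) {
      v <- sub$value[sub$condition == cond]
      p <- NA_real_
      if (cond != reference) {
        if (length(v) >= 2L && length(ref_vals) >= 2L &&
            stats::sd(v) + stats::sd(ref_vals) > 0) {
          p <- stats::t.test(v, ref_vals, var.equal = FALSE)$p.value
        } else if (length(v) < 2L || length(ref_vals) < 2L) {
          warning("fewer than 2 wells for metric '", met,
                  "'; Welch test skipped")
        } else {
          p <- 1  # identical constant groups: no evidence of difference
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        metric = met, condition = cond, n = length(v),
        mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
        fold = mean(v) / mean(ref_vals),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-well metrics and condition summary for a flux plate
#'
#' Runs [segment_trace()] and the appropriate metric derivation on every
#' trace of a plate, normalizes per `unit_cells` cells, and summarises
#' conditions with [compare_conditions()].
#'
#' @param plate a `flux_plate` from [generate_flux_experiment()] or
#'   [read_flux_plate()].
#' @param k terminal cycles averaged per segment (see [segment_trace()]).
#' @param unit_cells reference cell number for normalisation.
#' @param reference reference condition for folds and tests.
#' @return list with `per_well` (long data.frame) and `summary`
#'   (see [compare_conditions()]).
#' @export
flux_metrics_report <- function(plate, k = 3L, unit_cells = 1e4,
                                reference = NULL) {
  stopifnot(inherits(plate, "flux_plate"))
  rows <- lapply(seq_along(plate$traces), function(i) {
    tr <- plate$traces[[i]]
    lv <- segment_trace(tr, k = k)
    m <- if (tr$schedule$assay_kind == "glycolysis_stress")
      glycolysis_stress_metrics(lv) else mito_stress_metrics(lv)
    m <- normalize_per_cells(m, tr$cell_count, unit_cells)
    metrics_rows(m, tr$well, plate$conditions[i])
  })
  per_well <- do.call(rbind, rows)
  list(per_well = per_well,
       summary = compare_conditions(per_well, reference = reference))
}

#' OCR/ECAR ratio comparison between two conditions
#'
#' Pairs the wells of a mitochondrial-stress plate with those of a
#' glycolysis-stress plate (by order within condition), computes the
#' per-pair OCR/ECAR ratio on cell-normalized metrics, and reports the
#' per-condition mean ratio and the fold of each condition over the
#' reference.
#'
#' @param mito_plate,glyco_plate `flux_plate` objects with the same
#'   conditions and well counts.
#' @param k,unit_cells see [flux_metrics_report()].
#' @param reference reference condition (default first).
#' @return data.frame with columns `condition`, `n`, `ratio_mean`,
#'   `ratio_sd`, `fold`.
#' @export
ocr_ecar_comparison <- function(mito_plate, glyco_plate, k = 3L,
                                unit_cells = 1e4, reference = NULL) {
  stopifnot(inherits(mito_plate, "flux_plate"),
            inherits(glyco_plate, "flux_plate"))
  conds <- unique(mito_plate$conditions)
  if (!setequal(conds, unique(glyco_plate$conditions)))
    stop("plates do not share the same conditions")
  if (is.null(reference)) reference <- conds[1L]
  one <- function(plate, i) {
    tr <- plate$traces[[i]]
    lv <- segment_trace(tr, k = k)
    m <- if (tr$schedule$assay_kind == "glycolysis_stress")
      glycolysis_stress_metrics(lv) else mito_stress_metrics(lv)
    normalize_per_cells(m, tr$cell_count, unit_cells)
  }
  rows <- lapply(conds, function(cond) {
    im <- which(mito_plate$conditions == cond)
    ig <- which(glyco_plate$conditions == cond)
    n <- min(length(im), length(ig))
    ratios <- vapply(seq_len(n), function(j)
      ocr_ecar_ratio(one(mito_plate, im[j]), one(glyco_plate, ig[j])),
      numeric(1))
    data.frame(condition = cond, n = n, ratio_mean = mean(ratios),
               ratio_sd = if (n > 1L) stats::sd(ratios) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fold <- out$ratio_mean / out$ratio_mean[out$condition == reference]
  out
}
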