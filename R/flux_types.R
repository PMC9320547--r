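# Container types for extracellular-flux stress-test data: injection
# schedules, per-well rate traces, and estimated segment plateau levels.

#' Canonical injection compounds per stress-test kind
#'
#' Glycolysis stress tests start glucose-free and inject glucose, then
#' oligomycin (ATP-synthase block reveals glycolytic capacity), then
#' 2-deoxyglucose (shuts glycolysis down). Mitochondrial stress tests inject
#' oligomycin (ATP-linked respiration), then FCCP (uncoupled, maximal
#' respiration), then rotenone plus antimycin A (non-mitochondrial oxygen
#' consumption).
#'
#' @param assay_kind `"glycolysis_stress"` or `"mito_stress"`.
#' @return character vector of the three injected compounds, in order.
#' @export
canonical_compounds <- function(assay_kind) {
  switch(match.arg(assay_kind, c("glycolysis_stress", "mito_stress")),
    glycolysis_stress = c("glucose", "oligomycin", "2DG"),
    mito_stress       = c("oligomycin", "FCCP", "rotenone_antimycin"))
}

#' Segment labels implied by an assay kind (baseline + injected compounds)
#' @inheritParams canonical_compounds
#' @return character vector of length 4.
#' @export
canonical_segments <- function(assay_kind) {
  c("baseline", canonical_compounds(assay_kind))
}

#' Construct an injection schedule
#'
#' @param assay_kind `"glycolysis_stress"` or `"mito_stress"`.
#' @param after_cycle integer vector, strictly increasing: the measurement
#'   cycle after which each canonical compound is injected. The cycle at an
#'   injection index belongs to the preceding segment (segments are
#'   half-open on the right).
#' @return object of class `injection_schedule`.
#' @export
injection_schedule <- function(assay_kind, after_cycle) {
  assay_kind <- match.arg(assay_kind, c("glycolysis_stress", "mito_stress"))
  compounds <- canonical_compounds(assay_kind)
  after_cycle <- as.integer(after_cycle)
  if (length(after_cycle) != length(compounds))
    stop("need one injection cycle per compound (", length(compounds), ")")
  if (any(after_cycle < 1L) || any(diff(after_cycle) <= 0L))
    stop("injection cycle indices must be positive and strictly increasing")
  structure(
    list(assay_kind = assay_kind, compound = compounds,
         after_cycle = after_cycle),
    class = "injection_schedule")
}

#' Construct a single-well flux trace
#'
#' @param well well identifier.
#' @param kind `"ECAR"` (mpH/min) or `"OCR"` (pmol O2/min).
#' @param time_min numeric vector of measurement times in minutes, strictly
#'   increasing.
#' @param rate numeric vector of rates, same length as `time_min`.
#' @param schedule an [injection_schedule()].
#' @param cell_count post-run cell count for the well, > 0.
#' @return object of class `flux_trace`.
#' @export
flux_trace <- function(well, kind, time_min, rate, schedule, cell_count) {
  kind <- match.arg(kind, c("ECAR", "OCR"))
  stopifnot(inherits(schedule, "injection_schedule"))
  if (length(time_min) != length(rate))
    stop("time and rate vectors differ in length")
  if (length(time_min) < 1L || any(diff(time_min) <= 0))
    stop("timepoints must be non-empty and strictly increasing")
  if (!all(is.finite(rate))) stop("rates must be finite")
  if (max(schedule$after_cycle) >= length(rate))
    stop("last injection leaves no post-injection cycles in the trace")
  cell_count <- as.integer(cell_count)
  if (is.na(cell_count) || cell_count <= 0L) stop("cell_count must be > 0")
  structure(
    list(well = as.character(well), kind = kind,
         time_min = as.numeric(time_min), rate = as.numeric(rate),
         schedule = schedule, cell_count = cell_count),
    class = "flux_trace")
}

# cycle index ranges of each segment, as a named list
segment_cycles <- function(schedule, n_cycles) {
  bounds <- c(0L, schedule$after_cycle, n_cycles)
  labels <- c("baseline", schedule$compound)
  out <- vector("list", length(labels))
  names(out) <- labels
  for (s in seq_along(labels)) {
    lo <- bounds[s] + 1L
    hi <- bounds[s + 1L]
    if (hi < lo) stop("segment '", labels[s], "' has no measurement cycles")
    out[[s]] <- lo:hi
  }
  out
}

#' Estimate plateau levels of every trace segment
#'
#' Each segment's level is the mean of its last `min(k, n)` measurement
#' cycles, which for segments longer than `k` cycles discards the
#' equilibration transient immediately after the injection.
#'
#' @param trace a [flux_trace()].
#' @param k number of terminal cycles averaged per segment (default 3,
#'   the usual number of measurement cycles between injections).
#' @return a `segment_levels` data.frame with columns `segment`, `level`,
#'   `n_points`, `sd`, and an `assay_kind` attribute.
#' @export
segment_trace <- function(trace, k = 3L) {
  stopifnot(inherits(trace, "flux_trace"), k >= 1L)
  segs <- segment_cycles(trace$schedule, length(trace$rate))
  rows <- lapply(names(segs), function(lbl) {
    idx <- segs[[lbl]]
    use <- idx[seq.int(max(1L, length(idx) - k + 1L), length(idx))]
    x <- trace$rate[use]
    data.frame(segment = lbl, level = mean(x), n_points = length(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "assay_kind") <- trace$schedule$assay_kind
  class(out) <- c("segment_levels", "data.frame")
  out
}

# look one level up by segment label, with a clear error
seg_level <- function(levels, label) {
  i <- match(label, levels$segment)
  if (is.na(i)) stop("no segment '", label, "' in levels")
  levels$level[i]
}
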