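# Seeded simulation of extracellular-flux stress-test plates: segment-plateau
# traces with Gaussian measurement noise and optional linear drift, plus the
# planted ground truth needed for estimator-recovery tests.

#' Specification of a simulated stress-test trace
#'
#' @param assay_kind `"glycolysis_stress"` or `"mito_stress"`.
#' @param plateaus numeric vector of 4 non-negative segment plateau rates,
#'   named with [canonical_segments()] labels (names optional: positional
#'   order is baseline then the injections, in canonical order).
#' @param cycles_per_segment measurement cycles per segment, >= 1.
#' @param cycle_interval_min minutes between cycles, > 0.
#' @param noise_sd SD of additive Gaussian measurement noise, rate units.
#' @param drift_per_cycle additive drift per global cycle (default 0).
#' @param cell_count planted post-run cell count, > 0.
#' @param seed integer seed; the trace is a pure function of this spec.
#' @return object of class `flux_sim_spec`.
#' @export
flux_sim_spec <- function(assay_kind, plateaus, cycles_per_segment = 3L,
                          cycle_interval_min = 7, noise_sd = 0,
                          drift_per_cycle = 0, cell_count = 5e4, seed = 1L) {
  assay_kind <- match.arg(assay_kind, c("glycolysis_stress", "mito_stress"))
  labels <- canonical_segments(assay_kind)
  if (length(plateaus) != length(labels))
    stop("need ", length(labels), " plateaus (one per segment)")
  if (is.null(names(plateaus))) names(plateaus) <- labels
  if (!identical(names(plateaus), labels))
    plateaus <- plateaus[labels]
  if (anyNA(plateaus) || any(plateaus < 0))
    stop("plateaus must be named by canonical segments and be >= 0")
  cycles_per_segment <- as.integer(cycles_per_segment)
  if (is.na(cycles_per_segment) || cycles_per_segment < 1L)
    stop("cycles_per_segment must be >= 1")
  if (!(cycle_interval_min > 0)) stop("cycle_interval_min must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!(cell_count > 0)) stop("cell_count must be > 0")
  structure(
    list(assay_kind = assay_kind, plateaus = plateaus,
         cycles_per_segment = cycles_per_segment,
         cycle_interval_min = as.numeric(cycle_interval_min),
         noise_sd = as.numeric(noise_sd),
         drift_per_cycle = as.numeric(drift_per_cycle),
         cell_count = as.integer(cell_count), seed = as.integer(seed)),
    class = "flux_sim_spec")
}

#' Simulate one stress-test trace
#'
#' Measurement `i` in segment `s` is
#' `plateau_s + drift_per_cycle * (i - 1) + N(0, noise_sd)` with `i` the
#' global cycle index. The injection schedule places each injection after
#' the last cycle of its preceding segment.
#'
#' @param spec a [flux_sim_spec()].
#' @param well well label.
#' @param stream extra label mixed into the seed so several wells can be
#'   drawn from one spec without sharing noise.
#' @return a [flux_trace()] (kind `"ECAR"` for glycolysis stress, `"OCR"`
#'   for mitochondrial stress).
#' @export
generate_flux_trace <- function(spec, well = "A01", stream = "trace") {
  stopifnot(inherits(spec, "flux_sim_spec"))
  n_seg <- length(spec$plateaus)
  n <- n_seg * spec$cycles_per_segment
  truth <- rep(spec$plateaus, each = spec$cycles_per_segment)
  drift <- spec$drift_per_cycle * (seq_len(n) - 1)
  noise <- with_rng(derive_seed(spec$seed, paste0(stream, ":", well)),
                    stats::rnorm(n, 0, spec$noise_sd))
  sched <- injection_schedule(
    spec$assay_kind,
    after_cycle = spec$cycles_per_segment * seq_len(n_seg - 1L))
  flux_trace(
    well = well,
    kind = if (spec$assay_kind == "glycolysis_stress") "ECAR" else "OCR",
    time_min = spec$cycle_interval_min * seq_len(n),
    rate = as.numeric(truth + drift + noise),
    schedule = sched, cell_count = spec$cell_count)
}

#' Simulate a multi-well, multi-condition flux plate
#'
#' @param condition_specs named list mapping condition label to a
#'   [flux_sim_spec()]; all specs must share the assay kind.
#' @param wells_per_condition wells simulated per condition, >= 1.
#' @return object of class `flux_plate`: list with `traces` (list of
#'   [flux_trace()]), parallel `conditions` vector, and `truth` (planted
#'   plateau levels per condition).
#' @export
generate_flux_experiment <- function(condition_specs,
                                     wells_per_condition = 3L) {
  if (length(condition_specs) < 1L || is.null(names(condition_specs)))
    stop("condition_specs must be a named list with >= 1 condition")
  if (anyDuplicated(names(condition_specs)))
    stop("duplicate condition labels")
  kinds <- vapply(condition_specs, `[[`, "", "assay_kind")
  if (length(unique(kinds)) != 1L)
    stop("all condition specs must share one assay kind")
  wells_per_condition <- as.integer(wells_per_condition)
  if (wells_per_condition < 1L) stop("wells_per_condition must be >= 1")
  traces <- list(); conditions <- character(0)
  for (cond in names(condition_specs)) {
    spec <- condition_specs[[cond]]
    for (w in seq_len(wells_per_condition)) {
      well <- sprintf("%s_w%02d", cond, w)
      traces[[length(traces) + 1L]] <- generate_flux_trace(spec, well = well)
      conditions <- c(conditions, cond)
    }
  }
  wells <- vapply(traces, `[[`, "", "well")
  if (anyDuplicated(wells)) stop("duplicate well labels on plate")
  truth <- lapply(condition_specs, function(s)
    list(plateaus = s$plateaus, cell_count = s$cell_count,
         noise_sd = s$noise_sd, drift_per_cycle = s$drift_per_cycle))
  structure(list(traces = traces, conditions = conditions, truth = truth),
            class = "flux_plate")
}

#' Write / read a flux plate as plain TSV files
#'
#' `write_flux_plate()` writes three tables: the plate (one row per well and
#' cycle: `well`, `condition`, `kind`, `cycle`, `time_min`, `rate`), the
#' schedule (`assay_kind`, `compound`, `after_cycle`) and the cell counts
#' (`well`, `cells`). `read_flux_plate()` reconstructs the `flux_plate`.
#'
#' @param plate a `flux_plate`.
#' @param plate_tsv,schedule_tsv,cells_tsv file paths.
#' @return `read_flux_plate()` returns a `flux_plate` (without simulation
#'   ground truth); `write_flux_plate()` returns the paths, invisibly.
#' @export
write_flux_plate <- function(plate, plate_tsv, schedule_tsv, cells_tsv) {
  stopifnot(inherits(plate, "flux_plate"))
  rows <- lapply(seq_along(plate$traces), function(i) {
    tr <- plate$traces[[i]]
    data.frame(well = tr$well, condition = plate$conditions[i],
               kind = tr$kind, cycle = seq_along(tr$rate),
               time_min = tr$time_min, rate = tr$rate,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), plate_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sch <- plate$traces[[1L]]$schedule
  utils::write.table(
    data.frame(assay_kind = sch$assay_kind, compound = sch$compound,
               after_cycle = sch$after_cycle, stringsAsFactors = FALSE),
    schedule_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  cells <- data.frame(
    well = vapply(plate$traces, `[[`, "", "well"),
    cells = vapply(plate$traces, function(t) t$cell_count, integer(1)),
    stringsAsFactors = FALSE)
  utils::write.table(cells, cells_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(plate_tsv, schedule_tsv, cells_tsv))
}

#' @rdname write_flux_plate
#' @export
read_flux_plate <- function(plate_tsv, schedule_tsv, cells_tsv) {
  tab <- utils::read.delim(plate_tsv, stringsAsFactors = FALSE)
  sch_tab <- utils::read.delim(schedule_tsv, stringsAsFactors = FALSE)
  cells <- utils::read.delim(cells_tsv, stringsAsFactors = FALSE)
  sched <- injection_schedule(sch_tab$assay_kind[1L], sch_tab$after_cycle)
  wells <- unique(tab$well)
  traces <- list(); conditions <- character(0)
  for (w in wells) {
    sub <- tab[tab$well == w, , drop = FALSE]
    sub <- sub[order(sub$cycle), , drop = FALSE]
    cc <- cells$cells[match(w, cells$well)]
    if (is.na(cc)) stop("no cell count for well '", w, "'")
    traces[[length(traces) + 1L]] <- flux_trace(
      well = w, kind = sub$kind[1L], time_min = sub$time_min,
      rate = sub$rate, schedule = sched, cell_count = cc)
    conditions <- c(conditions, sub$condition[1L])
  }
  structure(list(traces = traces, conditions = conditions, truth = NULL),
            class = "flux_plate")
}
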