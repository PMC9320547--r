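# End-to-end pipeline: simulate the mirror fixture (or read user tables),
# derive flux metrics, run the keyword/consistent-direction screen,
# quantify the supporting assays, and write TSV outputs plus a manifest
# and a human-readable report.

#' Pipeline configuration
#'
#' @param seed integer master seed; every simulated table draws from a
#'   stream derived from it.
#' @param tau consistent-direction threshold for the screen (fractional
#'   relative expression; default 0.1, see the methods vignette for the
#'   power argument).
#' @param k terminal cycles averaged per trace segment.
#' @param unit_cells reference cell number for flux normalisation.
#' @param bold_threshold transporter-panel marking threshold.
#' @param keyword gene-set selection keyword.
#' @param wells_per_condition flux wells simulated per condition.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, tau = 0.1, k = 3L,
                            unit_cells = 1e4, bold_threshold = 0.35,
                            keyword = "glucose",
                            wells_per_condition = 3L) {
  stopifnot(tau >= 0, k >= 1L, unit_cells > 0, bold_threshold >= 0,
            nzchar(keyword), wells_per_condition >= 1L)
  structure(list(seed = as.integer(seed), tau = tau, k = as.integer(k),
                 unit_cells = unit_cells, bold_threshold = bold_threshold,
                 keyword = keyword,
                 wells_per_condition = as.integer(wells_per_condition)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nrow(df)
}

#' Run the simulate-analyze-report pipeline on the mirror fixture
#'
#' Simulates flux plates, the expression study, gene sets and assay tables
#' from `config$seed`, runs every analysis stage, and writes TSV outputs,
#' ground-truth sidecars, a JSON manifest and a plain-text report to
#' `out_dir`. Outputs are a pure function of the config (seed included);
#' partial outputs are removed if a stage fails.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; must not be an existing
#'   non-empty directory unless `overwrite = TRUE`).
#' @param overwrite replace existing outputs.
#' @return invisibly, a list of the in-memory stage results (`flux_mito`,
#'   `flux_glyco`, `ocr_ecar`, `screen`, `panel`, `assays`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("output directory exists and is not empty: ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(out_dir, written)))
  warnings_log <- character(0)
  log_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  rowcounts <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    rowcounts[[name]] <<- write_tsv(df, path)
    written <<- c(written, name)
  }
  seed <- config$seed

  res <- withCallingHandlers({
    # --- flux stage ---------------------------------------------------
    specs <- mirror_flux_specs(seed)
    mito_plate <- generate_flux_experiment(specs$mito,
                                           config$wells_per_condition)
    glyco_plate <- generate_flux_experiment(specs$glyco,
                                            config$wells_per_condition)
    mito_rep <- flux_metrics_report(mito_plate, k = config$k,
                                    unit_cells = config$unit_cells,
                                    reference = "adherent")
    glyco_rep <- flux_metrics_report(glyco_plate, k = config$k,
                                     unit_cells = config$unit_cells,
                                     reference = "adherent")
    ratio_tab <- ocr_ecar_comparison(mito_plate, glyco_plate,
                                     k = config$k,
                                     unit_cells = config$unit_cells,
                                     reference = "adherent")
    emit(mito_rep$per_well, "flux_mito_per_well.tsv")
    emit(mito_rep$summary, "flux_mito_summary.tsv")
    emit(glyco_rep$per_well, "flux_glyco_per_well.tsv")
    emit(glyco_rep$summary, "flux_glyco_summary.tsv")
    emit(ratio_tab, "ocr_ecar_ratio.tsv")
    flux_truth <- do.call(rbind, lapply(names(specs$mito), function(cond)
      data.frame(assay = "mito_stress", condition = cond,
                 segment = names(specs$mito[[cond]]$plateaus),
                 plateau = as.numeric(specs$mito[[cond]]$plateaus),
                 stringsAsFactors = FALSE)))
    glyco_truth <- do.call(rbind, lapply(names(specs$glyco), function(cond)
      data.frame(assay = "glycolysis_stress", condition = cond,
                 segment = names(specs$glyco[[cond]]$plateaus),
                 plateau = as.numeric(specs$glyco[[cond]]$plateaus),
                 stringsAsFactors = FALSE)))
    emit(rbind(flux_truth, glyco_truth), "ground_truth_flux.tsv")

    # --- screen stage -------------------------------------------------
    sets <- mirror_gene_sets(seed)
    gmt_path <- file.path(out_dir, "gene_sets.gmt")
    write_gmt(sets, gmt_path)
    written <- c(written, "gene_sets.gmt")
    selected <- select_gene_sets(sets, config$keyword)
    universe <- union_genes(selected)
    sim <- generate_expression_study(mirror_expression_spec(seed))
    rel <- relative_expression_table(sim$study)
    screen <- consistent_direction_screen(rel, universe, tau = config$tau)
    panel <- transporter_panel(rel,
                               bold_threshold = config$bold_threshold)
    calls <- data.frame(gene = screen$universe, stringsAsFactors = FALSE)
    calls$call <- ifelse(calls$gene %in% screen$down, "down",
                         ifelse(calls$gene %in% screen$up, "up", "none"))
    rel_out <- rel
    rel_out$percent <- sprintf("%+.1f%%", 100 * rel_out$r)
    emit(rel_out, "relative_expression.tsv")
    emit(calls, "screen_calls.tsv")
    emit(panel, "transporter_panel.tsv")
    emit(sim$truth, "ground_truth_expression.tsv")

    # --- assay stage --------------------------------------------------
    assays <- mirror_assay_tables(seed)
    mct4 <- ddct_fold(assays$qpcr, "SLC16A3", "test", "control")
    glut1 <- ddct_fold(assays$qpcr, "SLC2A1", "test", "control")
    prolif <- proliferation_ratio(assays$counts)
    lac <- relative_lactate(assays$lactate)
    sens_2dg <- sensitivity_contrast(assays$viability, "adherent",
                                     "suspended", "2DG")
    sens_rot <- sensitivity_contrast(assays$viability, "adherent",
                                     "suspended", "rotenone")
    sx_fold <- ros_fold(assays$ros, "superoxide_suspended",
                        "superoxide_adherent")
    ros_fold_v <- ros_fold(assays$ros, "ros_suspended", "ros_adherent")
    tidy <- rbind(
      data.frame(assay = "qpcr", condition = "suspension",
                 quantity = c("MCT4_fold", "GLUT1_fold"),
                 estimate = c(mct4$fold, glut1$fold),
                 sd = c(mct4$sd_ddct, glut1$sd_ddct),
                 p_value = NA_real_, stringsAsFactors = FALSE),
      data.frame(assay = "proliferation", condition = prolif$condition,
                 quantity = sprintf("ratio_glucose_%g", prolif$glucose),
                 estimate = prolif$ratio, sd = NA_real_,
                 p_value = NA_real_, stringsAsFactors = FALSE),
      data.frame(assay = "lactate", condition = "suspended_vs_adherent",
                 quantity = sprintf("fold_pH_%g", lac$comparison$pH),
                 estimate = lac$comparison$fold, sd = NA_real_,
                 p_value = lac$comparison$p_value,
                 stringsAsFactors = FALSE),
      data.frame(assay = "ros", condition = "suspended_vs_adherent",
                 quantity = c("superoxide_fold", "ros_fold"),
                 estimate = c(sx_fold, ros_fold_v), sd = NA_real_,
                 p_value = NA_real_, stringsAsFactors = FALSE),
      data.frame(assay = "sensitivity",
                 condition = "adherent_minus_suspended",
                 quantity = c("delta_score_2DG", "delta_score_rotenone"),
                 estimate = c(sens_2dg$delta, sens_rot$delta),
                 sd = NA_real_, p_value = NA_real_,
                 stringsAsFactors = FALSE))
    emit(tidy, "assay_estimates.tsv")

    list(flux_mito = mito_rep, flux_glyco = glyco_rep,
         ocr_ecar = ratio_tab, screen = screen, panel = panel,
         assays = tidy)
  }, warning = log_warn)

  # --- manifest and report -------------------------------------------
  manifest <- list(
    tool = "anoikisflux",
    version = as.character(utils::packageVersion("anoikisflux")),
    seed = config$seed, config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    row_counts = rowcounts, warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, "manifest.json")
  report_path <- file.path(out_dir, "report.txt")
  writeLines(render_report(res, config), report_path)
  written <- c(written, "report.txt")
  res$manifest <- manifest
  ok <- TRUE
  invisible(res)
}

# plain-text, paper-style summary of a pipeline run
render_report <- function(res, config) {
  pct <- function(x) sprintf("%+.1f%%", 100 * x)
  s <- res$flux_mito$summary
  g <- res$flux_glyco$summary
  pick <- function(df, metric, cond)
    df$mean[df$metric == metric & df$condition == cond]
  lines <- c(
    "Detachment-stress bioenergetics report",
    "======================================",
    "",
    sprintf("Mitochondrial stress test (per %g cells):", config$unit_cells),
    sprintf("  utilization  adherent %.3f  suspended %.3f",
            pick(s, "utilization_fraction", "adherent"),
            pick(s, "utilization_fraction", "suspended")),
    sprintf("  spare capacity  adherent %.2f  suspended %.2f",
            pick(s, "spare_capacity", "adherent"),
            pick(s, "spare_capacity", "suspended")),
    sprintf("  maximal respiration fold (susp/adh): %.2f",
            s$fold[s$metric == "maximal_respiration" &
                     s$condition == "suspended"]),
    "",
    "Glycolysis stress test:",
    sprintf("  utilization  adherent %.3f  suspended %.3f",
            pick(g, "utilization_fraction", "adherent"),
            pick(g, "utilization_fraction", "suspended")),
    sprintf("OCR/ECAR ratio fold (susp/adh): %.2f",
            res$ocr_ecar$fold[res$ocr_ecar$condition == "suspended"]),
    "",
    sprintf("Consistent-direction screen (tau = %g):", config$tau),
    sprintf("  down (%d): %s", length(res$screen$down),
            paste(res$screen$down, collapse = ", ")),
    sprintf("  up   (%d): %s", length(res$screen$up),
            paste(res$screen$up, collapse = ", ")),
    "",
    "Transporter panel (relative expression, suspension vs adhesion):")
  pan <- res$panel
  for (nm in unique(pan$name)) {
    sub <- pan[pan$name == nm, ]
    cells <- sprintf("%s%s", ifelse(sub$marked, "*", " "), sub$percent)
    lines <- c(lines, sprintf("  %-5s (%s): %s", nm, sub$gene[1L],
                              paste(sprintf("%s=%s", sub$line, cells),
                                    collapse = "  ")))
  }
  a <- res$assays
  lines <- c(lines, "",
             "Supporting assays:",
             sprintf("  %s / %s: %.3f", a$assay, a$quantity, a$estimate))
  lines
}
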