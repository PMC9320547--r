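# Plateau estimation, stress-test metric arithmetic, normalisation,
# OCR/ECAR ratio, condition comparison and plate TSV round trips.

test_that("segment levels are exact on noise-free traces", {
  spec <- flux_sim_spec("glycolysis_stress", c(10, 40, 60, 4),
                        noise_sd = 0)
  lv <- segment_trace(generate_flux_trace(spec))
  expect_equal(lv$level, c(10, 40, 60, 4))
  expect_equal(lv$segment, canonical_segments("glycolysis_stress"))
  expect_equal(lv$n_points, rep(3L, 4))
})

test_that("single-cycle segments return the lone measurement", {
  spec <- flux_sim_spec("mito_stress", c(30, 10, 62, 2),
                        cycles_per_segment = 1L, noise_sd = 0.4, seed = 2L)
  tr <- generate_flux_trace(spec)
  lv <- segment_trace(tr)
  expect_equal(lv$level, tr$rate)
  expect_equal(lv$n_points, rep(1L, 4))
})

test_that("plateau estimation error is bounded by the sampling noise", {
  errs <- numeric(500)
  for (i in seq_len(500)) {
    spec <- flux_sim_spec("mito_stress", c(30, 10, 62, 2), noise_sd = 0.5,
                          seed = 5000L + i)
    lv <- segment_trace(generate_flux_trace(spec))
    errs[i] <- mean(abs(lv$level - c(30, 10, 62, 2)))
  }
  expect_lt(mean(errs), 3 * 0.5 / sqrt(3))
})

test_that("glycolysis metrics follow their defining arithmetic", {
  m <- glycolysis_stress_metrics(
    make_levels("glycolysis_stress", c(10, 40, 60, 11)))
  expect_equal(m$non_glycolytic_acidification, 10)
  expect_equal(m$basal_glycolysis, 30)
  expect_equal(m$glycolytic_capacity, 50)
  expect_equal(m$glycolytic_reserve, 20)
  expect_equal(m$utilization_fraction, 0.6)
  expect_length(m$flags, 0L)
})

test_that("zero glycolytic reserve is the capacity-saturated boundary", {
  m <- glycolysis_stress_metrics(
    make_levels("glycolysis_stress", c(10, 40, 40, 11)))
  expect_equal(m$glycolytic_reserve, 0)
  expect_equal(m$utilization_fraction, 1)
})

test_that("mito metrics follow their defining arithmetic", {
  m <- mito_stress_metrics(make_levels("mito_stress", c(30, 10, 62, 2)))
  expect_equal(m$non_mitochondrial_ocr, 2)
  expect_equal(m$basal_respiration, 28)
  expect_equal(m$atp_linked_respiration, 20)
  expect_equal(m$proton_leak, 8)
  expect_equal(m$maximal_respiration, 60)
  expect_equal(m$spare_capacity, 32)
  expect_equal(m$utilization_fraction, 28 / 60)
})

test_that("equal basal and maximal respiration means no spare capacity", {
  m <- mito_stress_metrics(make_levels("mito_stress", c(17, 7, 17, 2)))
  expect_equal(m$spare_capacity, 0)
  expect_equal(m$utilization_fraction, 1)
})

test_that("fully flat traces yield zero metrics and a flagged ratio", {
  m <- mito_stress_metrics(make_levels("mito_stress", rep(5, 4)))
  expect_equal(m$basal_respiration, 0)
  expect_equal(m$spare_capacity, 0)
  expect_true(is.nan(m$utilization_fraction))
  expect_true("utilization_undefined" %in% m$flags)
})

test_that("negative derived rates are reported raw and flagged", {
  m <- glycolysis_stress_metrics(
    make_levels("glycolysis_stress", c(10, 8, 60, 11)))
  expect_equal(m$basal_glycolysis, -2)
  expect_true("negative_derived_rate" %in% m$flags)
})

test_that("metric identities hold exactly on arbitrary level sets", {
  set.seed(42)
  for (i in 1:300) {
    gl <- glycolysis_stress_metrics(
      make_levels("glycolysis_stress", runif(4, 0, 100)))
    expect_equal(gl$glycolytic_reserve,
                 gl$glycolytic_capacity - gl$basal_glycolysis,
                 tolerance = 1e-12)
    mt <- mito_stress_metrics(make_levels("mito_stress", runif(4, 0, 100)))
    expect_equal(mt$spare_capacity,
                 mt$maximal_respiration - mt$basal_respiration,
                 tolerance = 1e-12)
    expect_equal(mt$atp_linked_respiration + mt$proton_leak,
                 mt$basal_respiration, tolerance = 1e-12)
  }
})

test_that("metrics reject levels from the wrong assay kind", {
  expect_error(glycolysis_stress_metrics(
    make_levels("mito_stress", c(30, 10, 62, 2))), "glycolysis")
  expect_error(mito_stress_metrics(
    make_levels("glycolysis_stress", c(10, 40, 60, 11))), "mitochondrial")
})

test_that("per-cell normalisation rescales rates but not utilization", {
  m <- mito_stress_metrics(make_levels("mito_stress", c(32, 12, 62, 2)))
  n <- normalize_per_cells(m, cell_count = 5e4, unit_cells = 1e4)
  expect_equal(n$basal_respiration, 30 / 5)
  expect_equal(n$utilization_fraction, m$utilization_fraction)
  ident <- normalize_per_cells(m, cell_count = 1e4, unit_cells = 1e4)
  expect_equal(unclass(ident), unclass(m))
  expect_error(normalize_per_cells(m, cell_count = 0), "positive")
})

test_that("OCR/ECAR ratio is basal respiration over basal glycolysis", {
  mt <- mito_stress_metrics(make_levels("mito_stress", c(30, 10, 62, 2)))
  gl <- glycolysis_stress_metrics(
    make_levels("glycolysis_stress", c(10, 24, 60, 11)))
  expect_equal(ocr_ecar_ratio(mt, gl), 2)
  gl_eq <- glycolysis_stress_metrics(
    make_levels("glycolysis_stress", c(10, 38, 60, 11)))
  expect_equal(ocr_ecar_ratio(mt, gl_eq), 1)
  gl_bad <- glycolysis_stress_metrics(
    make_levels("glycolysis_stress", c(10, 10, 60, 11)))
  expect_warning(r <- ocr_ecar_ratio(mt, gl_bad), "undefined")
  expect_true(is.nan(r))
})

test_that("identical conditions compare with unit folds and p near 1", {
  spec <- flux_sim_spec("mito_stress", c(30, 10, 62, 2), noise_sd = 0)
  plate <- generate_flux_experiment(list(a = spec, b = spec), 3L)
  rep <- flux_metrics_report(plate, reference = "a")
  expect_true(all(abs(rep$summary$fold - 1) < 1e-12 |
                    is.nan(rep$summary$fold)))
  p <- rep$summary$p_value[rep$summary$condition == "b"]
  expect_true(all(is.na(p) | p > 0.99))
})

test_that("single-well conditions report folds but skip the Welch test", {
  spec <- flux_sim_spec("mito_stress", c(30, 10, 62, 2), noise_sd = 0.2,
                        seed = 3L)
  plate <- generate_flux_experiment(list(a = spec, b = spec), 1L)
  w <- capture_warnings(rep <- flux_metrics_report(plate, reference = "a"))
  expect_true(length(w) > 0 && all(grepl("skipped", w)))
  expect_true(all(is.finite(rep$summary$fold)))
  expect_true(all(is.na(rep$summary$p_value[rep$summary$condition == "b"])))
})

test_that("planted condition folds are recovered from noisy plates", {
  specs <- mirror_flux_specs(seed = 21L)
  plate <- generate_flux_experiment(specs$mito, 3L)
  rep <- flux_metrics_report(plate, reference = "adherent")
  fold <- rep$summary$fold[rep$summary$metric == "maximal_respiration" &
                             rep$summary$condition == "suspended"]
  expect_lt(abs(fold - 4), 0.4)
})

test_that("metric values are invariant to normalising before or after", {
  # metrics are linear in levels, so scaling levels then deriving equals
  # deriving then scaling
  lv <- make_levels("mito_stress", c(30, 10, 62, 2))
  lv_scaled <- lv
  lv_scaled$level <- lv$level * (1e4 / 5e4)
  a <- mito_stress_metrics(lv_scaled)
  b <- normalize_per_cells(mito_stress_metrics(lv), 5e4, 1e4)
  rate_fields <- c("non_mitochondrial_ocr", "basal_respiration",
                   "atp_linked_respiration", "proton_leak",
                   "maximal_respiration", "spare_capacity")
  expect_equal(unclass(a)[rate_fields], unclass(b)[rate_fields])
  expect_equal(a$utilization_fraction, b$utilization_fraction)
})

test_that("flux plates survive a TSV round trip", {
  specs <- mirror_flux_specs(seed = 8L)
  plate <- generate_flux_experiment(specs$glyco, 2L)
  d <- withr::local_tempdir()
  paths <- file.path(d, c("plate.tsv", "sched.tsv", "cells.tsv"))
  write_flux_plate(plate, paths[1], paths[2], paths[3])
  back <- read_flux_plate(paths[1], paths[2], paths[3])
  expect_equal(back$conditions, plate$conditions)
  for (i in seq_along(plate$traces)) {
    expect_equal(back$traces[[i]]$rate, plate$traces[[i]]$rate,
                 tolerance = 1e-6)
    expect_equal(back$traces[[i]]$well, plate$traces[[i]]$well)
    expect_equal(back$traces[[i]]$cell_count,
                 plate$traces[[i]]$cell_count)
  }
  rep_a <- flux_metrics_report(plate)
  rep_b <- flux_metrics_report(back)
  expect_equal(rep_b$per_well$value, rep_a$per_well$value,
               tolerance = 1e-6)
})
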