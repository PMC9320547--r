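# Default study-mirroring fixture: simulation specs reproducing the design
# of the melanoma detachment-stress study this package quantifies -- four
# cell lines under adhesion and suspension, a 1,005-gene glucose-metabolism
# universe mined from 29 keyword gene-sets, stress-test plates with the
# reported utilization fractions and folds, and the supporting assays.

MELANOMA_LINES <- c("A375", "A2058", "RPMI7951", "Hs695t")

DOWN_GENES <- c("CAV1", "IRS1", "LMNA", "LMNB2", "PEA15", "POLD1",
                "PRKAG2", "RNASEH2A", "SLC29A1", "SLC2A1")
UP_GENES <- c("AMACR", "ARNT2", "BBS2", "FOS", "FOXO1", "PCSK1", "PLAG1")

#' Published transporter-panel relative expressions (suspension vs adhesion)
#'
#' The reported relative expression (fraction, not percent) of the
#' monocarboxylate transporters MCT1/MCT2/MCT4 and the glucose importer
#' GLUT1 in four melanoma lines; used to plant the mirror fixture's
#' transporter effects and as the reference in recovery checks.
#'
#' @return data.frame with columns `gene`, `line`, `effect`.
#' @export
transporter_reference <- function() {
  eff <- rbind(
    SLC16A1 = c(-0.076, +0.006, -0.067, +0.147),
    SLC16A7 = c(-0.115, -0.064, +0.154, -0.065),
    SLC16A3 = c(-0.627, -0.286, -0.025, -0.517),
    SLC2A1  = c(-0.660, -0.407, -0.384, -0.600))
  data.frame(gene = rep(rownames(eff), times = 4L),
             line = rep(MELANOMA_LINES, each = 4L),
             effect = as.vector(eff), stringsAsFactors = FALSE)
}

#' The mirror fixture's 1,005-gene universe
#'
#' The consistently regulated genes, the transporter panel, and synthetic
#' filler symbols, 1,005 symbols in all.
#'
#' @return character vector of gene symbols.
#' @export
mirror_gene_universe <- function() {
  real <- unique(c(DOWN_GENES, UP_GENES,
                   "SLC16A1", "SLC16A7", "SLC16A3"))
  c(real, sprintf("GM%04d", seq_len(1005L - length(real))))
}

#' Mirror expression-study simulation spec
#'
#' Four melanoma lines, adhesion vs suspension, three replicates; 10
#' planted-down and 7 planted-up genes with effect magnitudes in
#' [0.3, 0.7]; transporter effects planted at the published panel values;
#' 3% multiplicative replicate noise (about one third of the smallest
#' planted magnitude, so planted calls are well powered and the
#' sub-threshold panel entries stay sub-threshold).
#'
#' @param seed integer seed.
#' @return an [expression_sim_spec()].
#' @export
mirror_expression_spec <- function(seed = 1L) {
  expression_sim_spec(
    genes = mirror_gene_universe(), lines = MELANOMA_LINES,
    replicates_per_condition = 3L,
    planted_down = DOWN_GENES, planted_up = UP_GENES,
    effect_range = c(0.3, 0.7),
    planted_effects = transporter_reference(),
    background_noise_sd = 0.03, seed = seed)
}

#' Mirror gene-set collection
#'
#' 40 sets over the mirror universe, 29 of whose names contain "glucose"
#' (the keyword-matched fraction); the keyword sets jointly cover the
#' universe so their member union is the full 1,005-gene target list.
#'
#' @param seed integer seed.
#' @return a [gene_set_collection()].
#' @export
mirror_gene_sets <- function(seed = 1L) {
  generate_gene_sets(mirror_gene_universe(), n_sets = 40L,
                     keyword = "glucose", fraction_keyword_sets = 29 / 40,
                     membership_range = c(40L, 155L), seed = seed,
                     cover_universe = TRUE)
}

#' Mirror stress-test simulation specs
#'
#' Plateau levels planted so that, per the study's findings: adherent cells
#' respire at full capacity (basal = maximal, no spare capacity) while
#' suspended cells use 46.7% of a maximal respiration four-fold the
#' adherent one; both conditions use ~80% of their glycolytic capacity,
#' with suspended glycolysis lower; and the suspended OCR/ECAR ratio is
#' 3.3-fold the adherent one. Noise SD is 5% of each trace's plateau
#' dynamic range.
#'
#' @param seed integer seed.
#' @param noise_frac measurement noise as a fraction of the plateau
#'   dynamic range (default 0.05).
#' @return list with named lists `mito` and `glyco` of
#'   [flux_sim_spec()]s (conditions `adherent`, `suspended`).
#' @export
mirror_flux_specs <- function(seed = 1L, noise_frac = 0.05) {
  mk <- function(kind, plateaus, label) {
    flux_sim_spec(kind, plateaus,
                  noise_sd = noise_frac * diff(range(plateaus)),
                  cell_count = 5e4, seed = derive_seed(seed, label))
  }
  list(
    mito = list(
      # basal = maximal = 15 above a non-mito floor of 2
      adherent = mk("mito_stress",
                    c(baseline = 17, oligomycin = 7, FCCP = 17,
                      rotenone_antimycin = 2), "mito_adh"),
      # basal 28 of maximal 60: utilization 0.4667, maximal fold 4
      suspended = mk("mito_stress",
                     c(baseline = 30, oligomycin = 10, FCCP = 62,
                       rotenone_antimycin = 2), "mito_susp")),
    glyco = list(
      # basal 30 of capacity 37.5: utilization 0.8
      adherent = mk("glycolysis_stress",
                    c(baseline = 10, glucose = 40, oligomycin = 47.5,
                      `2DG` = 11), "glyco_adh"),
      # basal 16.97 of capacity 21.212: utilization 0.8; OCR/ECAR ratio
      # 28/16.97 = 1.65 = 3.3 x adherent's 15/30
      suspended = mk("glycolysis_stress",
                     c(baseline = 10, glucose = 26.9697,
                       oligomycin = 31.2121, `2DG` = 11), "glyco_susp")))
}

#' Mirror supporting-assay tables
#'
#' Generates the qPCR, proliferation-count, ROS, lactate and
#' dose-response tables at the study's planted contrasts: MCT4/GLUT1
#' suppression matching the A375 panel values, proliferation ratios 0.1
#' (adherent) vs 0.6 (suspended) at a tenth of normal glucose, superoxide
#' at 10% vs 47% of the control span (4.7-fold) and total ROS at 30% vs
#' 45% (1.5-fold), lower suspended lactate at pH 7.0 with parity at pH
#' 8.5, and the 2DG/rotenone sensitivity reversal.
#'
#' @param seed integer seed.
#' @return named list of data.frames: `qpcr`, `counts`, `ros`, `lactate`,
#'   `viability`.
#' @export
mirror_assay_tables <- function(seed = 1L) {
  qpcr <- generate_qpcr_table(
    planted_folds = c(SLC16A3 = 0.373, SLC2A1 = 0.340),
    noise_sd_ct = 0.1, replicates = 3L, seed = derive_seed(seed, "qpcr"))
  counts <- generate_count_table(
    data.frame(condition = rep(c("adherent", "suspended"), each = 2L),
               glucose = c(25, 2.5, 25, 2.5),
               ratio = c(1, 0.1, 1, 0.6)),
    reference_cells = 4e5, noise_sd = 8e3, replicates = 3L,
    seed = derive_seed(seed, "counts"))
  ros <- generate_ros_table(
    planted_percent = c(superoxide_adherent = 10, superoxide_suspended = 47,
                        ros_adherent = 30, ros_suspended = 45),
    noise_sd = 5, replicates = 3L, seed = derive_seed(seed, "ros"))
  lactate <- generate_lactate_table(
    data.frame(condition = rep(c("adherent", "suspended"), times = 2L),
               pH = c(7.0, 7.0, 8.5, 8.5),
               mean = c(20, 12, 30, 30)),
    noise_sd = 1, replicates = 3L, seed = derive_seed(seed, "lactate"))
  viability <- rbind(
    generate_dose_response(c(0, 1, 2.5, 5, 10, 25, 50), top = 1,
                           bottom = 0.2, ic50 = 5, hill = 1,
                           noise_sd = 0.03, condition = "adherent",
                           compound = "2DG", seed = seed),
    generate_dose_response(c(0, 1, 2.5, 5, 10, 25, 50), top = 1,
                           bottom = 0.85, ic50 = 5, hill = 1,
                           noise_sd = 0.03, condition = "suspended",
                           compound = "2DG", seed = seed),
    generate_dose_response(c(0, 0.01, 0.03, 0.1, 0.3, 1, 3), top = 1,
                           bottom = 0.6, ic50 = 1, hill = 1,
                           noise_sd = 0.03, condition = "adherent",
                           compound = "rotenone", seed = seed),
    generate_dose_response(c(0, 0.01, 0.03, 0.1, 0.3, 1, 3), top = 1,
                           bottom = 0.15, ic50 = 0.05, hill = 1,
                           noise_sd = 0.03, condition = "suspended",
                           compound = "rotenone", seed = seed))
  list(qpcr = qpcr, counts = counts, ros = ros, lactate = lactate,
       viability = viability)
}
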