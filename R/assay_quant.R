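# Supporting assay quantification: 2^-ddCt qPCR folds, proliferation
# ratios under glucose titration, relative ROS percentage against assay
# controls, relative lactate comparisons, and dose-response sensitivity
# scores.

#' Relative gene expression by the 2^-ddCt method
#'
#' Per group, the target gene's replicate-mean Ct is referenced to the
#' housekeeping gene (`dCt = Ct_target - Ct_ref`); the test group is then
#' calibrated against the control group (`ddCt = dCt_test - dCt_control`)
#' and the fold change is `2^-ddCt`. Replicate scatter is propagated on the
#' ddCt scale: per-replicate dCt SDs are combined in quadrature and
#' reported alongside a fold interval `2^-(ddCt +/- sd)`.
#'
#' @param qpcr data.frame with columns `group`, `gene`, `replicate`, `ct`.
#' @param target target gene symbol.
#' @param test_group,control_group group labels (control is the
#'   calibrator).
#' @param reference_gene housekeeping gene (default `"GAPDH"`).
#' @return list with `fold`, `ddct`, `sd_ddct`, `fold_lo`, `fold_hi`.
#' @export
ddct_fold <- function(qpcr, target, test_group, control_group,
                      reference_gene = "GAPDH") {
  stopifnot(all(c("group", "gene", "replicate", "ct") %in% colnames(qpcr)))
  if (!all(is.finite(qpcr$ct))) stop("Ct values must be finite")
  dct <- function(grp) {
    t_ct <- qpcr$ct[qpcr$group == grp & qpcr$gene == target]
    r_ct <- qpcr$ct[qpcr$group == grp & qpcr$gene == reference_gene]
    if (!length(r_ct))
      stop("reference gene '", reference_gene, "' missing in group '",
           grp, "'")
    if (!length(t_ct))
      stop("target gene '", target, "' missing in group '", grp, "'")
    n <- min(length(t_ct), length(r_ct))
    d <- t_ct[seq_len(n)] - r_ct[seq_len(n)]  # replicate-paired dCt
    list(mean = mean(t_ct) - mean(r_ct),
         sd = if (n > 1L) stats::sd(d) else NA_real_)
  }
  a <- dct(test_group); b <- dct(control_group)
  ddct <- a$mean - b$mean
  sd_ddct <- if (is.na(a$sd) || is.na(b$sd)) NA_real_ else
    sqrt(a$sd^2 + b$sd^2)
  list(fold = 2^(-ddct), ddct = ddct, sd_ddct = sd_ddct,
       fold_lo = 2^(-(ddct + sd_ddct)), fold_hi = 2^(-(ddct - sd_ddct)))
}

#' Relative proliferation ratio under glucose titration
#'
#' Per condition, the mean cell count at each glucose concentration is
#' divided by the mean count at that condition's reference ("normal
#' culture") concentration.
#'
#' @param counts data.frame with columns `condition`, `glucose`,
#'   `replicate`, `cells`.
#' @param reference_glucose the normal-culture glucose concentration
#'   (default: the maximum observed per condition).
#' @return data.frame with columns `condition`, `glucose`, `mean_cells`,
#'   `ratio`.
#' @export
proliferation_ratio <- function(counts, reference_glucose = NULL) {
  stopifnot(all(c("condition", "glucose", "replicate", "cells") %in%
                  colnames(counts)))
  if (any(counts$cells < 0)) stop("cell counts must be >= 0")
  out <- list()
  for (cond in unique(counts$condition)) {
    sub <- counts[counts$condition == cond, , drop = FALSE]
    ref <- if (is.null(reference_glucose)) max(sub$glucose) else
      reference_glucose
    if (!ref %in% sub$glucose)
      stop("reference glucose concentration absent for condition '",
           cond, "'")
    agg <- tapply(sub$cells, sub$glucose, mean)
    ref_mean <- agg[[as.character(ref)]]
    if (!(ref_mean > 0)) stop("reference cell count is zero")
    out[[cond]] <- data.frame(
      condition = cond, glucose = as.numeric(names(agg)),
      mean_cells = as.numeric(agg), ratio = as.numeric(agg) / ref_mean,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative ROS percentage against assay controls
#'
#' Places a sample's fluorescence on the span between the negative control
#' (N-acetylcysteine, 0%) and the positive control (antimycin A, 100%):
#' `100 * (F_sample - F_neg) / (F_pos - F_neg)`. The formula is invariant
#' under any affine transformation (gain/offset) of the raw fluorescence.
#' The fold between two samples is the ratio of their percentages.
#'
#' @param ros data.frame with columns `sample`, `fluorescence` (replicate
#'   rows allowed; replicate means are used).
#' @param sample sample label to quantify.
#' @param positive_control,negative_control control sample labels.
#' @return relative ROS production, percent.
#' @export
ros_relative <- function(ros, sample, positive_control = "antimycin_A",
                         negative_control = "NAC") {
  stopifnot(all(c("sample", "fluorescence") %in% colnames(ros)))
  f <- function(lbl) {
    v <- ros$fluorescence[ros$sample == lbl]
    if (!length(v)) stop("sample '", lbl, "' absent from ROS table")
    mean(v)
  }
  pos <- f(positive_control); neg <- f(negative_control)
  if (pos == neg) stop("positive and negative control fluorescence equal")
  100 * (f(sample) - neg) / (pos - neg)
}

#' Fold in relative ROS between two samples
#' @inheritParams ros_relative
#' @param sample_a,sample_b sample labels; the fold is a over b.
#' @return ratio of the two relative percentages.
#' @export
ros_fold <- function(ros, sample_a, sample_b,
                     positive_control = "antimycin_A",
                     negative_control = "NAC") {
  ros_relative(ros, sample_a, positive_control, negative_control) /
    ros_relative(ros, sample_b, positive_control, negative_control)
}

#' Condition means and Welch comparison of lactate concentrations
#'
#' Summarises replicate lactate concentrations per (condition, pH) and
#' compares the two conditions at each pH with a two-sided Welch t-test.
#' With a single replicate in either group the p-value is skipped with a
#' warning.
#'
#' @param lactate data.frame with columns `condition`, `pH`, `replicate`,
#'   `concentration`.
#' @return list with `summary` (condition, pH, n, mean, sd) and
#'   `comparison` (pH, fold of second condition over first, p_value).
#' @export
relative_lactate <- function(lactate) {
  stopifnot(all(c("condition", "pH", "replicate", "concentration") %in%
                  colnames(lactate)))
  conds <- unique(lactate$condition)
  if (length(conds) != 2L) stop("expected exactly two conditions")
  sum_rows <- list(); cmp_rows <- list()
  for (ph in unique(lactate$pH)) {
    sub <- lactate[lactate$pH == ph, , drop = FALSE]
    vals <- lapply(conds, function(cond)
      sub$concentration[sub$condition == cond])
    for (i in seq_along(conds))
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        condition = conds[i], pH = ph, n = length(vals[[i]]),
        mean = mean(vals[[i]]),
        sd = if (length(vals[[i]]) > 1L) stats::sd(vals[[i]]) else NA_real_,
        stringsAsFactors = FALSE)
    p <- NA_real_
    if (all(lengths(vals) >= 2L)) {
      p <- if (stats::sd(vals[[1]]) + stats::sd(vals[[2]]) > 0)
        stats::t.test(vals[[2]], vals[[1]], var.equal = FALSE)$p.value
      else 1
    } else {
      warning("single replicate at pH ", ph, "; Welch test skipped")
    }
    cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
      pH = ph, fold = mean(vals[[2]]) / mean(vals[[1]]), p_value = p,
      stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, sum_rows),
       comparison = do.call(rbind, cmp_rows))
}

#' Dose-response sensitivity score (normalized AUC)
#'
#' Viability signals are normalized to the vehicle (dose 0) mean of the
#' same condition and compound; the score is one minus the trapezoidal
#' mean of normalized viability over the log10-dose grid of the non-zero
#' doses. 0 means no response at any dose, values near 1 mean complete
#' loss of viability; the score is invariant under rescaling of the raw
#' signal and never decreases when viability drops pointwise.
#'
#' @param viability data.frame with columns `condition`, `compound`,
#'   `dose`, `replicate`, `viability`.
#' @param condition,compound which series to score.
#' @return sensitivity score in `[0, 1]` (scores above 1 are possible only
#'   if normalized viability goes negative, which raw signals cannot).
#' @export
sensitivity_score <- function(viability, condition, compound) {
  stopifnot(all(c("condition", "compound", "dose", "replicate",
                  "viability") %in% colnames(viability)))
  sub <- viability[viability$condition == condition &
                     viability$compound == compound, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for this condition/compound")
  if (any(sub$dose < 0)) stop("doses must be >= 0")
  veh <- sub$viability[sub$dose == 0]
  if (!length(veh)) stop("vehicle (dose 0) wells missing")
  v0 <- mean(veh)
  if (!(v0 > 0)) stop("vehicle mean viability must be > 0")
  dosed <- sub[sub$dose > 0, , drop = FALSE]
  doses <- sort(unique(dosed$dose))
  if (length(doses) < 2L) stop("need >= 2 non-zero doses")
  vbar <- vapply(doses, function(d)
    mean(dosed$viability[dosed$dose == d]) / v0, numeric(1))
  x <- log10(doses)
  auc <- sum(diff(x) * (utils::head(vbar, -1) + utils::tail(vbar, -1)) / 2)
  1 - auc / (max(x) - min(x))
}

#' Sensitivity contrast between two conditions
#'
#' @inheritParams sensitivity_score
#' @param condition_a,condition_b condition labels; the contrast is
#'   `score(condition_a) - score(condition_b)` (positive: a more
#'   sensitive).
#' @return list with both scores and `delta`.
#' @export
sensitivity_contrast <- function(viability, condition_a, condition_b,
                                 compound) {
  sa <- sensitivity_score(viability, condition_a, compound)
  sb <- sensitivity_score(viability, condition_b, compound)
  list(score_a = sa, score_b = sb, delta = sa - sb)
}
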