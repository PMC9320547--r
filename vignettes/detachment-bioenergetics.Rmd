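---
title: "Stress-test bioenergetics and consistent-direction expression screening"
author: "anoikisflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-test bioenergetics and consistent-direction expression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anoikisflux)
```

## The problem

Metastasising tumour cells must survive without extracellular-matrix
anchorage. Detachment stress changes how melanoma cells harvest energy:
away from aerobic glycolysis (the Warburg phenotype, with high glucose
uptake and lactate export) toward mitochondrial respiration. The
measurable signatures are (i) extracellular-flux stress-test profiles —
extracellular acidification rate (ECAR, mpH/min) as the glycolysis proxy
and oxygen consumption rate (OCR, pmol O₂/min) as the respiration proxy —
(ii) expression changes of glucose-metabolism genes, notably the lactate
exporter MCT4 (SLC16A3) and the glucose importer GLUT1 (SLC2A1), that are
consistent in direction across cell lines, and (iii) supporting assays:
qPCR, lactate release, reactive-oxygen-species (ROS) levels, and
dose–response viability under glycolysis or electron-transport-chain
blockade. This package implements the quantitative chain for all three,
together with seeded simulators of each input so that every estimator can
be checked against planted truth.

## Stress-test model

A stress test is a piecewise-stationary process: between injections the
rate fluctuates around a plateau. We model measurement $i$ (global cycle
index) in segment $s$ as

$$y_i = \mu_s + \delta\,(i-1) + \varepsilon_i,\qquad
  \varepsilon_i \sim \mathcal N(0, \sigma^2),$$

with plateau $\mu_s$, optional linear drift $\delta$ (default 0, provided
to stress-test the estimator) and additive Gaussian noise, matching the
mean ± SD reporting convention of plate readers. Segments are half-open:
the cycle at which an injection is recorded still belongs to the preceding
segment.

**Plateau estimation.** Each segment's level is the mean of its last
$\min(k, n_s)$ cycles, $k = 3$ by default — the usual number of
measurement cycles between injections — so that for longer segments the
first post-injection cycle (the mixing/equilibration transient) is
discarded. With three cycles per segment this reduces to the segment mean.

**Metric derivation.** For a glycolysis test (glucose-free baseline, then
glucose, oligomycin, 2-deoxyglucose) with levels $L$:
non-glycolytic acidification $= L_\text{base}$, basal glycolysis
$B = L_\text{glc} - L_\text{base}$, glycolytic capacity
$C = L_\text{oligo} - L_\text{base}$, reserve $= C - B$, utilization
$= B/C$. For a mitochondrial test (baseline, oligomycin, FCCP,
rotenone/antimycin A): non-mitochondrial OCR $= L_\text{rot}$, basal
respiration $B = L_\text{base} - L_\text{rot}$, ATP-linked respiration
$= L_\text{base} - L_\text{oligo}$, proton leak
$= L_\text{oligo} - L_\text{rot}$, maximal respiration
$M = L_\text{FCCP} - L_\text{rot}$, spare capacity $= M - B$, utilization
$= B/M$. Three identities hold exactly by construction and are enforced by
tests: reserve $= C - B$, spare $= M - B$, ATP-linked + leak $= B$.

Rates are normalized per $10^4$ cells using the post-run cell count;
since every metric is linear in the levels, normalizing levels or metrics
is equivalent, and utilization fractions are invariant under any uniform
rescaling. Negative derived rates are *reported raw with a flag*, never
clamped: a negative basal glycolysis is an assay failure the analyst must
see. The pathway-preference index is the OCR/ECAR ratio, implemented as
basal respiration over basal glycolysis from paired, same-condition
wells (a raw baseline-level ratio would differ only by the non-glycolytic
and non-mitochondrial floors; the basal form is the one that isolates the
two pathways). Condition contrasts report arithmetic means, sample SDs,
folds, and two-sided Welch (unequal-variance) t-tests — Welch because
wells are few and variance homogeneity is not defensible.

## Expression screen

Gene sets are read from standard GMT; keyword selection is
case-insensitive substring matching over name *and* description by
default, because curated GO-style collections often carry the topic only
in the description (name-only mode is available). The member union of the
selected sets defines the candidate universe. Multi-probe platforms are
collapsed to gene level by the arithmetic mean on the normalized-intensity
scale before any ratio is formed.

For gene $g$ and line $\ell$, replicate intensities are averaged per
condition first and

$$r_{g\ell} = \frac{\bar I^{\text{susp}}_{g\ell} - \bar I^{\text{adh}}_{g\ell}}
                  {\bar I^{\text{adh}}_{g\ell}}$$

(averaging per-replicate ratios instead would give a different, biased
estimator and is deliberately not offered). The screen calls $g$ down when
$r_{g\ell} < -\tau$ in **all** lines and up when $r_{g\ell} > +\tau$ in
all lines. The operation's default is $\tau = 0$ — strict sign agreement,
the weakest defensible reading of "changed in every line".

**Why the pipeline default is $\tau = 0.1$.** Sign agreement alone does
not survive noise at genome scale: under the null, a gene's per-line $r$
has a symmetric sign, so with $L$ lines a null gene is sign-consistent
with probability $2^{1-L}$ — with 4 lines and ~1,000 candidate genes,
roughly 125 false calls. A threshold restores specificity: with replicate
noise of a few percent, the per-line SD of $r$ is
$\approx \sigma\sqrt{2/n_\text{rep}}$, and $\tau = 0.1$ puts the null
$\gtrsim 4$ SDs from a call while planted effects of magnitude
$\ge 0.3$ remain $\gtrsim 8$ SDs on the calling side. The threshold is a
screen parameter, not a significance test; the package performs no
per-gene inference because the screen is direction-only by design.

The transporter panel formats $r$ as signed percentages to one decimal
and marks entries with $|r| \ge 0.35$; that marking threshold separates
moderate (−28.6%) from strong (−38.4% and beyond) suppression in the
reference pattern the fixture plants.

## Assay quantifications

- **qPCR.** $\Delta Ct = Ct_\text{target} - Ct_\text{GAPDH}$ per group,
  $\Delta\Delta Ct = \Delta Ct_\text{test} - \Delta Ct_\text{control}$,
  fold $= 2^{-\Delta\Delta Ct}$, with the adhesion condition as the
  calibrator. Replicate scatter is propagated on the $\Delta\Delta Ct$
  scale (quadrature of per-group $\Delta Ct$ SDs) and reported as a fold
  interval, since folds are log-normal, not normal.
- **ROS.** The kit's two stated controls anchor a min–max scale:
  percent $= 100\,(F - F_\text{NAC}) / (F_\text{antimycin} -
  F_\text{NAC})$. This is the package's own operationalisation of
  "relative percentage against positive and negative controls"; it is
  affine-invariant in the raw fluorescence. Folds between samples are
  ratios of percentages, so both views (percent and fold) are reported.
- **Proliferation.** Mean cell count at each glucose concentration over
  the mean at the normal-culture concentration, per condition.
- **Lactate.** Condition means ± SD per pH with Welch comparisons;
  concentrations are inputs (no standard-curve fitting).
- **Sensitivity.** One minus the trapezoidal mean of vehicle-normalized
  viability over the log₁₀-dose grid. A normalized-AUC score is used
  instead of IC50 fitting because the claims being quantified are ordinal
  (more/less sensitive) and near-flat curves never cross 50%, where an
  IC50 fit is undefined. The score is 0 for a flat curve, approaches 1
  for complete kill, is invariant to the raw signal scale, and is
  monotone in pointwise viability.

## The synthetic fixture: what it emulates, what it does not

Each generator draws from a named pseudo-random stream derived from the
master seed, so adding a generator never perturbs another's output, and
every table is a pure function of its spec. The mirror fixture encodes
the study conditions:

- 4 melanoma lines (A375, A2058, RPMI7951, Hs695t) × adhesion/suspension
  × 3 replicates (replicate count per array condition is not public; 3 is
  this package's choice, matching the wet-lab n = 3 reporting).
- A 1,005-gene universe; 40 gene sets of which 29 carry the "glucose"
  keyword and jointly cover the universe; 10 planted-down and 7
  planted-up genes with per-line effect magnitudes drawn from
  $[0.3, 0.7]$; the four transporter genes planted at the published panel
  percentages. Expression noise is multiplicative log-normal (sdlog
  0.03 in the mirror fixture) — chosen so the smallest sub-threshold
  panel entry (−2.5%) sits >3 SDs below the $\tau = 0.1$ call line,
  i.e. from the power analysis above, not from any test outcome.
- Stress-test plates planted so that adherent cells respire at capacity
  (basal = maximal), suspended cells at 46.7% of a 4-fold larger maximal
  respiration; both conditions use 80% of glycolytic capacity; the
  suspended OCR/ECAR ratio is 3.3-fold the adherent one. Measurement
  noise is 5% of each trace's plateau dynamic range; 3 wells per
  condition, 3 cycles per segment.
- Assays planted at: MCT4/GLUT1 qPCR folds 0.373/0.340 (the A375 panel
  magnitudes, since the study reports the qPCR change only graphically);
  proliferation ratios 0.1 (adherent) vs 0.6 (suspended) at a tenth of
  normal glucose; superoxide 10% vs 47% of the control span (4.7-fold)
  and total ROS 30% vs 45% (1.5-fold); lactate 20 vs 12 units at pH 7.0
  and parity at pH 8.5; and a 2DG/rotenone sensitivity reversal.

The simulators emulate the *statistical* structure each estimator
assumes — plateaus plus Gaussian noise, log-normal intensities with
multiplicative condition effects, logistic dose response. They do not
emulate instrument-level artefacts (injection transients beyond a single
cycle, edge-well effects, probe cross-hybridisation, batch effects across
lines, heteroscedastic Ct noise). Passing recovery tests therefore shows
the estimators are correct and well-calibrated under the declared model,
not that real plates are free of those artefacts.

## Numerical and degenerate-input policy

Utilization is `NaN` and flagged when the denominator capacity is not
positive; the OCR/ECAR ratio is `NaN` with a warning when basal
glycolysis is non-positive; relative expression is `NaN`-flagged where
the adhesion mean is zero; Welch tests are skipped with a warning below
two replicates, and return p = 1 for identical zero-variance groups.
Screen inequalities are strict, so $r = 0$ genes are never called at
$\tau = 0$. Ties in plateau estimation cannot arise (means of fixed
windows); the estimator uses only cycles within the segment, so a
mis-specified schedule fails loudly rather than leaking cycles across an
injection.

## Problem sizes

The validation suite uses 1,000 random level sets for the exact
identities, 100 noise-free simulated traces for closed-form equivalence,
200 single-trace simulations per utilization target, 50 three-well plate
pairs for the fold recoveries, 1,000 small random tables for the screen
oracle, and 100 fixture seeds for list recovery — sizes at which the
Monte-Carlo medians are stable to well under the tolerances being
checked, while the whole suite runs in about a minute.

## Known limitations

- The screen is direction-only; it attaches no per-gene error rate, and
  its $\tau$ trades sensitivity for specificity explicitly.
- The OCR/ECAR ratio requires paired plates of the same condition; the
  pairing is by well order within condition.
- `geo_import()` reads local series-matrix files and a user-supplied
  title → (line, condition) mapping; it does not fetch accessions over
  the network, and intensities are assumed already background-corrected
  and normalized.
- Whether published flux ratios were computed per-cell or per-well is
  ambiguous in general; all package ratios are per-cell-normalized, and
  utilizations are invariant to that choice.
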