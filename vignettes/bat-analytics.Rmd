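---
title: "BAT dose-response analytics for LTP allergy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BAT dose-response analytics for LTP allergy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batdx)
```

`batdx` analyses basophil activation test (BAT) data for lipid transfer
protein (LTP) allergy: dose-response series of percent activated
basophils (%CD63⁺ or %CD203c^high) measured at serial allergen
concentrations of Pru p 3 (peach LTP) or Ara h 9 (peanut LTP) in allergic
patients and healthy controls. This vignette documents the models, the
defaults and the numerical choices; the package's tests compute every
empirical claim made here.

## The dose-response model

Percent activation at concentration $c$ (µg/mL) is modelled as a
four-parameter log-logistic curve,

$$f(c) = b + \frac{E}{1 + 10^{\,h\,(m - \log_{10} c)}},$$

with baseline $b$ (percent, unstimulated activation), maximal increment
$E$ (percent; $b + E \le 100$), $m = \log_{10}\mathrm{EC50}$ (µg/mL) and
Hill slope $h > 0$. The curve is monotone nondecreasing in $c$ and
reaches $b + E/2$ exactly at the EC50. The model assumes a single
saturating activation mechanism per series; bell-shaped (high-dose
suppressed) responses are not modelled.

Three derived quantities summarise a series:

* **CD-sens** $= 100/\mathrm{EC50}$, the basophil allergen threshold
  sensitivity. The literature defines CD-sens through the inverse of the
  concentration giving half the maximal response but prints no closed
  formula; we adopt $100/\mathrm{EC50}$ with EC50 in µg/mL, so the
  numeric scale depends on that unit convention — values are only
  comparable across studies using the same units. The half-maximal
  concentration is taken from the *fitted* curve, which is markedly more
  stable under counting noise than interpolating between measured
  points; `cd_sens(interpolate = TRUE)` provides the interpolation
  alternative for sensitivity analyses.
* **Curve AUC**: the trapezoid integral of background-subtracted
  activation (floored at zero) over the $\log_{10}$ concentration axis.
  It needs no fit, so it is defined for all subjects including controls,
  whereas CD-sens exists only for responders. Raw-scale and
  linear-axis variants exist behind switches
  (`subtract_background`, `log_axis`); the defaults are background
  subtraction on the log axis, and no normalisation, so AUC values are
  comparable within a run only.
* **Responder flag**: a series is a responder when its peak reaches
  `min_peak` (default 5 %) *and* at least `fold_over_background`
  (default 2) times the background, the background being floored at
  0.5 % so the fold criterion is never vacuous. Nonresponder exclusion
  before curve-derived statistics is standard practice in BAT studies,
  which rarely state their thresholds; ours are explicit and
  configurable. For nonresponders only the mean level and the curve AUC
  are reported; CD-sens deliberately raises an error, since basophil
  sensitivity cannot be calculated in nonresponding (nonallergic)
  individuals.

### Fitting

`fit_curve()` minimises the residual sum of squares under box
constraints ($b, E \ge 0$, $b + E \le 100$ via penalty,
$0.3 \le h \le 5$, $m$ within one decade of the measured concentration
range) using L-BFGS-B with multistart initialisation: one start per
measured concentration for $m$ crossed with slopes $\{0.7, 1.5, 3\}$.
The multistart grid matters: with most points on the plateau, a single
start can park the EC50 in a local minimum a decade away. Among starts
whose loss ties the best (relative tolerance $10^{-6}$), a cleanly
converged one is preferred when flagging convergence. On noise-free
data the fit recovers all four parameters to better than $10^{-3}$
anywhere inside the constraint box; under 500-event binomial noise the
median relative error of CD-sens across a default cohort's responders
is about 13 % (the tests bound it below 15 %). Degenerate inputs are
defined: an all-identical series returns a flat fit with $E = 0$ and
`fit_converged = TRUE`; fewer than four points is an error.

## Diagnostics

For each marker × concentration, `roc_curve()` compares allergic versus
control activation at thresholds placed at midpoints between consecutive
distinct pooled values (plus sentinels beyond the extremes);
`roc_auc()` is the Mann–Whitney statistic with ties counted ½, which
equals the trapezoidal area under that empirical curve (the tests verify
the identity to $10^{-12}$ and against `pROC`). `optimal_cutoff()`
maximises Youden's $J$ = sensitivity + specificity − 100 — no criterion
is canonical in the BAT literature, Youden is the usual choice and a
maximum-accuracy alternative is provided — with ties broken toward
larger specificity, then larger threshold (a conservative cut-off for a
screening context where false positives are the stated concern). PPV
and NPV use the observed cohort prevalence; they are therefore cohort
statistics, not transportable probabilities.

`select_discriminating_concentrations()` ranks concentrations by that
same rank statistic and breaks ties toward the higher concentration
(where reactivity has saturated, higher doses are cheaper to interpret);
on default synthetic cohorts, whose curves plateau above $10^{-3}$
µg/mL, the three highest concentrations win.

A subject's BAT call (`classify_subject()`) is positive when activation
*strictly* exceeds the concentration-specific cut-off at two or more
consecutive concentrations. By default the rule is evaluated over the
selected discriminating concentrations in ascending order — the
positivity analysis follows concentration selection — but any
concentration set with cut-offs can be supplied. Published cut-offs for
the two readouts at the three highest Pru p 3 concentrations ship as
`reference_cutoffs()` for applying those thresholds to new data; their
PPV/NPV columns are reproduced as printed, noting that they are not
recomputable from their own sensitivity/specificity and prevalence.

## Cohort statistics

`compare_groups()` implements the standard clinical comparison plan:
unpaired t or Mann–Whitney for two groups, paired t or Wilcoxon
signed-rank within subject (used for the Pru p 3 vs Ara h 9 contrast),
ANOVA with Bonferroni-adjusted pairwise t tests or Kruskal–Wallis with
Dunn's post hoc for more than two. Since comparison plans of this kind
usually list both families without a dispatch rule, ours is explicit:
with `scale = "auto"` the parametric branch requires every group to pass
Shapiro–Wilk at $\alpha = 0.05$, and the branch taken is recorded in the
result. Dunn's test is the tie-corrected mean-rank z-test with
Bonferroni adjustment by default. The tests calibrate the nonparametric
omnibus at the null: its type-I error over 1000 seeded simulations
(three lognormal groups of 15) lies within [3.5 %, 6.5 %] at nominal
5 %.

Percentages in `summarize_cohort()` are rounded half-up to two decimals
and always stored with numerator and denominator so each cell is
auditable. SPT positivity is a wheal area ≥ 7 mm². The oral food
challenge helper converts a volume schedule and a preparation
concentration (mg allergen per mL) into per-dose and cumulative amounts;
it deliberately takes the concentration as an explicit argument rather
than hard-coding a preparation.

## PCA

`run_pca()` performs SVD-based PCA on the centred (by default also
unit-variance scaled) subject × feature table, matching the defaults of
common web PCA tools used for clinical data; scaling is essential here
because sIgE (kU/L), activation percentages and wheal areas (mm²) live
on incommensurate scales. sIgE enters as $\log_{10}(x + 0.01)$ — serum
IgE is heavily right-skewed and a small offset keeps controls near the
assay floor finite. Rows with undefined features (chiefly CD-sens in
nonresponders) are dropped and reported. Component signs are fixed by
making each component's largest-magnitude loading positive, so results
are deterministic. Orthonormality of loadings, zero-mean scores and
exact reconstruction from all components are tested invariants.

## The synthetic cohort generator

`simulate_cohort()` emulates the *structure* of an LTP-allergy BAT
study: 16 controls and 92 allergic subjects (23 oral allergy syndrome /
44 urticaria-angioedema / 25 anaphylaxis), of whom 37 are additionally
peanut-allergic (Group B) and 55 peanut-tolerant (Group A); seven
ten-fold concentrations from $10^{-7}$ to $10^{-1}$ µg/mL; profilin
co-sensitization probabilities falling with severity (0.3044 / 0.1591 /
0.04); control sIgE capped below the 0.35 kU/L assay positivity
threshold and control SPT areas below 7 mm². Covariate blocks
(lognormal IgE and wheal areas, normal ages) are calibrated to the
medians and interquartile ranges typical of such cohorts — e.g. median
sIgE to Pru p 3 of a few kU/L in patients versus ~0.01 kU/L in controls.

Latent curves: allergic subjects draw $(b, E, m, h)$ from their group
block (Emax truncated to [15, 90] %, $m \sim N(-4, 0.8)$ truncated,
lognormal slopes in [0.5, 4], baseline near 1 % — backgrounds are
rarely reported, 1 % is our free but typical choice); controls draw
near-flat curves with Emax below 2.5 %. A shared per-subject latent
sensitization factor (loading 0.7) pushes Emax up and the EC50 down
together: strongly sensitized patients both react more and react at
lower doses, which is what makes CD-sens and curve AUC correlate
strongly ($r > 0.7$ among responders) as BAT cohorts show; set
`reactivity_sensitivity_coupling = 0` for independent draws. Group B
subjects receive an Ara h 9 Emax comparable to their Pru p 3 Emax
(factor 0.85–1.05), Group A a strictly attenuated one (0.35–0.65) on
the CD63 readout; because the allergen difference has been observed on
CD63 but not CD203c, the attenuation spares CD203c unless
`attenuate_arah9_cd203c = TRUE`.

Observation noise is binomial: a well with latent value $p \cdot 100$ %
counted over $N$ events (default 500) reports
$100 \cdot \mathrm{Bin}(N, p)/N$, giving the flow-cytometry counting
standard deviation $100\sqrt{p(1-p)/N}$ (a tested property).
`exact_curves = TRUE` (or $N = \infty$) switches noise off, which the
tests use for exact-recovery checks. Everything is driven by one seed
and is bit-reproducible.

What the generator does *not* emulate: event-level cytometry (FCS files,
gating, spillover), day effects and analyst variability, bell-shaped
high-dose suppression, nonresponders among patients (they arise only by
chance at low Emax), and any dependence of reactivity on severity group
— by design, severity groups differ in covariates but not in latent
reactivity, matching the finding that BAT does not separate severity.
Consequently, tests passing on synthetic cohorts demonstrate the
correctness of the *analysis machinery* under the stated noise model,
not clinical performance on real data: the default cohort is
well-separated (derived cut-offs reach sensitivity = specificity =
100 % at the upper concentrations), which real cohorts with borderline
reactors will not match.

## Problem sizes and determinism

The test-suite and the acceptance script run at the study's native scale
(108 subjects, 500 events/well), with 1000-replicate calibration loops
for the type-I error and 200 random instances for the ROC oracle
identities; full runs complete in about a minute of CPU. All
simulations are seeded; pipeline reruns under one seed produce
byte-identical CSV artifacts (a tested property).

## Known limitations

* CD-sens units follow the 100/EC50(µg/mL) convention; comparisons to
  studies using other conventions need rescaling.
* Curve AUC is unnormalised and integration-convention dependent;
  compare only within one convention.
* The confusion-matrix PPV/NPV are prevalence-bound; applying derived
  cut-offs to populations with other prevalences changes them.
* Dunn's post hoc uses a normal approximation; for very small groups
  with many ties, exact pairwise Mann-Whitney tests may be preferable.
* The generator's group blocks are plausibility calibrations, not
  estimates; do not use synthetic cohorts to benchmark clinical
  accuracy claims.
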