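---
title: "Methods: long-term kidney toxicity analysis after 177Lu-octreotate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-term kidney toxicity analysis after 177Lu-octreotate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renaltox)
```

## Scope and shape

`renaltox` implements, as one tested pipeline, the analyses used to
characterize late radiation injury to mouse kidneys after
^177^Lu-octreotate: internal dosimetry, transcript-level biomarker
discovery, planar-scintigraphy renal-function quantification, and blood
chemistry/hematology summaries. Because the underlying study is a sequence
of analyses rather than a single tool, the repository is organized as an
analysis workflow: every computation lives in the package (`R/`), and the
numbered scripts under `analysis/` are thin narrative drivers that run each
stage and write tables under `results/`. There is deliberately no shell
CLI; the scripts and the exported functions are the interface.

All inputs are either packaged fixtures transcribed from the published
summary tables (marker panel, regulator-target map, blood ratios) or
synthetic data produced by the package's own generators, so every stage is
testable offline.

## Kidney dosimetry

The mean absorbed dose to the kidney follows the MIRD formalism with the
source region equal to the target region (self-dose):

$$\bar D = \tilde A \cdot \frac{\Delta \, \phi}{M},$$

where $\tilde A$ is the time-integrated activity (MBq·h), $\Delta = \sum_i
E_i Y_i$ the mean electron energy emitted per decay, $\phi$ the absorbed
fraction, and $M$ the kidney mass. Defaults are $\Delta$ = 147 keV
(electrons only), $\phi$ = 0.93, the ^177^Lu physical half-life 6.647 d
(159.528 h), and $M$ = 0.3 g — a typical whole kidney in an adult
C57BL/6 mouse; the mass is configurable because the source study does not
state it. Photon dose and cross-organ terms are out of scope.

`integrate_tac()` uses the trapezoid rule with two explicit edge
conventions, chosen so tests can be exact: the initial segment rises
linearly from (0, 0) to the first sample (an i.v. bolus is fast but not
instantaneous), and the tail beyond the last sample decays with the
*physical* half-life only, contributing $A_\mathrm{last}/\lambda$. Ignoring
biological clearance in the tail is conservative; with curves sampled to
seven-plus physical half-lives the tail is negligible anyway. Simulated
curves are sampled on a log-spaced grid (default 400 points from 0.25 h to
1200 h), dense early where the fast clearance component changes quickly;
on such grids the trapezoid integral agrees with adaptive quadrature of
the generating model to well under 1%.

### The saturable uptake model

The published doses (16, 29, 40, 48, 54 Gy for 30--150 MBq) imply a
dose per MBq that falls with injected activity, consistent with
receptor-mediated uptake saturating at therapeutic amounts of peptide. The
generator uses the simplest form with that behavior, a one-site curve for
the fraction of injected activity at the uptake plateau:

$$u(A) = \frac{u_0\, k_\mathrm{sat}}{k_\mathrm{sat} + A},$$

followed by biexponential biological clearance (defaults: 90% clearing
with a 12 h half-life, 10% with 120 h — ordinary small-animal kinetics,
fixed once; the source study gives no kinetic form) multiplied by physical
decay. `calibrate_uptake_model()` fits $D(A) = B A/(k_\mathrm{sat}+A)$ to
the three lower anchors (30→16, 60→29, 90→40 Gy) by nonlinear least
squares and converts $B$ into $u_0$ by measuring, with the pipeline's own
integration scheme, the dose delivered per MBq of plateau activity. The
calibrated model ($u_0 \approx 0.093$, $k_\mathrm{sat} \approx 274$ MBq —
a ~9% zero-activity kidney uptake, plausible for octreotate) then
reproduces all five published doses within ±10% (120 MBq: +2.6%; 150 MBq:
+5.9%). The two top anchors are consistency checks, not independent
predictions: the published doses rest on external biodistribution data
that this model only emulates.

## Synthetic expression studies

`gen_expression_set()` emulates the animal design: five activities plus
saline controls, three late time points (4/8/12 months), kidney cortex and
medulla, n = 3 exposed animals per group, and three age-matched controls
per time point shared across activities. Each gene gets a fixed baseline
log2 intensity (N(8, 1.5²)); exposed samples add the gene's true effect at
their (dose, time) cell; every measurement adds Gaussian log2 noise.
`noise_sd = 0.2` was chosen once as a typical replicate standard deviation
for log2 expression in an inbred strain under controlled conditions. Gene
classes are null, monotone in dose, late responders (effects from 12
months), and tabulated recurrent markers; the default model plants a
Cdkn1a-like gene carrying the published cortex dose profile (1.3, 1.0,
1.6, 1.4, 2.0 log2 at 12 months). Effects declared monotone are validated
against the design's dose grid at generation time. The default simulated
array has 1000 genes — a deliberately scaled-down array that keeps the
full test suite fast while preserving the mostly-null composition real
normalization assumes.

What the generator does *not* emulate: probe/bead-level structure,
background correction, array batch effects, heteroscedastic or correlated
genes, and outlier animals. Passing tests therefore demonstrate the
statistical pipeline's behavior under its stated assumptions, not
robustness to those artifacts.

## Differential expression

The testing stage follows the published criteria exactly where they are
stated: log2 intensities, quantile normalization, a variance filter,
per-group comparison against age-matched controls, Benjamini-Hochberg
adjustment, and the dual threshold — significant iff FDR-adjusted
q < 0.01 **and** |log2 ratio| > 0.58 (log2 of a 1.5-fold change), both
strict, so boundary values are not significant.

Choices the source leaves open, decided here:

* **Test statistic.** A two-sided Welch t-test on log2 values per gene and
  group (n = 3 vs 3). It is transparent, matches the log-scale ratio, and
  is checkable by hand; no variance moderation is applied. The
  implementation is vectorized across genes and cross-checked against
  `t.test()`. When both groups have exactly zero variance, p = 1 if the
  means agree and p = 0 otherwise (a convention only reachable with
  noise-free input).
* **Adjustment family.** BH is applied per (tissue, time point, activity)
  group across genes; the family choice is echoed in output metadata.
* **Order and cutoff of the variance filter.** Normalize first, then drop
  the lowest 20% of cross-sample variances (configurable). Zero-variance
  genes are always dropped when the filter is active; an all-constant
  matrix filters to empty with a warning rather than an error.
* **Tie handling in quantile normalization.** Tied values receive the mean
  of the across-sample order-statistic means over their tied rank range
  (`limma::normalizeQuantiles(ties = TRUE)`, cross-checked in the tests
  against a hand-rolled implementation).

`de_all_groups(normalize = FALSE)` skips the renormalization step. This
exists because quantile normalization presumes a mostly-null gene
population; on a small focused panel with many planted effects it provably
compresses them (on a 40-gene panel with 13 planted genes it roughly
halved realized detection power in our Monte-Carlo runs). The simulator's
output is calibrated across samples by construction, so the Monte-Carlo
studies of estimator bias, detection power, and dose-response scoring run
the testing stage directly; the realized-FDR study keeps the full path,
where normalization is harmless under the global null.

### Power and error under the study design

With n = 3 per group the per-group power of this design is intrinsically
modest: at a true effect of 0.8 log2 (4× the noise SD) the fold-change
criterion alone is met with probability ≈ 0.91, and BH at q < 0.01 across
a panel demands very small p-values at ~4 degrees of freedom. Detection is
therefore assessed at the gene level — a planted gene counts as detected
when called significant in at least one of its dose-by-time groups, the
same unit the recurrence analysis counts. Under the default two-tissue
design, a 40-gene panel with twelve monotone genes whose top-dose effects
span 0.8--2.4 log2 is detected at ≥ 0.9 aggregate power over 200 seeds,
and a single gene planted at 2.0 log2 at the top dose only is recovered in
over 95% of seeds. Under the global null the mean realized false-discovery
proportion per BH family stays at or below 0.02 over 50 seeds.

## Biomarker analysis

* **Recurrence.** Significant calls are arranged as a genes × 15-group
  matrix per tissue (`build_recurrence()`); a gene's recurrence count is
  its number of filled cells. "Recurrent" defaults to ≥ 2 groups, a
  configurable convention since the source never quantifies it. The
  packaged marker panel reproduces the published pattern: 34 (cortex) and
  32 (medulla) unique previously proposed kidney-injury/radiation markers,
  with Cdkn1a filled in 12/15 cortex and 13/15 medulla groups. One
  packaged cell (Ccnd1, medulla, 12 months, 120 MBq) prints as exactly
  0.58: printed values are rounded, so fixture-mode recurrence takes
  printed cells as the published significant calls and does not re-apply
  the strict threshold, which only governs the simulation path.
* **Dose response.** Spearman rank correlation of dose-ordered log2 ratios
  (average ranks for ties, pairwise-complete cells, fewer than three
  complete pairs reported as insufficient data rather than an error), plus
  a strict-monotonicity flag. The published Cdkn1a cortex profile at 12
  months scores ρ = 0.8. The statistic choice is ours; the source asserts
  dose dependence without naming one.
* **Upstream regulators.** A transparent overlap computation: per
  regulator, the intersection of its packaged target set with the query
  gene set, with a one-sided Fisher exact (hypergeometric tail) p-value
  and a deterministic ranking (overlap desc, p asc, name). This
  deliberately does not reproduce any proprietary causal-network score.
  The universe defaults to the post-filter array size (20000 in the
  drivers). In fixture mode the recurrent-transcript evidence spans both
  packaged tables — the marker panel's genes and the regulator map's
  targets (listed precisely because they recur).

## Scintigraphy

The simulator renders 256 × 256 planar frames: kidneys as 2D Gaussian
blobs (σ = 6 px, truncated at 3σ and renormalized so expected counts are
exact), the bladder as a uniform disc (r = 10 px), the calibration syringe
as a 16 × 8 px rectangle outside the body, and the remainder of the
injected activity spread uniformly over a body ellipse. Expected counts
per object are sensitivity × activity × duration (default 2000
counts/MBq/min, a single-head parallel-hole magnitude) plus a uniform
background (0.02 counts/px/min); Poisson noise is applied pixelwise, with
a noise-free mode for exact expectations. Renal tracer kinetics are a
linear two-compartment chain (body pool → kidneys → bladder, defaults
0.08/min and 0.10/min) tracked as decay-corrected fractions so mass is
conserved exactly; an impairment factor in [0, 1] scales the excretion
rate, with 0 reproducing the accumulate-with-no-bladder-filling pattern
seen at the highest exposures. Frames apply ^99m^Tc decay (6.007 h) at the
frame midpoint; the syringe is rendered at its stated constant activity,
so `quantify_frame()` explicitly decay-corrects the calibrated ROI
activity back to injection time.

ROIs follow the published rule: all pixels at or above 10% of the maximal
pixel count, as the 8-connected component containing a seed. The maximum
is local — computed in a window (default 61 px) around the seed — because
the global frame maximum is the syringe. Seeds are supplied by the caller;
there is no automatic organ detection. Two intrinsic properties of this
rule are worth knowing:

* **Threshold truncation.** On a Gaussian kidney the 10% contour encloses
  ~90% of the counts, so segmented %IA underestimates truth by roughly
  10%. Ratio quantities (DMSA percent of control) are unaffected because
  both numerator and denominator truncate alike. Unbiasedness of the
  calibrated quantification itself is asserted with the generator's truth
  masks.
* **Low-contrast bleed.** Early DTPA frames have a cold bladder (~2% IA in
  a flat disc, only ~2× the body pool per pixel), so the 10%-of-max ROI
  merges with surrounding tissue. The qualitative renogram checks
  therefore assert segmented-bladder monotonicity from 7.5 min on and
  verify full-series monotonicity against the kinetic oracle with truth
  masks. A bladder too cold to segment at all (full obstruction) is
  recorded as 0 %IA and flagged rather than raising an error.

The DTPA protocol is seven 1-minute frames at 2.5--32.5 min with the
bladder content read at 27.5 min; DMSA is a single 3-minute frame at 3 h,
normalized to the mean control %IA. Group comparisons use the classical
paired two-sided t-test with significance at p < 0.05 (strict); all-zero
differences give t = 0, p = 1, and zero-variance nonzero differences give
p = 0 with a degeneracy flag.

## Blood markers

Panels carry WBC, RBC, urea, and creatinine with fixed baselines (8 ×
10⁹/L, 9 × 10¹²/L, 8 mmol/L, 20 µmol/L). Group summaries are ratios of
group means (n = 3), reported the way the study reports them: percent of
control, a reduction factor (100/percent, one decimal) for quantities that
fall, and a fold increase (percent/100, also rounded to the nearest
integer for "n-fold" phrasing). The packaged ratio table yields WBC
reduction factors 2.0/1.9/1.6 at 4 months (30/90/150 MBq) and a 5-fold
urea increase at 12 months after 150 MBq. The simulator plants the
packaged ratio as the expected value with multiplicative log-normal noise
(CV 0.1) and maps absorbed dose to the nearest published activity level;
creatinine cells are stored exactly as printed (essentially all 100%).

## Numerical and degenerate-input conventions

* Energy conversion fixed at 1 keV = 1.602176634 × 10⁻¹⁶ J; 1 MBq·h =
  3.6 × 10⁹ decays.
* All generators take explicit seeds and restore the caller's RNG state;
  the pipeline derives every stage seed from one master seed, and repeated
  runs are byte-identical.
* Strict inequalities at every published threshold (q < 0.01,
  |log2 ratio| > 0.58, p < 0.05).
* Empty ROI masks quantify to 0 MBq / 0 %IA; zero syringe counts are a
  calibration error; zero control means are normalization errors.
* Unknown pipeline-configuration keys are errors.

## Problem sizes

The shipped tests and drivers use sizes chosen to keep a laptop run short
while leaving the statistics meaningful: 40--1000 simulated genes, 200
seeds for power/bias/dose-response Monte-Carlo runs, 50 seeds for the
null-FDR study, and 500 Poisson replicates for quantification
unbiasedness. Each is a package choice stated here, not a statistical
necessity; all scale up linearly.

## Known limitations

* The uptake model is a calibrated stand-in for external biodistribution
  data; its doses are consistency checks, not predictions, and the kidney
  mass default (0.3 g) is an assumption.
* No attenuation, scatter, collimator blur, or depth modeling in the
  scintigraphy simulator, matching the study's own
  "similar attenuation" calibration convention.
* The Welch test with n = 3 has limited per-group power (discussed above);
  conclusions about single groups rest on few degrees of freedom, exactly
  as in the animal study.
* Gene symbols are matched case-insensitively after trimming; no attempt
  is made to resolve aliases.
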