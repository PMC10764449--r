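---
title: "Linking home-cage locomotion to tendon-healing histomorphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking home-cage locomotion to tendon-healing histomorphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tendonwatch` models a preclinical study design in which mice with
surgically injured Achilles tendons live in digital ventilated cages (DVCs)
that record a smoothed locomotion index continuously, with or without access
to a running wheel, and are assessed 28 days post-injury by quantitative and
semi-quantitative tendon histomorphometry. The scientific question is
whether unbiased night-time activity predicts the recovery of tissue
microarchitecture. This vignette documents the models, the tunable
parameters, the numerical choices, and the limits of what the synthetic
validation can show.

## The activity model

A cage's locomotion index is simulated at one-minute resolution (the
sampling period of real DVC exports varies by configuration; one minute is
fine enough for every analysis here, which aggregates to 3-hour bins or
half-day means). The expected index at minute $t$ of day $d$ is

$$\mathbb{E}[x_t] = m_{b(t)} \cdot f(d),$$

where $m_0,\dots,m_7$ is a circadian template of eight 3-hour levels
(bin 0 starts at lights-on, 07:00; bins 4–7 are the dark period) and $f$ is
a multiplicative injury factor:

$$f(d) = \begin{cases}
1 & d < 0\\
g - \bigl(g - (1-\delta)\bigr)\,e^{-d/\tau} & d \ge 0,
\end{cases}$$

with dip depth $\delta \in [0,1]$, recovery time constant $\tau$ (days) and
asymptotic gain $g$ (final-to-baseline night activity). Gaussian noise is
added and the trace clipped to $[0,1]$. The exponential-relaxation form is
the package's modelling choice: the study design only fixes the qualitative
features (a global activity minimum on the surgery day, recovery from day 1,
group-dependent late levels), and a single dip-plus-relaxation is the
simplest family exposing exactly those knobs. `injury_factor()` is exported
so tests can check the generator against its own closed form.

The packaged template `c(0.10, 0.07, 0.06, 0.09, 0.52, 0.42, 0.30, 0.20)`
puts every dark bin above every light bin and peaks in the 12–15 h bin just
after lights-off, then decays to the 21–24 h bin — the canonical nocturnal
mouse profile. Group presets differ only in $(\delta, \tau, g)$: lesioned
groups dip by 55–65% on day 0, free-wheel groups recover faster
(bilateral-free overshoots baseline, $g = 1.12$), blocked-wheel groups
plateau below it ($g = 0.92$–$0.97$); controls get a mild rehousing dip
($\delta = 0.15$). These are qualitative orderings chosen once, not fitted
values — the study they emulate reports no group-level quantitative
activity parameters.

Analysis conventions: a sample belongs to the light period iff its clock
time is in [07:00, 19:00) (half-open, so the light/dark split is an exact
partition); the "night of day $d$" is the 12 h following day $d$'s
lights-off; day 0 is the surgery day. Light-period analyses exclude days 0
and 14 by default (surgery and food-supplementation artifacts), via a
configurable day mask that does not touch night-period analyses. Baseline
normalization divides each post-surgery night mean by the mean of the last
3 pre-surgery nights; control normalization divides each animal's day 0–27
mean by the wheel-matched control-group mean. The day 0–27 window (rather
than 1–27) is the default aggregation; a `days` argument changes it. SEMs
use the $n-1$ standard deviation.

## The histology field model

Each synthetic field is 370 × 250 µm at 0.5 µm/pixel (740 × 500 px), so the
5-areas-by-4-fields sampling scheme totals exactly 1.85 mm²; the study
design states only the total, and this factorization is the package's
choice. A field contains a Poisson number of nuclei (healthy mean 70 per
field, the healthy-tissue reference value), placed by rejection sampling
under a minimum center distance, with a fallback to unconstrained placement
after 200 rejections (recorded per nucleus in the ground truth, so tests
can exclude forced placements from spacing checks). Nuclei are 20 × 4 µm
ellipses — the elongated spindle shape of tenocyte nuclei — rendered with
an anti-aliased one-pixel soft edge at intensity 0.63 over a 0.08
background, plus Gaussian camera noise (SD 0.03).

Orientations are drawn from a normal with the healthy mean at 17.02° and SD
8°, folded to (−90°, 90°]. A folded normal rather than a von Mises keeps
the generator on the same family as the estimator's Gaussian peak fit, so
parameter recovery is a well-posed check. The healthy spacing (21 µm,
slightly above the nucleus length) makes fused pairs rare, so the expected
*detected* count equals the Poisson mean; injured presets use 10 µm spacing
and higher densities (100–150 per field) with wider dispersions (12–22°)
and larger mean angles (24–45°), ordered bilateral-free best to
unilateral-blocked worst. Again: orderings, not fitted values.

## Nuclei detection

`detect_nuclei()` re-implements a standard primary-object segmentation:
Gaussian smoothing (σ = 1 µm), global Otsu threshold, 8-connected
components, an 8–120 µm² area filter, and distance-transform watershed
declumping for components above 110 µm² (≈1.8× the packaged single-nucleus
area of 63 µm²). Orientation per object comes from the second central
moments of its pixel set.

One guard is worth explaining: Otsu always *finds* a threshold, even in a
field that contains nothing but noise, and smoothed noise then yields
hundreds of spurious components. Detection therefore requires genuine
bimodal separation between the two Otsu classes,
$(\mu_{fg}-\mu_{bg})/s_{within} \ge 4$: a pure-Gaussian image splits well
below this cutoff regardless of its variance, while any field with real
nuclei scores far above it. Below the cutoff the field is reported empty,
and a test covers the noise-only case. An exactly
constant image (Otsu undefined) returns an empty set with a warning flag
rather than an error.

## Directionality

`directionality()` computes per-pixel local orientation from the smoothed
structure tensor $J = G_\sigma * (\nabla I \,\nabla I^\top)$, accumulates an
orientation histogram over (−90°, 90°] in 2° bins (90 bins, the convention
of the common interactive tools), and fits a single Gaussian with constant
offset, initialized at the tallest bin and unwrapped circularly around it.
The fitted center is the tissue *direction*, the SD the *angle dispersion*,
and the histogram mass within ±2 SD of the center the *goodness*.

Three numerical choices matter, and all were made by measuring parameter
recovery on the generator (whose truth is known):

- **Gradient kernel.** The default is the Scharr 3×3 kernel (weights
  3/10/3), not Sobel. Sobel's angular anisotropy biases the fitted peak by
  one to two degrees toward the image axes on fields of small ellipses;
  Scharr, designed for rotational accuracy, removes most of the bias (a
  test asserts the default kernel sits closer to the 17.02° truth than
  Sobel does on the same fields). `kernel = "sobel"` remains available.
- **Tensor smoothing.** σ = 4 px (2 µm at the default pixel size) rather
  than a tighter 2 px: wider smoothing lowers the coherence of the highly
  curved ellipse ends, concentrating histogram mass in the straight flank
  segments that actually carry the orientation signal.
- **Histogram weight.** Pixels are weighted by coherence$^4$ × energy. The
  fourth power sharpens the same effect; with it, the mean fitted
  dispersion lands within 2° of the generator's 8° orientation SD (a test
  asserts this), where plain coherence weighting overshoots substantially.
  The *isotropy flag* — "no
  bin above twice the uniform level", reported as `low_goodness` — is
  evaluated on the plain coherence × energy histogram instead, because the
  sharpened weighting amplifies the pixel-grid diagonal bias of white noise
  past that threshold.

The fitted dispersion still slightly exceeds the generator SD (the
single-ellipse orientation kernel has finite width, and variances add);
this is an estimator property shared with the interactive tools the
procedure mirrors, and the dispersion *ordering* across presets — what the
scoring rubric consumes — is preserved (a strict-monotonicity test covers
SDs of 4°, 8°, 16°). If the least-squares fit fails to converge, weighted
circular moments of the histogram are used as a fallback.

Per-tendon aggregation weights each field's direction and dispersion by its
goodness, using the axial (period-180°) circular mean for directions; a
test checks this against refitting the pooled histogram. The direction
ratio versus healthy folds both directions to [0°, 90°] before dividing; a
healthy direction of exactly 0° makes the ratio undefined and raises an
error pointing to the absolute-deviation mode (`mode = "deviation"`), which
is also the reading some presentations of "angle deviation" suggest — the
package implements both and defaults to the ratio.

## The scoring rubric

The six-parameter rubric is shipped as a versioned YAML rule table
(`inst/extdata/scoring_rules.yaml`) and encoded in `score_*()` functions.
Two boundary ambiguities in the rubric wording had to be fixed, and the
choices are recorded in the rule file so they are auditable:

- cellularity: score 1 is $(2, 3]$ and score 2 is $[1.3, 2]$, so a fold
  change of exactly 3 scores 1 and exactly 1.3 scores 2 (the "<1.3" of
  score 3 read strictly);
- alignment: the rubric's score-1 band "3 < ratio > 2.1" is read as
  $(2.1, 3]$, and score 2 absorbs everything at or below 2.1 that is not
  score 3 (ratio < 1 with dispersion < 25%), leaving no gap at $(2, 2.1]$;
- metaplasia "up to four areas" is read as 2–4, since one area has its own
  band;
- the dispersion threshold "25%" is interpreted as a percentage of the 90°
  orientation half-range (`dispersion_to_percent()`), i.e. 22.5°; the
  source rubric never states the unit conversion from degrees.

Totality (every admissible input maps to exactly one score in 0–3),
monotonicity in each driving quantity, and recovery of every stated
threshold by bisection are all tested. The THS is the exact integer sum of
the six sub-scores; the healthy reference sits at 18 by construction of the
control profiles (the source material never prints its healthy reference
value, so 18 is asserted only of the generator's own controls).

## Agreement and inference

Cohen's κ uses the fixed category set {0, 1, 2, 3} (unused categories
contribute zero marginal mass) and returns exactly 1 in the degenerate
single-category case. Weighted κ defaults to linear weights $|i-j|/3$ —
the common choice for ordinal clinical scores — with quadratic weights by
flag; the scheme used is recorded in the output. The assessor simulator
perturbs true scores by at most ±1 step, which matches the high-agreement
regime these studies report and keeps the weighted-κ expectations simple.

The correlation module computes product-moment correlations pairwise-
complete, Fisher Z′ 95% CIs, and $t$-based two-tailed p-values on $n-2$
degrees of freedom. No multiplicity correction is applied by default (the
emulated analysis applies none); a Holm column is available by flag.
Perfect correlations are flagged degenerate with point CIs rather than
propagating infinities. ANOVA + Tukey HSD and the t-tests delegate to the
standard base-R fits (`aov`, `TukeyHSD`, `t.test`; tests verify them
against hand-computed decompositions and `ptukey`); the t-test defaults to
the pooled Student form, the classic reading of "independent t-test", with
Welch by flag. D'Agostino–Pearson K² is implemented from the
transformed-moment formulas (no installed package provides it) and is
validated against frozen values from an independent implementation; it
refuses $n < 8$.

The metric-cohort generator draws from a multivariate normal whose
correlation matrix carries the three reference coefficients (activity ×
alignment 0.41, activity × dispersion −0.76, cellularity × alignment 0.54,
all other off-diagonals 0 — a matrix that is positive definite, smallest
eigenvalue 0.086). Factorization is by eigendecomposition (via
`MASS::mvrnorm`), which also handles exactly singular specs such as a
$\rho = 1$ pair. Non-PSD inputs are rejected with the smallest eigenvalue
reported, or repaired by eigenvalue clipping plus unit-diagonal rescaling
when explicitly requested. Marginal means and SDs (activity 1.0 ± 0.2,
direction ratio 1.6 ± 0.45, dispersion 20 ± 5°, fold change 1.8 ± 0.35) are
plausible tendon-level values, chosen once.

One statistical subtlety: the recovery test for the correlations compares
the mean sample $r$ over 500 cohorts of $n = 52$ against the *finite-sample
expectation* $\rho\,(1 - (1-\rho^2)/(2(n-1)))$ rather than against $\rho$
itself. At $\rho = -0.76$ and $n = 52$ the $O(1/n)$ bias of $r$ (~0.003) is
comparable to two Monte-Carlo standard errors of the 500-cohort mean
(~0.005), so $\rho$ would be the wrong center for a sampling-distribution
check at this precision.

## The pipeline

`run_study()` chains generation and analysis into one run, writing every
intermediate table (CSV/JSON) so each stage can be re-run and inspected
independently; per-stage seeds derive from the master seed by a fixed
counter (`derive_seed(seed, stage)`), making two runs of the same
configuration byte-identical. `validate_config()` reports every structural
violation with a path into the configuration and must pass before a run
starts. A control-only design skips the correlation stage with a logged
reason rather than failing. Per-tendon true sub-scores are the group
profile jittered by ±1 with probability 0.2 (biological variability, so
group THS summaries have realistic spread), and the two simulated assessors
then rate those true scores with a 0.1 one-step confusion probability.

Problem sizes: the packaged full design simulates 64 cages × 35 days of
minute data, but images only a configurable subset of tendons
(`tendons_imaged_per_group`, default 1) because field synthesis and
analysis dominate runtime (~1.5 s per 740 × 500 px field); the remaining
tendons enter through the metric cohort ($n = 52$, the full histology
sample). `demo_config()` scales everything to seconds (2 animals and 2
tendons per group, 120 × 90 µm fields, ~12 nuclei) and is what the examples
and the pipeline tests use. Parameter-recovery checks run at 100 fields /
500 cohorts, sizes at which Monte-Carlo error is well below the tolerances
being asserted.

## What the synthetic validation does and does not show

Passing tests demonstrate that every estimator recovers the parameters of
data generated under its own assumptions: clean circadian structure,
elliptical non-overlapping-ish nuclei on a flat background, Gaussian
orientation scatter, multivariate-normal metric cohorts, and ±1-step
assessor noise. Real DVC traces have cage-change artifacts, weekend
effects, and sensor drift; real fluorescence fields have uneven
illumination, out-of-focus nuclei, staining variability, and genuinely
overlapping cells; real ordinal raters disagree in structured, non-random
ways. None of these are modelled, deliberately: the package validates the
*computational* chain, not the robustness of the assays. The two-channel
semi-quantitative parameters (COL1 organization, vascularity, metaplasia)
enter as annotated observations, not as synthesized images, and wheel
rotations are not simulated (the emulated cage system does not sense them).
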