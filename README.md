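# tendonwatch

Can the round-the-clock locomotor activity of a mouse recovering from an
Achilles tendon injury predict how well the tendon itself is healing?
`tendonwatch` implements the full analysis chain needed to ask that question
in a preclinical home-cage-monitoring study, together with a synthetic-data
generator that reproduces the statistical structure of such a study with
known ground truth — so every estimator in the chain can be validated
end-to-end without any animal data.

The package is aimed at preclinical researchers working with digital
ventilated cage (DVC) activity data and quantitative tendon histology, and at
methodologists who want a fully testable reference implementation of this
kind of pipeline.

## What it computes

**Activity metrics** from a minute-resolution locomotion index in [0, 1]
under a 12/12 h light/dark schedule (lights on 07:00–19:00):

- daily light/dark means (`split_day_night()`), with day 0 = surgery day;
- circadian profiles as eight 3-h bins from lights-on (`bin_3h()`),
  aggregated over baseline and post-surgery weeks
  (`aggregate_bins_by_period()`);
- night activity normalized to the last 3 pre-surgery nights
  (`normalize_to_baseline()`) and to the wheel-matched control group
  (`normalize_to_control()`).

**Histomorphometry** on single-channel (nuclei) fluorescence fields sampled
as 5 tendon areas × 4 fields (370 × 250 µm each, 1.85 mm² total):

- nuclei detection by Gaussian smoothing → Otsu threshold → connected
  components → area filter → watershed declumping (`detect_nuclei()`);
- texture directionality by structure tensor: an orientation histogram over
  (−90°, 90°] in 2° bins is fitted with a single Gaussian, whose center is
  the tissue *direction* and whose SD is the *angle dispersion*
  (`directionality()`);
- cellularity fold change and direction ratio versus healthy controls, and
  per-tendon aggregation (`assemble_tendon_metrics()`).

**Scoring**: the six-parameter ordinal rubric (cellularity, alignment, COL1
organization, vascularity, chondro- and osteometaplasia; each 0–3) as an
executable, serializable rule table, summed into the Total Histological
Score, THS ∈ [0, 18] (`score_*()`, `total_histological_score()`).

**Agreement** between two blinded assessors: percent agreement, Cohen's κ,
and weighted κ (linear `|i−j|/3` or quadratic weights) on 0–3 rating tables.

**Inference**: Pearson correlation matrices with Fisher Z′ confidence
intervals `tanh(atanh(r) ± 1.96/√(n−3))`, one-way ANOVA with Tukey HSD,
pooled/Welch two-tailed t-tests, and the D'Agostino–Pearson K² normality
test (`pearson_matrix()`, `one_way_anova_tukey()`, `independent_t_test()`,
`dagostino_pearson()`).

**Generators with ground truth**: circadian activity traces with a
surgery-day dip and exponential recovery (`simulate_activity()`), fields of
oriented elliptical nuclei (`simulate_histology_field()`), tendon-level
metric cohorts with a prescribed correlation matrix
(`simulate_metric_cohort()`), and noisy two-assessor rating tables
(`simulate_assessors()`). `run_study()` chains everything into one
reproducible run.

## Worked example

```r
library(tendonwatch)

# one healthy-tendon field with known ground truth
preset <- study_histology_presets()$ctr
field  <- simulate_histology_field(preset, area_index = 3, field_index = 1,
                                   seed = 3)
nrow(attr(field, "ground_truth")$nuclei)   # 61  (true nucleus count)
nrow(detect_nuclei(field))                 # 61  (all recovered)

d <- directionality(field)
round(c(direction = d$direction, dispersion = d$dispersion), 2)
#   direction dispersion
#       18.09       8.52
```

The preset encodes healthy tissue with mean orientation 17.02° and
dispersion 8°; on this field the estimator reads 18.09° and 8.52°, and over
100 fields the mean fitted direction sits within a fraction of a degree of
the preset truth. Scoring the tendon-level metrics:

```r
score_cellularity(1.2)                       # 3 (near-healthy cell density)
score_alignment(0.9, dispersion_percent = 20) # 3 (parallel, low dispersion)
total_histological_score(3, 3, 3, 3, 3, 3)$ths  # 18 (healthy ceiling)
```

A full synthetic study (activity → histomorphometry → scoring → agreement →
correlations) at reduced scale:

```r
bundle <- run_study(demo_config(seed = 1), "demo_out")
read.csv(bundle$files$ths_summary)
#                group mean_ths    sd_ths n
# 1  bilateral_blocked     10.0 2.8284271 2
# 2     bilateral_free     13.0 1.4142136 2
# 3        ctr_blocked     17.5 0.7071068 2
# 4           ctr_free     18.0 0.0000000 2
# 5 unilateral_blocked     10.0 0.0000000 2
# 6    unilateral_free     10.0 1.4142136 2
```

Controls sit at the rubric ceiling, bilateral-free animals heal best among
the lesioned groups, and blocked-wheel unilateral animals worst — the
ordering the generator encodes and the scoring stage recovers.

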