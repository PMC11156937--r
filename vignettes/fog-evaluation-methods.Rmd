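---
title: "Measuring freezing-of-gait detectors: metrics, agreement and daily-living profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring freezing-of-gait detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogbench)
```

## The measurement problem

Freezing of gait (FOG) is an episodic, context-dependent inability to start
or continue walking in Parkinson's disease. The reference way to quantify
it is frame-by-frame expert review of video: two trained raters mark, for
every moment of a FOG-provoking protocol, whether the person is frozen and
in which triggering context — gait initiation ("start hesitation"), turning,
or straight walking; episodes whose context cannot be determined are marked
`notype`. Automated detectors replace this labor with per-sample confidence
scores computed from a single lower-back 3-axis accelerometer (128 Hz
protocol recordings in m/s²; 100 Hz home recordings in g, with per-sample
Valid/Task flags restricting which samples may be scored).

`fogbench` implements the *evaluation* side of that pipeline: the scoring
metric, the operating-point metric family, the episode-level gold-standard
outcomes, the agreement statistics, and the daily-living hourly analysis —
plus a synthetic generator so that each stage can be exercised and tested
without the original recordings or any trained model.

## Scoring: per-sample average precision

A detector submits, per sample and per class, a real confidence score.
For one class with binary ground truth and an evaluation mask, the package
computes non-interpolated average precision over descending unique score
thresholds:

$$\mathrm{AP} = \sum_n (R_n - R_{n-1})\, P_n,$$

with tied scores sharing a threshold. The headline metric, mAP, pools the
samples of all sessions per class (micro-averaging — a single pooled
submission is what gets scored), excludes `notype` samples from every
per-class computation (their class is unknown but their FOG status is not;
they re-enter the binary all-FOG analyses as positives), and averages the
three class APs unweighted. Undefined metrics — no positives under the mask
— raise classed errors rather than returning 0, because silent zeros corrupt
rankings. Correctness is anchored to a brute-force threshold-enumeration
oracle (the test suite compares 1,000 random instances of length ≤ 12,
including dense tie patterns, exactly), since no worked numeric example of
the metric exists to transcribe.

## Operating points and the confusion-metric family

PR and ROC curves are built one point per unique threshold; AUC is the
trapezoidal area. The decision threshold for the metric family (F1,
accuracy, precision, recall, specificity) minimizes the Euclidean distance
of the PR point to $(1,1)$. Two deliberate choices:

* *Tie-break toward higher recall, then lower threshold.* A missed freeze
  carries higher clinical cost than a false alarm; when two PR points are
  equidistant from (1,1) the more sensitive one wins. Configurable in the
  sense that the caller can select any threshold and pass it downstream.
* *All-FOG scores are the per-sample maximum over the three class
  channels.* How the binary FOG-vs-non-FOG score stream should be formed
  from three class confidences is not prescribed anywhere; the max rule
  treats a sample as exactly as suspicious as its most confident class,
  and it is invariant to which class carries the evidence. Thresholds are
  selected per class and separately for all-FOG, since each problem has
  its own PR geometry.

## Episodes and the three gold-standard outcomes

Maximal runs of positive samples form episodes (0-based, half-open sample
intervals — uniform duration arithmetic, no off-by-one at concatenation
boundaries). Per subject the package reports percent time frozen
(%TF = 100 · masked FOG time / masked observation time), the episode
count, and total FOG duration. Post-processing knobs exist —
`merge_gap_s` merges runs separated by short gaps, `min_duration_s` drops
brief episodes — but both default to off: the reference analyses were run
without event post-processing, and episode *counts* are known to be
sensitive to split/lump behavior in a way durations are not. The invariant
battery checks conservation (durations × rate = positive samples),
transition-count identity, and monotonicity of both knobs.

## Agreement statistics

Model-vs-truth agreement on the per-subject outcomes uses the
single-measure, absolute-agreement, two-way ICC (Shrout–Fleiss ICC(2,1)),
computed from the row/column/error mean squares of the subjects × raters
matrix; absolute agreement (rather than consistency) is required because a
detector that systematically over-counts episodes should be penalized, not
forgiven. Day-to-day stability of daily %TF uses the mean-rating
absolute-agreement form ICC(A,k) with k = 6 days — recordings do not all
span seven complete days, so the first six are used and incomplete subjects
are dropped rather than imputed. The literature describes the day-to-day
form as "2-way mixed" while the model-agreement form is written "ICC(2,1)"
(random raters); the mixed/random distinction affects interpretation, not
the point estimate, so both are computed from the same decomposition and
named explicitly in the result object. Confidence intervals use the
McGraw–Wong F-distribution method; the test suite verifies both estimators
against an independent `aov()` sums-of-squares oracle at 1e-10 and checks
95% CI coverage empirically (500 panels, n = 15, true ICC 0.8, coverage
required in [0.90, 0.99]).

Group effects are summarized with Cohen's d using the df-weighted pooled
SD.

## Multiple testing: the two-stage BKY procedure

Hour-by-hour comparisons run 24 (or 16) tests, so the package implements
the Benjamini–Krieger–Yekutieli two-stage linear step-up procedure: stage
one runs the BH step-up at $q' = q/(1+q)$ to estimate the number of true
nulls from its rejection count $r_1$; stage two re-runs the step-up at
$q'\,m/(m - r_1)$. Adjusted p-values are defined operationally as the
smallest nominal $q$ at which a hypothesis is rejected, found by bisection
(the rejection region grows monotonically in $q$). The tests compare
rejection sets against a literal transcription of the two-stage definition
on 1,000 random p-vectors.

## Daily living: bout-restricted hourly %TF

Week-long 24/7 recordings are evaluated only during walking bouts padded by
5 s on each side — freezing can only occur during or immediately around
gait, and the padding captures episodes at bout boundaries. Per clock hour,
%TF = 100 · FOG∧bout time / bout time; an hour with no bout time is
*undefined*, not zero, and week averages are taken over the days where the
bin is defined (no imputation of empty hours). Samples are attributed to
hour bins by their midpoints, so episodes spanning a bin edge split
pro-rata at sample resolution. Daily %TF uses the same ratio at day
granularity, and equals the bout-time-weighted mean of the defined hourly
values — an algebraic identity the property tests verify at 1e-9.

The statistics layer mirrors the reference analysis plan: per-hour
two-tailed Mann–Whitney U tests between freezers and non-freezers with BKY
adjustment (exact enumeration for small tie-free samples, tie-corrected
normal approximation otherwise — `stats::wilcox.test`'s policy, which is
also what the plan names); a Friedman test of the 16 daytime hours
(07:00–22:59) against each subject's *night reference* — the median of the
defined night-hour bins (23:00–06:59, the complement of the fixed daytime
window) — with per-hour paired Wilcoxon post-hocs, BKY-adjusted; a severity
split of freezers at the NFOG-Q median (cutoff 20; scores at the cutoff are
"moderate"); and a Friedman/Dunn comparison of the three severity groups.
That last design — an omnibus blocked test across three *independent*
groups — is statistically unusual; the package implements the
blocked-by-hour reading (group mean %TF per daytime hour, hours as blocks)
rather than substituting Kruskal–Wallis, and the Dunn mean-rank z tests run
on the same blocked ranks. Ensemble detectors combine by pointwise OR of
binarized member decisions (each member at its own operating point, since
no shared threshold is defined for heterogeneous models).

## The synthetic generator

The generator exists so that every stage above is exercisable end to end;
it emulates the statistical structure of the real datasets, not their
waveforms.

*Protocol sessions* are a semi-Markov chain over stand / walk / turn /
gait-initiation / rest with lognormal dwell times — explicit dwell
distributions give direct control over bout and episode durations, which a
per-sample Markov chain would not. On entering a trigger context an episode
of the matching class is injected with the configured probability (defaults
turn 0.6, walk 0.15, initiation 0.05 — turning dominates, as in the real
event tables). Episode durations are lognormal; no empirical duration
distribution is published, so the family is a modeling choice with exposed
parameters, and the class means are anchored to the event-table margins
(469.1 min over 2887 turn events ⇒ 9.7 s; 15.0 s start hesitation; 5.7 s
walking). A configurable fraction of episodes is akinetic (5.6% in the
128 Hz protocol dialect, 29.3% in the home dialect) and, in the home
dialect, a fraction is labeled `notype`.

*Signals* are deliberately spectral, not biomechanical: walking is a step
frequency fundamental (1.8 Hz) plus harmonic, trembling FOG a two-component
oscillation inside the 3–8 Hz freeze band, akinetic FOG and rest sit at the
noise floor, and segments are cosine-tapered at boundaries for continuity.
No attempt is made to imitate individual patients, and no acceptance
property depends on waveform detail beyond band location and variance
ratios — which is also the honest statement of what passing tests show
about real data: the pipeline arithmetic is right; nothing here validates
detection difficulty on real signals.

*Week-long recordings* place walking bouts per clock hour (dense daytime
walking, ~1.5 min bouts; sparse ~25 s night bouts — the bathroom-walk motif
that keeps the night reference defined), then fill bouts with episodes so
the expected within-bout FOG fraction is `severity × hourly_intensity`.
The default intensity profile peaks at 07:00 (early-morning off-medication
state) and 22:00, sets hours 02:00–03:00 to zero (a clean no-effect
stratum for specificity checks), and keeps a low positive level otherwise.
Non-freezers emit zero true FOG.

*Cohorts* (default 45 freezers / 19 non-freezers) draw subject severities
from a gamma distribution. Because non-freezers have identically zero %TF,
the pooled-SD standardized group difference depends on both group sizes;
the generator solves the gamma coefficient of variation from the requested
effect (`cv = 1/(d·sqrt((n_f−1)/(n_f+n_nf−2)))`) so the *population*
Cohen's d equals the injected value (default 0.7) for the cohort actually
generated. One consequence worth knowing: with a CV of ~1.7 the severity
distribution is strongly right-skewed, and the *sample* Cohen's d estimator
is biased upward at n = 45 (the sample SD under-estimates a skewed σ); the
20-run acceptance experiment measures a mean near 0.8 against the injected
0.7, inside the ±0.2 acceptance band. NFOG-Q scores are assigned
rank-monotonically in severity over 11–28 so the cohort median lands at the
questionnaire cutoff of 20 and the median split yields 25 moderate / 20
severe freezers.

*Detectors* of controllable quality score
`plogis(quality·indicator + N(0,1))` after jittering episode boundaries
and inserting false-positive bursts; quality 0 is an uninformative detector
(AP = prevalence in expectation), large quality approaches perfect ranking,
and AP/F1 must increase in rank with quality — the monotonicity acceptance
check.

Reproducibility: every generator takes an explicit seed; cohort members
derive independent substreams from `(seed, subject_id)` so subjects are
reproducible under any generation order.

## The freeze-index baseline

As a training-free end-to-end detector the package ships the classical
freeze index: the ratio of accelerometer power in the 3–8 Hz freeze band to
the 0.5–3 Hz locomotor band over a centered 4 s window. The spectral
estimator is fixed and stated — mean-detrended, Hann-windowed,
magnitude-squared FFT, band power by bin summation with half-weight
boundary bins, reflection padding at the edges — because the index is only
reproducible if its estimator is. Windows with numerically zero locomotor
power are capped at a configured maximum and flagged. The index is scale
invariant (a power ratio); on white noise it equals the bandwidth ratio
5/2.5 = 2 in expectation, which the tests use as a flat-spectrum oracle.
The min-max-scaled index is copied to all three class channels: the
baseline has no context model, so class attribution belongs to downstream
thresholding.

## Numerical and design notes

* Sample intervals are 0-based half-open throughout; durations are
  `(end − start)/fs`.
* Home-dialect acceleration units are taken as g with a configurable
  conversion constant (default 9.80665), recorded in the recording's
  provenance field; the protocol dialect is already m/s².
* The Time column may carry sample index or seconds; the dialect
  declaration (a shipped YAML file) says which.
* PR-curve threshold ties and distance ties use a 1e-12 comparison slack;
  F1 is checked to equal the harmonic mean of the reported precision and
  recall at 1e-12.
* Detector confidence noise is temporally smoothed (default 2 s moving
  window, unit variance preserved): real per-sample confidences are
  autocorrelated, and white noise would shred decision runs into
  one-sample episodes. The quality-monotonicity experiment re-scores one
  common noise realization at every quality level (common random numbers),
  under which AP is non-decreasing in quality pathwise, so the rank
  correlation isolates the quality dial rather than Monte-Carlo noise.
* Problem sizes in the test suite are chosen for density of evidence per
  unit compute: oracle batteries run at n = 1,000 instances; cohort
  recovery runs 20 seeds of a 45 + 19 cohort simulated at 1 Hz label
  resolution (hourly and daily %TF are sampling-rate invariant, so nothing
  is lost by not simulating 100 Hz waveforms for a week); waveform-level
  checks run at 32–128 Hz on minutes-long sessions.
* Known limitations: the generator's night bouts guarantee a defined night
  reference, which real compliance does not; walking-bout *detection* is
  out of scope (ground-truth bouts are an input; a naive stand-in would
  not validate the published bout detector); and nothing in the synthetic
  battery certifies performance of any real detector on real signals.
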