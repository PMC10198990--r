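---
title: "Consensus-based scoring of continuous affect ratings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-based scoring of continuous affect ratings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iettrack)
```

## The problem

In the Inferential Emotion Tracking (IET) paradigm, observers watch short
video clips in which the target character is blurred out and continuously
rate that character's affect on a two-dimensional valence-arousal grid. There
is no objective ground truth for "the character's true emotion", so accuracy
is defined against the *consensus* of the rater pool. `iettrack` implements
that scoring model — the Informal Cultural Consensus Model — together with
the reliability diagnostics, trait-correlation battery, and Monte-Carlo
video-subset (item) analysis that a study built on this paradigm needs, plus
a synthetic cohort generator so every stage can be validated against known
ground truth without any human data.

## The Informal Cultural Consensus Model

For one video and one affect dimension, stack the raters' time series into a
time x participant matrix. Each column is standardised (zero mean, unit
variance), and the consensus trajectory is the first principal component's
factor-score series — the weighted linear combination of raters that
captures the largest share of their shared variance. Raters who agree with
the pool are up-weighted; idiosyncratic raters are down-weighted. This is
"informal" consensus analysis: no guessing parameters are estimated, which
is appropriate for continuous responses.

A participant's accuracy on a video is the Pearson correlation between their
own series and the consensus scores. Accuracies are pooled on the
variance-stabilised scale: Fisher-Z transform (`atanh`), average, transform
back (`tanh`). Correlations are clipped to ±(1 − 1e-7) before `atanh` so a
perfect correlation stays finite; the perturbation is far below reporting
precision.

Choices a user should know about:

* **Standardisation before PCA.** Rater gain and offset are nuisance
  parameters (everyone uses the grid a little differently), so the PCA is
  run on standardised columns (equivalently, on the correlation matrix).
  This makes every downstream accuracy invariant to positive-gain affine
  transformations of any rater's series, which the test suite checks.
* **Sign convention.** A principal component is defined up to sign. Scores
  are flipped so the mean participant loading is non-negative; an exactly
  balanced loading pattern (numerically zero mean) is resolved toward a
  non-negative loading for the first sorted participant id. Correlation
  *magnitudes* never depend on this; only the sign of r does.
* **Leave-in by default.** The consensus for a video is computed from *all*
  raters, including the one being scored. With realistic pool sizes the
  self-contribution is negligible (the suite verifies leave-in and
  leave-one-out scores differ by < 0.05 at 50 raters); a
  `loo_consensus = TRUE` switch in `score_study()` provides the strict
  leave-one-out variant for sensitivity analyses.
* **Flat raters.** A rater who never moves the cursor has no defined
  correlation. That cell is recorded as *missing* and excluded from pooling
  — recording r = 0 would invent a datum.

## Reliability diagnostics

`bootstrap_ci()` provides percentile bootstrap intervals for any statistic
of a sample (per-participant and per-video accuracy summaries use the mean).

`permuted_accuracy_null()` builds the chance distribution of accuracy by
circularly time-shifting each rater's trajectory within each video before
re-scoring against the (unshifted) consensus. Circular shifting preserves a
series' autocorrelation and marginal distribution — the aspects that make
smooth trajectories spuriously correlate — while destroying temporal
alignment. Shifts stay at least 10 s away from zero lag in both directions.
One structural subtlety: summed over *all* circular shifts of a demeaned
series, the correlations with any fixed series cancel exactly, so excluding
the aligned near-zero shifts necessarily leaves the null mean slightly
negative, by about (autocorrelation mass within the excluded window) / T.
This is why the generator's default latent correlation length (3 s) sits
well below the 10 s minimum shift: at the default clip lengths the residual
bias is within ±0.05 and shrinks with clip duration.

`loo_difficulty_correlations()` implements the engagement check: rank videos
by pooled accuracy (the *difficulty function*); an engaged rater should find
the same videos hard as everyone else. Each participant's per-video accuracy
vector is correlated with the group's difficulty function computed *without*
them, and compared against a per-participant null built by permuting the
video labels of their own vector (5000 permutations by default).
Participants whose correlation falls inside the null 95% CI are flagged as
indistinguishable from random responders; `run_pipeline()` reports the
trait battery both with and without them (the sensitivity block).

## Trait associations

All associations are Spearman rank correlations (no distributional
assumptions), with the large-sample t approximation for p-values. The
planned battery defaults to 17 comparisons: the four task scores (IET
valence, IET arousal, Eyes Test, Films task) crossed with four trait
measures (AQ, EQ, fluid intelligence, crystallised intelligence), plus the
IET-valence x AQ re-run excluding flagged participants. The 17-way Bonferroni
correction `min(1, 17 p)` is applied at the plan size; the plan itself is an
explicit, user-editable tibble (`default_comparison_plan()`), since a
hard-coded implicit plan would be unauditable.

Partial Spearman correlations are computed by rank-then-residualise: every
variable is converted to average ranks, x- and y-ranks are residualised on
the covariate ranks (plus intercept) by least squares, and the partial rho
is the Pearson correlation of the residuals. With one covariate this matches
the classical recursion `(r_xy − r_xz r_yz) / sqrt((1−r_xz²)(1−r_yz²))` on
rank correlations to 1e-10 (tested), and with no covariates it reduces
*exactly* to the plain Spearman rho. Bootstrap CIs case-resample
participants, recompute the partial correlation per resample, Fisher-Z
average, and read significance from whether the percentile 95% interval
excludes zero. Permutation tests shuffle one variable and use the add-one
two-sided estimate `p = (1 + #{|rho*| ≥ |rho|}) / (B + 1)`, which is never
zero; an exact enumeration mode (n ≤ 8) exists as an oracle for the sampled
version. Descriptive statistics follow the common software conventions:
sample SD (n−1), adjusted Fisher-Pearson skewness, bias-corrected excess
kurtosis (kurtosis needs n ≥ 4 and is `NA` below that).

## Video-subset (item) analysis

`subset_effect_curve()` asks how many videos are needed to see the trait
effect: for each subset size k it repeatedly (5000 iterations by default)
draws k videos without replacement, pools each participant's accuracy over
them, correlates with the trait, and Fisher-Z averages across iterations. At
k = V no sampling is done, so the curve's endpoint equals the full-sample
rho exactly. `min_videos_for_threshold()` compares the curve's magnitude
against `fraction x |full rho|` (75% by default); magnitudes are compared
because the hypothesised effect is negative while thresholds are
conventionally quoted positive. `best_videos()` ranks videos by the
most-negative per-video trait correlation (the hypothesised direction), with
ties broken by video id. `crossval_correlation()` repeats a 5-chunk
split-recompute-average cycle as a stability check, and
`group_split_comparison()` contrasts accuracy between median-split or
rank-quartile trait groups with a two-sided bootstrap sign test on the
resampled group difference, `p = 2 min(P(diff* ≤ 0), P(diff* ≥ 0))`.

Median splits order by trait then participant id and halve the cohort, so
ties at the median are allocated by rank and groups stay equal. Quartile
sizes are `floor(n/4)` per group with the remainder pushed to the top group
(one unit to the third group when the remainder is 3), keeping sizes within
2 of each other — at n = 102 this yields 25/25/25/27.

## The synthetic cohort generator

The generator is the package's test bed and defines the conditions every
stochastic check runs under. Defaults emulate a 102-participant,
35-video study with 1-3 minute clips sampled at 10 Hz (the rating rate of
web-based continuous report is not standardised; 10 Hz is typical of
cursor-tracking implementations and is configurable).

* **Latent affect course.** Each clip's true valence and arousal follow
  independent stationary Ornstein-Uhlenbeck-style AR(1) processes with unit
  stationary variance and a 3 s correlation length, squashed into the grid
  by `tanh`. Smooth, bounded, one smoothness knob; and the correlation
  length is deliberately far below the permutation null's 10 s minimum
  shift (see above).
* **Observation model.** A rater's series is
  `gain (c · latent + (1 − c) · distractor) + bias + noise`, clipped to the
  grid, with lapse-and-hold events (probability 0.01 per sample). The
  distractor is an independent draw of the same latent process per
  participant-video, so low-competency raters are internally consistent but
  *wrong* — a stricter test for the difficulty diagnostics than white noise
  would be.
* **Video difficulty.** Each video's noise level is the baseline
  (`noise_sd = 0.25` grid units) times a uniform multiplier in 0.1-4. This
  common difficulty gradient is what makes every rater find the same clips
  hard; without it the leave-one-out difficulty correlation has nothing to
  detect. With these defaults the synthetic cohort lands in the regime such
  studies report: mean pooled valence accuracy near 0.63, a wide spread of
  per-video accuracies, and only ~1-2% of participants flagged.
* **Competency and traits.** Competency is uniform on 0.3-0.95 via a
  Gaussian copula whose correlation with the AQ-driving factor is
  `trait_loading` (default −0.4: higher autism-trait scores, lower tracking
  fidelity). AQ totals are discretised to the observed span 9-33 of a
  non-clinical cohort (the instrument spans 0-50), so median-split and
  quartile analyses behave realistically. Other questionnaire totals are
  drawn around published non-clinical means/SDs with modest loadings on the
  trait factor and on competency (fluid/crystallised intelligence load on
  competency, which is why intelligence correlates with tracking accuracy
  in generated cohorts), clipped to their instrument maxima.

What the generator does *not* emulate: real consensus trajectories are
driven by shared stimulus events, not stationary processes; rater errors in
humans are autocorrelated with attention and fatigue rather than white;
questionnaire totals are sums of discrete items with their own structure.
Passing tests therefore demonstrate that the *pipeline* is correct and
well-calibrated under a plausible data-generating process — they do not
certify any empirical claim about human raters.

## Problem sizes and numerical choices

The test suite runs its full-scale checks at the study's own shape
(102 x 35) with clip lengths drawn from the short end of the 1-3 minute
range where only the cohort shape matters, and at reduced sizes (tens of
participants, 4-10 videos, 25-90 s clips) for per-operation checks;
Monte-Carlo counts of 1000-2000 are used where the default would be 5000,
with B always at or above the 1000 floor the resampling functions enforce.
Calibration checks use 200 null replicates (type-I) and 100 replicates
(coverage). Degenerate inputs are handled by contract: constant rater
columns are dropped with a warning (all-constant is an error), constant
variables make correlations an error rather than a silent `NA`, bootstrap
resamples that collapse a variable are redrawn a bounded number of times,
and every stochastic function takes an explicit integer seed and is
bit-reproducible under it.

## Known limitations

* The consensus model assumes one shared answer structure per video; it
  cannot represent legitimately bimodal interpretations (two audiences
  reading a scene differently) — the first component simply averages them.
* The circular-shift null's small negative bias (discussed above) is
  structural; for very short clips (< ~40 s at the default smoothness) the
  bias grows and the null should be interpreted with care. The reader
  rejects clips shorter than twice the minimum shift outright.
* The per-participant difficulty null permutes that participant's own video
  labels; with few videos (< ~10) the null is coarse and flagging is
  conservative.
* Partial Spearman by rank residualisation is one of several published
  definitions of a "partial rank correlation"; with no covariates it is
  exact, and with covariates it matches the recursive formula, but other
  software may implement slightly different variants.
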