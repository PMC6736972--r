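---
title: "Multilevel mediation of social and conditioned cue effects on pain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel mediation of social and conditioned cue effects on pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painmediate)
```

## The scientific problem

Expectations about pain can come from at least two different sources:
symbolic *social information* (what other people report) and *associative
learning* (conditioned cues that have been paired with higher or lower
stimulation). `painmediate` implements the full analysis chain used to
dissociate these two routes: which brain systems *mediate* the effect of
each cue type on reported pain, and are those systems the same or
different?

The experimental design it targets is a pain-learning task: on each of 96
trials (6 runs of 16), a participant sees (1) a social cue — ten other
participants' pain ratings drawn on the rating scale, sampled from
N(0.3, 0.15) or N(0.7, 0.15) truncated to [0, 1] — and (2) a conditioned
stimulus (CS). The CS is partially reinforced: the low CS is followed by
48 or 49 degrees C (50/50), the high CS by 49 or 50 degrees C. The social
cue is statistically independent of temperature. Per subject, exactly 24
trials are at 48 C, 48 at 49 C and 24 at 50 C; cue effects on pain are
analyzed only in the 49 C trials, where stimulus intensity is matched
across cue conditions. Cues are coded -1/+1 and temperature -1/0/+1.

## The mediation model

For a treatment $X$ (one cue contrast), mediator $M$ (expectation rating,
or one voxel's single-trial betas) and outcome $Y$ (pain rating), three
OLS regressions are fit *per subject*, each including the other cue as a
covariate:

$$M = a X + Z\gamma_1 + e_1, \qquad
  Y = b M + c' X + Z\gamma_2 + e_2, \qquad
  Y = c X + Z\gamma_3 + e_3.$$

Path $a$ is the cue effect on the mediator, $b$ the mediator-outcome
relationship controlling for the cues, $c$ the total effect, $c'$ the
direct effect, and $ab$ the mediated effect. With the same covariates in
all three regressions the identity $c = c' + ab$ holds per subject to
machine precision (it is tested at 1e-10 relative error on random data).

Group inference is two-level summary statistics: subject-level estimates
are carried to a second level and tested across subjects. The mediated
effect is tested as the *mean of subject-level products* $a_i b_i$, which
decomposes as

$$\overline{ab} = \bar a\,\bar b + \tfrac{n-1}{n}\,\mathrm{cov}(a, b),$$

so a population can mediate through consistent mean paths, through
correlated individual differences, or both. The decomposition is reported
with every result.

### Why a studentized bootstrap

The default group test resamples subjects with replacement and uses the
studentized pivot $T^* = (\bar x^* - \bar x)/\widehat{se}^*$, with the
two-sided p-value the fraction of $|T^*|$ at or beyond the observed
$|t|$. We also implemented the bias-corrected percentile variant
(`method = "bc"`) and measured both under the complete null at the
design's cohort size ($n = 36$): the BC percentile test had type-I error
0.084 at $\alpha = .05$ and was several-fold liberal in the far tail,
while the studentized test was calibrated (0.035-0.051) all the way into
the $p \approx 0.002$ region that matters under voxelwise FDR correction
— the studentized pivot is second-order accurate, which is exactly the
regime BH thresholding probes. The studentized test is therefore the
default; `"bc"`, a one-sample `"ttest"`, and a delta-method `"sobel"`
fallback (fast, conservative under the complete null) remain available.
Voxelwise, one common subject-resampling plan (a single bootstrap index
matrix per map) is shared across all voxels and paths, for speed and
cross-voxel coherence of the resampling noise.

## Voxelwise maps, FDR and display pruning

`voxelwise_mediation()` applies the same subject-level model at every
voxel via Frisch-Waugh-Lovell residualization (a handful of matrix
products per subject rather than three `lm()` calls per voxel; equality
with the per-voxel estimator is tested to 1e-10). Significance maps are
thresholded by Benjamini-Hochberg step-up FDR at $q < 0.05$, by default
*pooling the p-values of paths a, b and ab of one model into a single
family* — correcting "across the whole brain and mediation paths" — and
the attained voxel-level p cutoff is reported. Around the FDR core, two
lenient display tiers ($p < .01$, $p < .05$ uncorrected) are retained
only for connected components that contain at least one FDR-significant
voxel (`prune_display()`; 26-neighborhood by default, configurable,
tie-free). Conjunctions use the conjunction null — a voxel counts only if
individually significant in both maps — and overlap is quantified by the
Dice coefficient at $p < .05$ uncorrected.

## Network-level decoding

Four complementary summaries localize effects relative to a network
partition (any integer label atlas; `synthetic_partition()` builds
blocky Voronoi partitions for testing):

* **Wedge similarity** — Pearson r between a (thresholded, signed,
  zeroed-outside-tier) map and each network's binary indicator; the wedge
  display convention is radius proportional to r, area to r squared, with
  negative r drawn at zero radius and the sign kept in the table.
* **Subnetwork contrasts** — each subject's *unthresholded* path-a map is
  z-scored across in-mask voxels, averaged within each label, and the two
  cue models are compared by paired t tests; z-scoring makes the contrast
  invariant to per-subject affine scale differences.
* **Octant/SSD covariation** — every voxel is a point in the
  (Social ab, CS ab) plane, classified into eight 45-degree sectors
  numbered clockwise from the +y (CS) axis: octant 1 uniquely
  CS-positive, 2 shared positive, 3 uniquely Social-positive, 5/6/7 the
  negative mirrors, 4 and 8 opposite-signed ("suppressor") combinations.
  Sectors are half-open (lower-angle boundary included) so classification
  is total and deterministic; the classifier is property-tested against
  an independent atan2-interval oracle on 1e5 points including exact
  boundaries. Each octant is summarized by its voxel count and the sum of
  squared distances from the origin (SSD), which weights voxels by effect
  magnitude.
* **Term decoding** — Pearson r of a map against a stack of named term
  maps, returning the top k (default 10) unique terms; uniqueness is by
  lowercased string, with no stemming or stoplist.

## Classification

`loso_forced_choice()` trains a linear SVM (margin cost 1 by default,
features standardized with training-fold statistics only) to separate
Social from CS path-a images under leave-one-subject-out cross-validation.
The held-out subject is scored by the forced-choice rule — correct iff its
Social image gets the higher Social-side decision value than its CS image
— which makes accuracy invariant to monotone transforms of the decision
values. Accuracy is reported with its binomial SE and a two-sided exact
binomial test against 0.5.

## Single-trial estimation rules

* **Spike detection** (`detect_spikes()`): a time point is an outlier if
  its global signal deviates from the run median by more than 10 m.a.d.,
  or if its Mahalanobis distance across channel summaries (slice means
  and spatial SDs) exceeds the same robust threshold. Detection is
  recursive ("step-down", up to 3 iterations): flagged points are
  excluded and the statistics recomputed, so a cluster of extreme points
  can no longer mask a moderate spike. The m.a.d. is scaled by 1.4826
  (consistent with the SD under normality) by default; the raw-m.a.d.
  convention is available via `mad_constant = 1`, since field usage of
  the 10-m.a.d. rule is ambiguous about the scaling. The
  Mahalanobis covariance is estimated from unflagged points and shrunk
  toward its diagonal when ill-conditioned; with fewer samples than
  channels the global criterion is used with a warning.
* **Single-trial GLM** (`single_trial_design()`, `fit_single_trial_glm()`):
  one stick regressor per pain event plus nuisance columns (e.g., 24
  motion-derived regressors) and unit spike indicators. Per-trial
  variance inflation factors are computed against all other columns, and
  trials with VIF strictly greater than 2.5 are excluded from all
  downstream analyses (`apply_vif_filter()`, with a subject/trial/VIF
  exclusion log).
* **SCR deconvolution** (`fit_scr_glm()`): single-trial skin-conductance
  amplitudes by OLS on stick regressors convolved with a canonical
  response kernel. The kernel is a two-parameter gamma family (shape 3,
  scale 1.2 s, unit peak) — the contract is "known kernel in, amplitudes
  out", and any same-rate kernel can be substituted. Preprocessing uses a
  zero-phase order-4 Butterworth low-pass at 1 Hz. The SCR and fMRI
  estimators share one GLM core and are tested against a common oracle.

## The synthetic-data generator

Because the raw study data are not openly downloadable, every stage is
exercised on synthetic experiments with known ground truth. The generator
is first-class, tested code, and its defaults define the simulated study
conditions; they are not tuned per analysis.

* **Design**: exact counterbalancing — the CS-by-temperature contingency
  is realized in exact counts, and the social cue is balanced within
  every CS-by-temperature cell, making independence structural rather
  than asymptotic. One master seed spawns per-subject child seeds from a
  prefix-stable stream, so growing the cohort never reshuffles earlier
  subjects.
* **Behavior**: expectation = intercept + betaS g(t) S + betaC h(t) C +
  noise; pain = intercept + betaT T + gammaE E + direct effects + noise;
  both clipped to [0, 100] with the clip rate logged (under defaults it
  is ~0.1 percent; heavy clipping would bias mediation recovery, which is
  why it is surfaced). The social modulation g(t) declines linearly to
  60 percent of its initial weight over the 48 within-condition trials;
  the CS learning curve h(t) = 1 - exp(-(t-1)/12) starts at exactly zero
  (no learning before the first reinforcement) and saturates with a
  12-trial constant. Defaults put the social effect on expectations
  (~10 rating points per cue unit) well above the CS effect (~3), with
  within-subject residual SDs of 8-9 points — large, durable social
  effects and smaller, emerging CS effects. SCR amplitudes carry a weak
  positive social effect (0.05 a.u. per cue unit against a 0.3 a.u.
  residual), sized so it is detectable but marginal at n = 36.
* **Brain**: a 20x20x20 grid with three disjoint 200-voxel rectangular
  populations — social mediators, CS mediators (per-subject latent
  L = a_i X + eta feeding both the voxel signal and, via b_i L, the pain
  rating; (a_i, b_i) drawn bivariate-normal with correlation 0.3 so the
  group ab has both mean and covariance components), and pain-only
  voxels tracking the cue-independent pain residual (path b without
  path a) — plus thousands of pure-noise null voxels for FDR
  calibration. Mediator contributions are added to the pain column
  before re-clipping, so the planted voxels genuinely mediate the final
  outcome. Betas are generated directly (no hemodynamic convolution) and
  noise is spatially independent; spatial structure enters only through
  the blocky population layout. Generative truth (per-subject paths,
  population labels) is returned for recovery scoring.

What passing tests on these data do and do not show: they demonstrate
that the estimators are algebraically correct, calibrated under the
generator's Gaussian, spatially independent noise, and able to recover
planted effects at the design's sample sizes. They do not demonstrate
robustness to spatially autocorrelated noise, hemodynamic model
mismatch, rating-scale floor/ceiling pileups, or non-Gaussian
physiological artifacts, which real data contain.

## Numerical and design choices

* Stimulus positions are kept in [0, 1] by rejection resampling, so the
  realized distribution is the truncated normal (the analytic truncated
  mean is the test oracle).
* "Time" in cue-by-time interactions is the within-condition trial
  counter (matching per-condition time-course axes); the absolute trial
  index is available by option. Time is centered within subject.
* Behavioral mediation uses 49 C trials with the other cue as covariate,
  mirroring the voxelwise models.
* Display-tier pruning defaults to 26-connectivity; 6 and 18 are
  available. Half-open octant boundaries; BH cutoff reported as the
  largest rejected p (0 when none).
* Group CIs are t-based at the second level for plain group effects and
  bootstrap-t for mediation paths; with zero between-subject variance
  the result is reported with a warning rather than dividing by zero.
* Degenerate inputs are errors or logged exclusions, never silent:
  single-subject group fits, constant moderators, rank-deficient designs
  (the offending columns are named), constant classifier images,
  zero-variance voxels (p = 1, flagged), empty masks, and empty Dice
  (defined as 0 with a message).
* The mediator must carry variance beyond the treatment for path b to be
  identified; fully noise-free chains are validated through path a and
  the generative matched-pair pain contrast instead.
* Pipeline problem sizes: the end-to-end default is 36 subjects, 96
  trials, a 20^3 grid, 10000 bootstrap resamples for behavioral
  mediation and 5000 for maps; the test suite uses reduced cohorts
  (6-16 subjects, 10-12^3 grids) chosen so the whole suite runs in
  about a minute while every claim it checks is still powered.
* `run_config()` round-trips numeric and character fields to JSON; the
  two time-modulation functions are not serialized and are recorded as
  their defaults in sidecars.

## Known limitations

* The summary-statistics two-level model does not weight subjects by
  first-level precision and fits no random-slope likelihood (by design,
  matching the field convention it reimplements).
* Single-mediator models only; no simultaneous multi-mediator search.
* The voxel grid carries no anatomy: no atlas lookup, no real
  resting-state networks, no published signature weights — partitions
  and signatures are supplied by the user or synthesized.
* The LOSO SVM at the synthetic defaults separates the planted patterns
  perfectly (accuracy 1.0); real contrast images are far noisier, so
  absolute accuracies are not comparable to real-data values — only the
  machinery (fold isolation, forced-choice rule, binomial inference) is.
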