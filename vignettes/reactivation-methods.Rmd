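---
title: "Measuring music-evoked memory reactivation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring music-evoked memory reactivation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

When a musical theme that accompanied an earlier movie scene recurs later
in the film, does it reactivate the cortical representation of that earlier
scene — and does stronger reactivation predict whether the scene is
recalled the next day? `reverie` implements a complete analysis pipeline
for this question, built around a two-group design: one group watches the
film with its soundtrack, a control group watches the identical film with
the music removed. Comparing a music-group viewer's brain activity during a
*later* occurrence of a theme against the *no-music* group's activity
during the *earlier* scenes that carried the same theme isolates
reinstatement of non-musical scene content: the no-music group never heard
the theme, so shared musical sound cannot explain the similarity.

## Data model

The pipeline operates on parcellated BOLD-like data: for each participant
and cortical parcel, a voxels-by-TRs matrix. The temporal backbone is a
`scene_table` — ordered, non-overlapping, half-open intervals
`[start_s, end_s)`, each optionally labelled with the song playing. Scene
ids are 1-based and increase with time. A song whose scenes form two or
more maximal runs of consecutive scenes is *repeated*; only repeated-song
scenes enter the analysis.

Scene boundaries themselves come from human raters.
`consensus_boundaries()` pools every rater's timestamps, smooths them with
a Gaussian kernel (default 3 s), locates the local maxima of the pooled
density on a regular grid (default 0.1 s), and keeps the peaks whose
height reaches a percentile of the peak heights (default 90th). The
threshold is taken over peak heights rather than over all grid values:
between boundary clusters the density is essentially zero, so a
grid-value percentile would be dominated by empty stretches and would let
isolated single-rater peaks through, the opposite of a consensus. We pool
boundaries before smoothing; since the density is a sum of Gaussians,
per-rater smoothing followed by summation gives the identical function.
The reconciliation of the single scene-describing rater's boundaries with
the group consensus is genuinely open in the method text; we adopt a snap
rule (`snap_scene_boundaries()`): a first-rater boundary survives when a
consensus boundary falls within `snap_tolerance_s` (default 3 s) of it,
otherwise its two flanking scenes merge. This is one defensible reading;
the tolerance is exposed so users can probe sensitivity.

## The reactivation score

For each cueing *mega-scene* (a maximal run of successive scenes sharing a
song, second or later occurrence of that song) and each *strictly earlier*
same-song scene, three quantities are computed per participant and parcel:

1. **raw score** — the Pearson correlation, across voxels, between the
   music participant's time-averaged mega-scene pattern and the no-music
   group's average pattern for the earlier scene;
2. **baseline** — the same correlation computed entirely within the
   no-music group by a leave-one-out procedure (each held-out no-music
   participant's mega-scene pattern against the remaining participants'
   average earlier-scene pattern, averaged over held-out participants);
   subtracting it removes scene similarity that exists without music;
3. **reactivation score** — the baseline-corrected contrast z-scored
   against a permutation null: earlier-scene identities are shuffled among
   all repeated-music scenes and the contrast recomputed per shuffle
   (default 1000 shuffles; the same shuffle drives the raw and baseline
   terms, so the null of the difference is coherent).

Scenes strictly inside a mega-scene's own run are never used as comparison
targets, because within-run similarity could reflect working memory rather
than retrieval. Two details are unstated in the method text and are
interpretive choices, logged on every pipeline run: the shuffle unit (we
permute earlier-scene identities within participant and parcel, which
preserves the pairing structure and the marginal pattern distribution) and
the aggregation from pair level to scene level when one earlier scene is
cued by several mega-scenes (we average pair-level z scores per earlier
scene and record `n_pairs`). Correlations are not Fisher-transformed; the
z-scoring happens only against the permutation null.

TR membership of a scene uses the TR *onset* inside the half-open,
optionally lag-shifted interval. The default lag is 0 s because the
reference procedure describes no hemodynamic shift; `lag_s` is exposed for
users who want one (e.g. 4.5 s). Mega-scene patterns average member-scene
patterns with equal weight per scene, not per TR of duration.

Randomness is governed by one master seed. Each (participant, parcel) cell
derives a deterministic substream seed (`substream_seed()`), so results are
independent of iteration order and reproducible cell by cell; the
straight-line reference implementation (`reference_reactivation_scores()`)
shares exactly this substream derivation and nothing else with the
optimized engine.

## Subsequent-memory statistics

Per participant, scene-level scores are averaged within subsequently
remembered and subsequently forgotten bins (`bin_scores()`); a scene is
remembered when at least one recall utterance was labelled with it.
Parcels are tested with a one-tailed remembered > forgotten t-test. The
method text states "paired" in three places and "independent" in one; we
default to the paired test — the data are within-participant pairs of bin
means — and expose `test = "independent"` for fidelity experiments.
Participants with an empty bin have no defined paired difference and are
dropped listwise for that parcel (flagged in the output). A parcel whose
differences are constant and non-zero is flagged degenerate rather than
given an infinite t; all-zero differences are the well-defined t = 0.
Multiple comparisons are corrected with Benjamini–Hochberg FDR
(`fdr_adjust()`), restricted to the stated correction set (for the
default-mode hypothesis, the DMN parcels); BH is used as the citable
standard for the reference procedure's AFNI FDR, from which it differs
only in interpolation details. The searchlight significance threshold
defaults to q <= 0.1.

## Controlling for encoding strength

Spatial intersubject correlation (ISC) — the correlation between one
participant's time-averaged scene pattern and the average of the other
N − 1 participants of the same condition — serves as a proxy for initial
encoding strength. We require at least 3 participants per condition so the
N − 1 average is a genuine average. Parcels where binned ISC predicts
recall at an uncorrected p < 0.05 form the region set
(`isc_memory_screen()`); within each participant, the region ISC values
are then regressed out of the reactivation scores in successive
single-predictor OLS steps, each with an intercept, residuals carried
forward (`sequential_residualize()`). The step order is unstated in the
reference procedure; we order regions by parcel id, record the order, and
offer a seeded random order for sensitivity analysis, since sequential OLS
is order-dependent for correlated predictors. Constant predictors are
skipped with a warning. The residuals then rerun the subsequent-memory
machinery (`residual_memory()`), which also emits a pre/post comparison
table.

## Condition contrasts

Three contrasts ask whether the reactivation–recall link requires music:

* **No-music control** (`reactivation_scores(mode = "nomusic_control")`):
  the identical pipeline run entirely within the no-music group; each
  held-out participant takes the subject role, and is excluded both from
  the comparison-group average and from the baseline computation — the
  exclusion is enforced structurally, not by convention.
* **Parcels-as-observations contrast**: per parcel and condition, the
  remembered-versus-forgotten t is converted to a z score by tail-area
  matching (`t_to_z()`, chosen over the crude z = t because per-condition
  dfs can be modest), and the music − no-music differences are tested with
  a one-tailed paired t across parcels (df = parcels − 1). The output
  records the caveat that this treats participants as a fixed effect.
* **Participant-reliability contrast**: per participant, the reliability
  of the remembered-versus-forgotten difference across DMN parcels
  (paired t over parcels, converted to z) is compared between groups with
  a one-tailed two-sample pooled-variance t (df = n1 + n2 − 2), which does
  generalize to new participants.

The network generalization (`network_contrast()`) repeats the parcelwise
contrast within each of 9 networks obtained by collapsing 17-network-style
labels — the trailing A/B/C subnetwork letter is stripped while the
central and peripheral visual networks stay distinct — and corrects the 9
p-values with BH FDR. The label mapping ships as data
(`parcel_metadata()`) and is user-overridable.

## The synthetic-data generator

No public dataset accompanies this design, so `simulate_dataset()`
generates two-group parcellated data with the statistical structure the
analysis assumes. For participant $p$, parcel $k$, and a TR inside scene
$s$:

$$x = e_{p,s}\, g\, u_{k,s} \;+\;
  \mathbb{1}[\text{music},\ s \in \text{later block},\ k \in
  \text{affected}] \cdot \frac{1}{|E_s|}\sum_{s' \in E_s}
  \gamma_{p,s'}\, u_{k,s'} \;+\; \varepsilon$$

with $u_{k,s}$ a fixed unit-norm scene signature shared across
participants and groups (drawn once per dataset, so cross-group pattern
correlation is meaningful), $e_{p,s} \sim \mathrm{lognormal}(0,
\sigma_e)$ the encoding strength, $E_s$ the strictly-earlier same-song
scenes cued during $s$, and $\varepsilon$ i.i.d. Gaussian noise. The
reactivation amplitude is
$\gamma_{p,s'} = \gamma\, e_{p,s'}^{\,\kappa}\, \xi_{p,s'}$ with
$\xi \sim \mathrm{lognormal}(0, \sigma_\gamma)$. The coupling exponent
$\kappa$ (default 1) ties reactivation to encoding strength; this is a
deliberate design choice — when recall is driven by encoding alone, a
coupled reactivation channel is exactly the third-variable confound the
ISC control is meant to remove, so the specificity of that control can be
tested non-trivially. Recall of a cued earlier scene is Bernoulli with
success probability $\mathrm{logistic}(a + b\,e_{p,s'} + c\,
\gamma_{p,s'})$; other repeated-music scenes use the encoding term only.
The no-music group runs through the identical code path with $\gamma$
forced to 0, which makes the two groups exchangeable when no effect is
planted. No hemodynamic convolution is simulated: the pipeline consumes
time-averaged patterns, so a boxcar-at-TR model keeps the generator
analytically tractable for oracle tests. One seed fixes all randomness
bitwise.

What the generator does *not* emulate — autocorrelated physiological
noise, motion, HRF dispersion, spatially correlated signatures between
parcels, semantic similarity structure between scenes — bounds what
passing tests show: they validate the statistical machinery (exactness,
calibration, specificity, power under the assumed generative model), not
robustness to every property of real BOLD data.

## Validation studies and their study sizes

The package ships fixed validation scenarios (`scenario_*()`) and study
runners (`validate_*()`) whose results `scripts/acceptance.R` reports:

* **Oracle equivalence** — a 6-scene, 2-song, 3-per-group noise-free
  instance on which the optimized engine must match the straight-line
  reference to 1e-10. Encoding spread stays positive (`encoding_sd =
  0.4`): with all participants exactly identical the contrast is
  identically zero and the permutation null degenerates, so "noise-free"
  here means no voxel noise, not no individual differences.
* **Null calibration** — 500 parcels, 24 participants per group, no
  planted reactivation, 200 shuffles: the remembered > forgotten
  rejection rate at alpha = 0.05 must sit inside its binomial confidence
  band, and the pooled permutation z scores must be standard-normal to
  within mean ±0.1 and variance [0.9, 1.1].
* **Baseline correction** — with both groups generated identically, the
  grand-mean contrast must be within two (participant-clustered) standard
  errors of zero. Clustering by participant respects the dependence of
  scores sharing a participant.
* **Parameter recovery** — reactivation planted in 5 of 50 parcels with
  the gain calibrated so the raw pair-level correlation uplift is ~0.15
  (`react_gain = 0.9` at 40 voxels per parcel), a reactivation-to-recall
  channel `c = 3`, and the recall intercept set so the cued-scene recall
  rate is near one half in the music group; in at least 80% of 50
  replicates the affected parcels must occupy exactly the top-5 t values,
  while the no-music control run on the same data stays at the nominal
  rejection rate.
* **Encoding-strength control** — 20 parcels, 6 songs with 60 cued scenes
  (many more scenes than selected regions, so 20 sequential regressions
  do not exhaust the residual degrees of freedom; this mirrors the
  reference design's proportions of ~67 scenes to 20 regions). With
  recall driven only by encoding (b = 2, c = 0) and reactivation coupled
  to encoding, the pre-regression effect is strong but the
  post-residualization false-positive rate must return to alpha; adding
  an independent reactivation channel (c = 3), the effect must survive
  residualization with power >= 0.7.

Study sizes (parcel counts, voxel counts, replicate numbers, shuffle
counts) are the packaged defaults of these scenarios; they were chosen
once, by power analysis on the generative model, as the smallest sizes at
which the targeted operating characteristics are measurable with stable
confidence intervals.

## Numerical choices and degenerate inputs

* Correlations are computed by column standardization and cross-products;
  zero-variance patterns are an error naming the offending column rather
  than a silent `NA`.
* A permutation null with zero standard deviation (possible only in
  engineered inputs) is an error, not a z of ±Inf.
* `t_to_z()` works on the log-probability scale, so extreme t values map
  to finite, monotone z.
* Half-open intervals make TR-to-scene assignment tie-free; scenes that
  cover no TRs after lag shifting are an error naming the scene.
* BH q-values inherit `p.adjust()`'s enforced monotonicity; a correction
  set of size one leaves p unchanged.

## Known limitations

The pipeline treats parcels independently (no spatial model), assumes
scene annotations are correct, and inherits the reference design's
fixed-effect caveat for the parcels-as-observations contrast. The ISC
control removes only linearly-ISC-expressible encoding variance: if
reactivation relates nonlinearly to encoding strength, residual
confounding remains — this is a property of the method, reproduced
faithfully, not a defect of the implementation.
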