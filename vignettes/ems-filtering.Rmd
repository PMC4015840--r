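---
title: "Effect-matched spatial filtering: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effect-matched spatial filtering: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsfilter)
```

## The problem and the model

Multi-sensor recordings (EEG, MEG, ECoG) deliver an epoched array
$X \in \mathbb{R}^{m \times n \times p}$ — $m$ channels, $n$ time samples,
$p$ trials — with a condition label $y_k$ per trial. Scientific questions are
usually about the *time course of an experimental effect*, yet the effect is
smeared over many sensors whose relative contribution changes over the epoch.
The classical answer, averaging a fixed region of interest (ROI), assigns
weight $1/n_{roi}$ to member sensors and $0$ elsewhere: a rigid, binary
spatial filter that cannot follow the moving topography and cancels any
effect whose polarity differs across member sensors.

Effect-matched spatial filtering treats the *observed effect topography
itself* as a matched filter. At sample $j$, an objective function $f$ maps
the channel-by-trial slice (plus labels or behavioral covariates) to one
coefficient per channel — for the canonical binary contrast,

$$ d_j \;=\; \langle x_A \rangle_j - \langle x_B \rangle_j, $$

the difference of the class means at each channel. The filter is normalized,
$\hat w_j = d_j / \lVert d_j \rVert$, so that projections preserve
measurement units, and each trial's topography at sample $j$ is reduced to
the scalar $s_{jk} = \hat w_j^\top x_{jk}$. Among all unit vectors, $\hat
w_j$ maximizes the class-separation functional $\sum_k y_k \langle x_k, w
\rangle$ with $y_k = \pm 1/N_{A,B}$, and under i.i.d. Gaussian sensor noise a
matched filter is SNR-optimal. Strung over samples, each trial yields one
*surrogate time course* in the data's units; the trial-by-sample matrix $S$
supports both averaged and single-trial analyses.

Estimating the filter from the same trials that are projected onto it would
be circular, so filters are estimated on held-out-trial complements:
leave-one-out (LOO, the default), leave-one-out-per-condition (LOOPC, for
balanced designs), stratified $k$-fold, or leave-one-subject-out (LOSO) for
group-level use. The no-leakage contract is strict: the filter a trial is
projected onto is bit-for-bit independent of that trial's data, and the test
suite audits this by corrupting held-out trials. Under the null the LOO
construction has zero expected effect, which the suite verifies on 200
replicates of Gaussian data (20 channels x 50 samples x 40 trials); note the
per-replicate distribution is skewed at low channel counts, which is why
within-subject inference on surrogate aggregates should use label-permutation
resampling (`permute_labels()`) rather than t or sign tests.

## Objectives

The objective is pluggable (`ems_objective()`); the package validates only
that it returns one finite coefficient per channel and never sees held-out
trials. Shipped objectives:

* `objective_diff_of_means(pair)` — the canonical per-timepoint contrast.
* `objective_windowed_diff(pair, window)` — a stationary template: the
  windowed class-mean difference yields one filter per fold, applied at every
  sample (`stationary_transform()`). Its course peaks in the defining window
  and deflects again wherever the same topography re-appears.
* `objective_temporal_difference(window_a, window_b)` — amplitude change
  between two disjoint windows (e.g. readiness-potential-style buildup),
  labels not used.
* `objective_temporal_regression(predictor)` — per channel, the OLS slope of
  the flattened trial-by-sample data on a temporal predictor. The regression
  is fit on the flattened matrix (one stationary beta topography), with an
  intercept; `make_rt_predictor()` builds the -1/0/+1 response-locked
  predictor (closed intervals, 200 ms before to 50 ms after each response,
  second-response coding wins on overlap because it is the later event).

Optionally, a coefficient vector can be multiplied by a shrinkage-regularized
inverse noise covariance (`whiten_filter()`), as in Fisher's linear
discriminant. Whitening is off by default: the plain matched filter keeps the
weight vector identical to the forward model (the observed effect
topography), which is what makes it directly interpretable; we re-normalize
after whitening so units are still preserved.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| CV scheme | `cv_scheme()` | `"loo"` | best per-fold estimate; k-fold available when fold-averaged filters are preferred |
| zero-norm tolerance | `ems_transform()` | `1e-12 * max(1, ||slice||)` | scale-aware degeneracy test; exact nulls give flagged zeros, not errors |
| confidence level | `effect_time_course()` | 0.99 | descriptive band on the class difference (Welch t quantile) |
| SNR windows | `estimate_snr()` | user-set | half-open, disjoint; RMS over signal, n-1 SD over baseline, dB scale |
| smoothing | `nested_gnb_decode()` | 50 ms | centered boxcar, edge-truncated |
| GNB variance floor | `nested_gnb_decode()` | `1e-12 * var(data)` | keeps degenerate class variances from producing infinite likelihoods; activations are counted |
| shrinkage | `whiten_filter()` | — (off) | 0 = raw covariance, 1 = isotropic |

Windows everywhere are half-open `[start_s, end_s)` and resolved by direct
comparison against the time vector, so adjacent windows never double-count a
sample; the RT predictor alone uses closed intervals to match its
"from ... to ..." definition. Ties in the GNB posterior go to condition A,
deterministically. Mixed sensor groups recording in different units are
refused by the transforms until `zscore_by_sensor_group()` has been applied;
z-scoring uses the population SD of each group's whole block, making it
idempotent and exactly unit-variance.

## Design decisions that were genuinely open

* **LOOPC pairing.** Folds pair the i-th condition-A trial with the i-th
  condition-B trial in original order — deterministic and seed-free; nothing
  in the method depends on which A is paired with which B.
* **Decoder outer loop.** One outer iteration per balanced trial pair, with
  seeded random pairing; the per-class mean and variance come from an inner
  LOO transform of the training trials, and the held-out pair is projected
  onto the filter from the full training set.
* **Duration metric.** "Duration" of a component is not defined at formula
  level in common usage; we use the time span of the contiguous run,
  containing the peak, where the course stays at or above a configurable
  fraction (default one half) of the peak.
* **LOSO.** Per-subject class means are pre-computed and act as
  pseudo-trials; the fold filter is estimated from the retained subjects'
  means and applied to every trial of the held-out subject.
* **k-fold stratification.** Folds are label-stratified and seeded; the
  round-robin deal keeps class counts per fold within one.

## What the generators emulate — and what they do not

`gen_null_dataset()` draws i.i.d. standard Gaussian data with random
half/half labels. `gen_effect_dataset()` adds planted components: a
per-channel topography, active in a window (boxcar or raised-cosine profile),
optionally condition-specific, with optional truncated-Gaussian onset jitter,
optional multiple sensor groups at different unit scales, and an optional
channel-correlation matrix for the non-i.i.d. regime that motivates
whitening. `gen_rt_dataset()` emulates a dual-task experiment: log-normal
RT1 and RT2 > RT1, an early component whose *duration* tracks RT1, a late
raised-cosine component whose *peak latency* tracks RT1, and response-locked
activity with a lateralized topography of opposite sign around the two
responses (hands); control trials are pure noise with missing (`NaN`)
reaction times. The early/late topographies are drawn orthogonal to the
response pattern and each other so matched projections isolate single
components. All generators are bit-reproducible functions of seed and
scenario and return ground-truth records sufficient to recompute every
oracle.

These are deliberately idealized: no 1/f or oscillatory background spectra,
no biophysical forward model, no artifacts, no autocorrelated noise. Passing
tests therefore demonstrate algorithmic correctness and the method's
comparative behavior in its stated optimality regime, not performance on any
particular real recording.

## Study conditions used by the test suite

Problem sizes were chosen so the whole suite runs comfortably on one CPU
while keeping Monte-Carlo error well below the asserted margins:

* Null unbiasedness: 200 replicates of 20 x 50 x 40, LOO, difference of
  means; grand mean within 3 Monte-Carlo SEs of zero.
* SNR-versus-trial-count comparison: 20 channels, 0.5 s epochs at 100 Hz,
  30 trials per condition; a topography of +1 on channels 1-4 and -1 on
  channels 11-14, amplitude 0.75 at noise SD 1 (single-trial SNR well below
  1 after projection), active in [0.2, 0.3) s. 100 seeded subsamples per
  trial count n = 3..25. The ROI baseline spans all eight responsive
  channels with equal weight, so the opposite-polarity regions cancel — the
  configuration a uniform ROI cannot capture — while the estimated filter
  learns the signs; mean EMS SNR exceeds mean ROI SNR at every n.
* Decoding: 16 x 40 x 24, planted amplitude 0.8 in [0.15, 0.3) s; window
  accuracy is compared against chance using the binomial SE of the pooled
  decision count (decisions are independent across samples here because the
  synthetic noise is temporally white); label-permuted data must stay within
  3 pooled SEs of one half.
* Latency recovery: 40 target trials, amplitude 1, noise SD 0.5. The
  single-trial estimator projects onto the matched topography, smooths with
  a boxcar of roughly the component width (100 ms for the 150 ms
  raised-cosine), half-wave rectifies (the planted deflection is positive
  along the matched direction), and searches the latency range the component
  can occupy; rank correlation with the planted latencies exceeds 0.9. In
  the near-noise-free limit (noise SD 1e-8) every latency is recovered
  within one sample.

## Worked example

```{r example}
pair <- condition_pair(1, 2)
topo <- c(1, 1, 0, 0, -1, -1, 0, 0) / 2
scenario <- effect_scenario(
  n_channels = 8, n_samples = 60, n_trials_per_class = 15,
  components = list(effect_component(topo, c(0.25, 0.40), amplitude = 1.2)),
  seed = 14)
eff <- gen_effect_dataset(scenario)

res <- ems_transform(eff$dataset, objective_diff_of_means(pair))
course <- effect_time_course(res$surrogates, pair)
snr <- estimate_snr(course$difference, course$time,
                    signal_window = c(0.25, 0.40), noise_window = c(0, 0.20))
snr

dec <- nested_gnb_decode(eff$dataset, pair, seed = 2)
round(max(dec$smoothed_accuracy), 3)
```

The SNR report gives the dB ratio of the RMS difference in the planted
window to the baseline SD; the decoder's peak smoothed accuracy sits far
above one half inside the planted window.

## Known limitations

* Optimality is established for the difference-of-means objective; other
  objectives are supported but their statistical properties must be assessed
  per case (the LOO skew can differ by objective).
* Surrogate time courses within one recording are mutually dependent
  (filters share trials); only per-subject condition averages are
  independent units for classical statistics.
* The SNR measure presumes a baseline interval free of the effect; it is the
  caller's responsibility to choose disjoint, meaningful windows.
* Stationary-template courses cannot distinguish a re-appearing topography
  from a different source with a collinear topography.
* The epochs container stores epoched data only; continuous recordings,
  artifact handling and vendor formats are upstream of this package.
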