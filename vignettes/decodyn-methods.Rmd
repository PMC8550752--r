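---
title: "decodyn: models, decoders and statistics for a dynamic neural code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{decodyn: models, decoders and statistics for a dynamic neural code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package is for

`decodyn` implements, as one tested pipeline, the evidence chain for a
*deep, distributed and dynamic* neural code of object category: a recurrent
hub-and-spokes semantic network whose internal representations change
nonlinearly while it settles; a sliding-window temporal-generalization
decoding engine; a synthetic ECoG cohort generator standing in for patient
recordings; and the statistics that establish the four signatures of such a
code — constant decodability, local temporal generalization with
overlapping waves of classifier clusters, a widening generalization window,
and a changing code direction measured by the variability of change (VoC)
of decoder coefficients along the posterior-to-anterior axis.

## The semantic environment

`generate_environment()` builds binary patterns for 90 simulated objects in
3 domains x 3 categories x 10 items. Visual patterns are distorted
prototypes: each domain has an i.i.d. Bernoulli(0.5) prototype, each
category prototype flips domain-prototype bits with probability
`flip_prob_category`, and each item flips category-prototype bits with
probability `flip_prob_item`. A "bit flip" is a deterministic complement of
the sampled positions. Verbal patterns give every item exactly three active
label units: a superordinate (domain) label, a basic-level (category)
label, and a unique subordinate label, so the verbal layer has
3 + 9 + 90 = 102 units.

Two parameters are genuinely open — the visual dimensionality and the flip
rates, which the generative recipe needs but which only qualitative
structure constrains. We default to 48 visual bits with flip probabilities
0.15 (category) and 0.05 (item): large and separated enough that the mean
pairwise similarity ordering *within-category > within-domain >
cross-domain* holds robustly, which is the property the tests check
(`similarity_report()`), rather than any particular similarity value.

## The network and its dynamics

The model (`net_architecture()`, `init_network()`) is a five-layer, fully
recurrent network: visual I/O (48), visual hidden (30), a 25-unit
cross-modal hub, verbal hidden (30), verbal I/O (102), with reciprocal
connections between adjacent layers and an independent weight matrix in
each direction. Only the hub size is fixed by the reference architecture;
the hidden-spoke sizes are configurable defaults.

Units are continuous-time sigmoids with time constant tau = 0.25 updated by
the *time-averaged output* rule `a <- a + tau * (sigmoid(net) - a)`. Each
update sweep visits every unit once in a freshly permuted order, using the
latest values of all other units; a settling interval is `1/tau = 4`
sweeps. I/O units carry a fixed, untrainable bias of -3 (resting activation
about 0.047); "perceiving" an item adds +6 to the net input of its ON input
units for the whole episode, so a clamped unit starts at net +3. The state
at input onset (every unit at `sigmoid(bias)`) is logged as frame 0 and one
frame is logged per sweep: test-mode settling (8 intervals, 32 sweeps)
yields 33 frames.

Training (`train_network()`) is full-batch gradient descent on squared
error between activations and target patterns, with targets applied to
every visual and verbal unit at every logged frame. Each item contributes
one visual-input and one verbal-input trial (180 trials). Settling halts
for a pattern once every I/O unit is within 0.2 of its target; frames past
that point contribute no error. Gradients are propagated through the exact
sequence of permuted asynchronous updates — the backward pass replays the
recorded permutations, so the analytic gradient matches centered finite
differences to better than 1e-4 relative error (tested). Three numerical
choices deserve note:

* **Asynchrony and gradients.** The permutation sequence is drawn from a
  seeded stream and recorded; forward and backward traverse the identical
  sequence. Nothing else would make the gradient exact.
* **Loss convention.** We use the classic half-squared-error convention
  (output-error derivative `a - t`). With the derivative convention that
  doubles this, the effective step at the stated learning rate of 0.002
  overshoots near the loss plateau and the loss oscillates; the half
  convention descends monotonically at the same stated rate.
* **Initial state.** Episode onset is the resting state `sigmoid(bias)`;
  since hidden biases are trainable, the gradient includes the initial
  state path.

Training at the reference hyperparameters (learning rate 0.002, no weight
decay, no momentum) brings the correct-side fraction — the proportion of
visual + verbal target units on the correct side of 0.5 at the end of
settling, `evaluate_outputs()` — above 99%. The loss surface has a long
shallow tail: most of the remaining error lives in the 90 unique
subordinate label units. Scripted runs (tests, `scripts/acceptance.R`) use
a documented reduced epoch count that reaches the plateau; the package
default (`epochs = 30000`) reproduces the full reference schedule.

## Simulated naming and hub decoding

`simulate_naming()` clamps visual input for the 60 items of one domain pair
(repeating over all three pairs), settles 8 intervals, records the 25 hub
units at all 33 frames, and adds i.i.d. uniform noise on [-0.005, +0.005]
as measurement error. `decode_trajectory()` emulates sparse electrode
sampling: 3 of 25 hub units are drawn at random (the sparse subsample of
the reference analysis; the subsample size is configurable), a plain
logistic decoder (`glm`, mean-centered features) is fit per timepoint with
leave-one-out diagonal accuracy, every decoder is tested at every other
timepoint, and the 33 x 33 accuracy matrix is averaged over 10 subsamples.
Off-diagonal testing uses an all-data refit of each timepoint's decoder,
mirroring the ECoG procedure (whether the reference analysis reused LOO
fold models instead is not determinable; the refit is the cleaner analog).

## The synthetic ECoG cohort

`generate_cohort()` emulates the cohort shape of the reference data — 8
subjects, 16-24 ventral-temporal electrodes each, 100 stimuli (50 animate /
50 inanimate) repeated over 4 sessions, voltages at 1000 Hz from -200 to
+1640 ms — and, crucially, a category code that is static posteriorly and
dynamic anteriorly. Each electrode's category loading is

    w_e(t) = A_e * cos(theta_e(t)) * g(t)

where `g(t)` ramps on over 100 ms starting at `onset_ms = 200` and the
phase `theta_e(t)` has three parts, each scaled by the electrode's
anteriority (its MNI y coordinate normalized over the configured range —
the same operationalization used by the gradient statistics):

* a base direction per electrode, bimodal (near 0 or pi, with small
  angular jitter) so every static site carries a usable positive or
  negative loading, as in the lateral/medial fusiform pattern;
* a *decaying rotation* at `2*pi*rotation_rate_hz * anteriority` radians/s
  with time constant `rotation_tau_ms = 500` (plus a small persistent
  residual, `rotation_floor`), which makes early anterior codes rotate and
  then largely stabilize — the source of the widening generalization
  window;
* *piecewise-constant reorientations*: the anterior direction is coherent
  within blocks of `code_block_ms = 120` and jumps by an
  anteriority-scaled random angle (`code_jump_sd = 1.2` rad) at block
  boundaries, shared across stimuli and sessions. Coherence within a
  block lets decoders exploit anterior sites fully inside a 50 ms window,
  while the *meaning* of an anterior deflection changes between windows —
  the operational content of "changing code direction".

Amplitude grows 60% from the posterior to the anterior end
(`amp_gradient`), reflecting the anterior hub carrying the strongest
category signal. A stimulus's voltage is the category-signed loading
scaled by a shared per-item jitter (N(1, 0.3), floored at 0) plus a
per-item, per-electrode component (SD 0.7) that gives every electrode
partially unique category information — decoders then gain from pooling
sites, as on real multichannel recordings. Measurement noise is AR(1)
with per-sample coefficient 0.995 at 1000 Hz: field-potential noise is
dominated by low frequencies, and this temporal coherence (autocorrelation
about 0.78 across the 50 ms window lag) is what keeps decoder coefficients
stable across neighboring windows wherever the underlying code is static.
With fast noise the variability-of-change statistic is floored by
estimation noise at every electrode and no spatial gradient can be
detected, however strong the loading-level gradient. The marginal noise SD
(15 uV against a 6-9.6 uV loading) was chosen once so single-subject
hold-out accuracy is high but below ceiling. Optional artifact injection
(> 500 uV excursions) exercises the rejection path.

What this generator emulates: the spatiotemporal statistics that the
decoding signatures depend on — onset latency, a posterior-to-anterior
dynamics gradient, session repetition, item-level variability, slow
autocorrelated noise. What it does not: real field-potential spectra
(oscillations, band structure), epileptiform artifacts, electrode
covariance structure, reference-electrode effects (the reference analyses
were near-identical with and without referencing), or any genuine semantic
structure beyond a binary category. Passing tests therefore show that the
*pipeline* detects a dynamically reorienting distributed code when present
and reports null results when absent — not that real cortex behaves this
way.

`preprocess_cohort()` applies the standard chain: 2000 Hz traces are
down-sampled by pair-averaging, each trial is baseline-corrected by its
200 ms pre-stimulus mean, trials exceeding +/-500 uV are rejected and
logged (a stimulus losing all repetitions is an error naming it),
surviving repetitions are averaged per stimulus, and the epoch is cropped
to 0-1640 ms.

## The decoding engine

`window_spec()` fixes the sliding-window geometry: 50 ms windows advancing
in 10 ms steps across 1640 ms yield 160 windows (32 fully non-overlapping);
with 20 electrodes at 1000 Hz each window holds 1000 features, concatenated
electrode-major. `fit_l1_decoder_nested()` is the ECoG decoder: L1-logistic
models (glmnet) with outer stratified 10-fold cross-validation for hold-out
accuracy and, inside each outer training set, 9-fold selection of the
penalty from a 50-value log-spaced grid running from the closed-form
all-zero penalty `max|x_j'(y - mean(y))|/n` down to 1e-4 of it. Features
are z-scored with parameters estimated inside each training fold. The
penalty is selected by minimum mean hold-out *binomial deviance*, with
ties breaking toward stronger regularization: hold-out accuracy, the
obvious alternative, plateaus as a function of the penalty, which makes
the selected value jump by orders of magnitude between neighboring
windows and floods the coefficient time-series — and hence the
variability-of-change statistic — with rescaling noise. The final decoder
is refit on all data at the penalty chosen by 10-fold CV on the full
data. Within one subject a single stratified fold partition is shared by
every window (the sliding-window convention), so window-to-window
coefficient changes reflect the data rather than fold resampling.
`temporal_generalization()` assembles the train x test accuracy matrix:
diagonal entries are the cross-validated accuracies, off-diagonal entries
apply each window's final decoder (with its own standardization folded into
raw-space coefficients) to every other window's features.

For large scripted runs the decoder also offers a single-level scheme
(`nested = FALSE`): one stratified 10-fold cross-validation both selects
the penalty and supplies the hold-out accuracies at the selected penalty.
It is cheaper by an order of magnitude and differs from the nested scheme
only by the small optimism of selecting and evaluating on the same folds;
the signature statistics are insensitive to this, and the nested scheme
remains the default and the tested reference.

`cluster_profiles()` groups the matrix rows (accuracy-over-time profiles)
by complete-linkage agglomeration on cosine distance, cut at k = 10 — the
largest k at which, in the reference analyses, every cluster beyond the
first was uniquely best somewhere. `binomial_threshold()` computes exact
Bonferroni-corrected accuracy thresholds with the strict tail convention
`n_tests * P(X > k) < alpha`: this convention — not the inclusive tail —
reproduces the reference thresholds of 44/60 correct at 330 comparisons
(10 clusters x 33 timepoints) and 68/100 at 320 (10 clusters x 32
non-overlapping windows); both tails are returned for audit.

## The four-signature statistics

* **Overlapping waves** (`overlapping_waves_test()`): the group cluster
  assignment is applied to each subject's matrix; at each window the best
  cluster (highest across-subject mean) is compared with every other by
  paired t-tests (df = subjects - 1), Benjamini-Hochberg adjusted jointly
  across all cluster x window comparisons (per-window scope available),
  with tiers at adjusted p < 0.05, 0.01, 0.001. The tier thresholds are a
  display convention; the test is the BH-adjusted comparison set.
  Because the best cluster is a selected maximum, the raw best-vs-rest
  comparisons are anti-conservative when nothing decodes at all; windows
  where even the best cluster fails the corrected binomial reliability
  threshold are therefore masked (tier `NA`), the analog of the reference
  display's blacked-out timepoints. With the mask the table is calibrated:
  at zero effect amplitude no comparisons are flagged (tested over 20
  seeds).
* **Generalization width** (`generalization_width()`): per (train, test)
  window a one-tailed one-sample t-test of subject accuracies against 0.5;
  width = count of test windows at p < 0.01 uncorrected (about 1.6 expected
  false positives across 160 windows). The width-versus-fit-time series,
  restricted to the non-overlapping (independent) windows, is fit by
  `piecewise_fit()`: continuous hinge models, exhaustive breakpoint grid
  search over observed locations, breakpoint count by minimum BIC with
  2 + 2m parameters (slopes/intercept plus estimated locations). With
  zero breakpoints the fit reduces exactly to ordinary least squares.
* **VoC** (`coefficient_voc()`): per electrode, the per-window summed
  signed coefficients (the same summary projected onto cortical surfaces
  in the reference workflow) are differenced at a 5-window lag (50 ms at a
  10 ms step — 155 deltas from 160 windows; the "160 deltas" sometimes
  quoted is not realizable with ordered pairs) and VoC is the sample
  variance of the strictly non-zero deltas, undefined below 2. Constant
  series give no non-zero deltas (missing); a linear ramp gives equal
  deltas (VoC = 0); fluctuating series give large VoC.
* **VoC gradient** (`voc_gradient()`): electrodes pooled across subjects
  are split into deciles by MNI y; decile mean VoC is regressed on decile
  mean y (r-squared, p), and per-subject slopes of VoC on y are tested
  against zero one-tailed with df = subjects - 1.

## Problem sizes used by the scripted runs

The package defaults reproduce the reference problem sizes (160 windows,
nested CV, 30000 training epochs, 10 hub subsamples x 3 domain pairs x 5
network runs). The test suite and the acceptance script run the same code
on documented reduced sizes, the package's standard check profile:
signature runs use 25 ms window steps (64 windows — the full set of 32
fully non-overlapping windows and an exact 50 ms VoC lag are preserved),
the single-level CV scheme and a 10-value penalty grid; training-endpoint
runs use 1500 epochs per run in the suite and 3600 in the acceptance
script (the correct-side fraction sits on a long shallow plateau, creeping
up by fractions of a percent per thousand epochs; a monitored full-length
run continues the same monotone climb through 99% and beyond);
null-calibration runs use compact cohorts (600 ms epochs, 6 electrodes,
40 stimuli, 2 sessions, 20 seeds), since type-I error control does not
depend on problem size. Every such size appears literally in the test or
script that uses it.

## Known limitations

* The synthetic cohort is a statistical stand-in, not a biophysical model;
  see above for what it does and does not emulate.
* The breakpoint count penalty in BIC treats breakpoint locations as free
  parameters; with near-noiseless data BIC can legitimately prefer more
  breakpoints than the generating hinge (the log-SSE term is unbounded
  below), which the tests exercise with on-grid hinges.
* Exact reproduction of the reference patient results requires the
  deposited recordings; the package ships an adapter-shaped container
  (`save_cohort()`/`load_cohort()`) but no data.
* The hub subsample size follows the explicit 3-of-25 procedure of the
  reference analysis; the 15% figure quoted elsewhere in its text (about 4
  units) is close but not identical, and the size is configurable.
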