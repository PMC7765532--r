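---
title: "Methods: simulating and decoding single-trial P300 responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding single-trial P300 responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p300cca)
```

## The problem

In a visual oddball brain-computer interface, symbols on a screen flash one
at a time while the user attends to one of them. The attended (target)
flashes elicit an event-related potential (ERP) with a characteristic
negative deflection around 200-300 ms and a positive P300 peak around
300-400 ms over centro-parietal and parieto-occipital sites; unattended
(non-target) flashes do not, but every flash drives a steady-state visual
response at the flash rate. The decoding task is to classify *single*
1.2-second EEG epochs as target or non-target. `p300cca` implements the full
analysis stack - simulation, preprocessing, CCA spatial filtering,
shrinkage-LDA classification, and evaluation - as a tested, reproducible
pipeline.

## The synthetic session generator

Real sessions of this kind require an EEG laboratory; the generator in
[sim_config()]/[simulate_session()] reproduces the protocol structure with
known ground truth so that every downstream stage can be validated without
recordings.

A session is a sequence of blocks with five phases: fixation (2 s), target
presentation (2 s), preparation (1 s), stimulation (about 30 s), and rest
(5 s). During stimulation the symbols flash under a no-repeat, equiprobable
schedule: each round is a random permutation of all symbols, redrawn when it
would repeat the previous round's last symbol across the boundary, so
per-symbol counts within a block are exactly equal. Flashes repeat every
150 ms (75 ms on + 75 ms off); rounds per block are
`round(30 / (0.150 * n_symbols))` and blocks are appended until at least 280
target flashes exist (the default). With 5 symbols this yields exactly 280
target and 1120 non-target flashes - the count identity
`N_nontarget = N_target * (N_symbols - 1)` holds for every complete session.

Numerical choices worth stating:

* **Sample grid.** At 256 Hz the 150 ms flash period rounds to 38 samples.
  The steady-state sinusoid is generated at the *realized* rate
  `fs / 38 ≈ 6.737 Hz` rather than the nominal `1/0.150 ≈ 6.667 Hz`, so it
  stays phase-locked to the flash onsets it models.
* **ERP morphology.** Each deflection is a Gaussian bump (default: -4 uV at
  250 ms and +8 uV at 350 ms, 45 ms SD) scaled by a per-channel gain that
  peaks at Pz and, for the cartoon-face (CF) condition, multiplied by 1.5 at
  the six posterior channels. The Gaussian shape is a modelling choice;
  published waveforms constrain the latencies and topography but not a
  functional form. Amplitudes sit in the 5-10 uV range typical of P300
  literature.
* **Background noise.** The default is AR(1) noise with coefficient 0.95
  and total SD 9 uV. The autoregressive spectrum is dominated by low
  frequencies, like real EEG, which matters for the artifact-rejection
  band-power criterion: *white* noise has a flat spectrum, and the power
  ratio between 20-40 Hz and 4-40 Hz of a flat spectrum is 20/36 ≈ 0.56 -
  above the 0.5 rejection threshold - so a white-noise default would cause
  every clean epoch to be discarded. White noise remains available through
  `noise_model = "white"` for experiments that want it.
* **Artifacts.** [inject_artifacts()] contaminates flash-aligned windows
  with one of three waveforms, each engineered to trip exactly one rejection
  criterion: a narrow 250 uV transient (peak-to-peak only - a sustained step
  would also raise the epoch SD above 50 uV), a slow ±60 uV alternation (SD
  only), and a 60 uV 30 Hz tone (band ratio only). Because epochs span
  1.2 s but flashes are 150 ms apart, neighbours of a contaminated flash
  overlap the artifact; ground truth lists the directly injected flashes,
  and evaluation treats overlapping neighbours as contaminated too.

What the generator does **not** emulate: volume conduction and realistic
channel covariance, eye-blink and muscle morphology, latency jitter and
habituation of the ERP across trials, or any semantics of the face stimulus.
Passing tests therefore show that the *method stack* behaves correctly on
protocol-faithful signals with known ground truth - not that the pipeline's
absolute accuracies transfer to any particular real recording.

## Preprocessing

Epochs run from -0.2 to 1.0 s around each flash: 51 pre- plus 256
post-stimulus samples at 256 Hz (the half-open `[onset - 51, onset + 256)`
convention; the quoted window in seconds leaves the sample arithmetic open,
and this choice makes the later trim/decimation produce exactly 51 retained
samples).

Rejection precedes filtering and uses three per-channel criteria with strict
inequalities: peak-to-peak > 200 uV, sample SD > 50 uV, and Welch band-power
ratio P[20-40]/P[4-40] > 0.5 (Hann window, segment `min(Ns, 256)`, 50%
overlap, trapezoidal integration over the band; a zero denominator defines
the ratio as 0 so constant epochs are kept). An epoch is discarded when any
channel trips any criterion, and the report records which.

The band-pass is a linear-phase windowed-sinc FIR (Hamming), 4-14 Hz, order
`3.3 * fs / 2 Hz` transition-width rule with 2 Hz transitions (423 taps at
256 Hz), applied by zero-padded convolution with group-delay compensation so
the output is zero-phase. An 8 Hz probe passes within 1% at epoch centre; a
30 Hz probe is attenuated by more than 50 dB. Because the filter is longer
than the epoch, amplitudes within roughly 100 samples of the epoch edges are
attenuated; the classification window (0-0.8 s) sits mostly inside the
well-behaved region, and the same distortion applies identically to every
epoch and channel, which is what matters for classification.

Baseline correction is *not* applied on the classification path (the 4 Hz
high-pass edge removes offsets); [compute_erp()] offers it for ERP display
and statistics.

## CCA spatial filters

Epochs are trimmed to `[0, 0.8)` s - `floor(0.8 * fs)` = 204 samples - and
decimated by 4 by plain subsampling (alias-free because of the prior 14 Hz
low-pass), giving `Nd = 51` samples per channel. The target epochs are
stacked row-wise into `X'` of size `(N_target * Nd) x Ne`, their average is
replicated into an identically shaped matrix, and canonical correlation
analysis between the two learns channel weightings whose projections
maximally correlate single trials with the average target response.

The CCA solver implements the generalized eigenproblem directly: `wp` is an
eigenvector of `Cpp^-1 Cpq Cqq^-1 Cqp`. The replicated-average matrix is
rank-deficient by construction (its rows repeat every `Nd` rows), so a small
ridge `1e-8 * trace/N` is added to each auto-covariance diagonal.
Eigenvector scale and sign are mathematically free; columns are unit-norm
with sign fixed so the filtered target average's largest-magnitude sample is
positive, making refits reproducible. The test suite checks the solver
against two independent oracles (a whiten+SVD formulation and
`stats::cancor`) to 1e-6, and checks invariance of the correlations under
invertible channel mixing.

Each epoch is then projected through the first `Nsf = 3` filters and the
`51 x 3` result concatenated column-major into a 153-dimensional feature
vector. Only the `wp` (single-trial) side of the CCA is used downstream;
concatenation order is irrelevant to the classifier as long as it is
consistent.

## Shrinkage LDA and stepwise selection

The classifier is LDA with the pooled within-class covariance shrunk toward
a scaled identity `nu*I`, `nu = trace(S)/d`, with the analytic Ledoit-Wolf
style intensity computed from the data - no tuning parameter. The decision
threshold sits at the midpoint of the projected class means (equal effective
priors): the evaluation metric is balanced accuracy, and empirical priors
(1 : N_symbols-1) would bias predictions toward the non-target class.

Feature selection is a forward-backward stepwise wrapper scored by 5-fold
cross-validated balanced accuracy *within the training data*. The tolerance
for "improves" / "does not significantly reduce" is 0.01 - one balanced-
accuracy point - which keeps chance-level features out of the model; ties
break toward the lowest feature index, and the procedure is deterministic
given the data and fold seed. `crossval()` caps the selection at 15 features
by default, a compute budget that in practice is never reached on simulated
sessions before the tolerance stops the search.

## Evaluation

`crossval()` allocates epochs to five stratified folds (stratification
guarantees both classes in every fold; plain random allocation is
asymptotically equivalent) and refits the *entire* chain - spatial filter,
selection, classifier - on the training folds only. Reported accuracies are
fold means of the target rate, non-target rate, and their balanced mean
`CAtotal = 0.5 (CAtarget + CAnontarget)`. Note that with 150 ms flash
spacing and 1.2 s epochs, adjacent epochs share samples; cross-validation
folds therefore overlap in signal content. This mirrors the standard design
for these experiments and is documented rather than "fixed" by blocking,
since the single-trial labels remain independent of the shared background.

`permutation_test()` re-runs the identical cross-validation (including
selection) on label permutations - the full chain, so the null remains
exchangeable - and uses the add-one p-value `(1 + #{null >= obs}) / (m + 1)`
with a default of `m = 200` permutations.

`transfer_eval()` fits the chain on one full dataset and evaluates once on
another (condition transfer or symbol-count transfer). When a model trained
on high-gain (CF-like) sessions is tested on low-gain (SF-like) sessions,
the learned threshold sits between strong target responses and non-targets,
so weak targets fall below it: the target rate drops far more than the
non-target rate. The pipeline reproduces this asymmetry on simulations.

The KDE ERP test fits a Gaussian-kernel density (Silverman bandwidth) to
each channel's *pre-stimulus* samples of the averaged ERP and flags
post-stimulus samples whose KDE-CDF falls outside `[alpha/2, 1 - alpha/2]`.
The CDF is evaluated as the exact Gaussian-mixture CDF
`mean(pnorm((x - x_i)/bw))` - the quantity a grid integration of the
density approximates, without the quadrature error. Using the averaged
ERP's own baseline (rather than single-epoch baselines) matches the
single-trace shading such tests produce in practice. The smoothing of the
51-sample baseline makes the test mildly conservative-to-liberal depending
on bandwidth; calibration tests require the null flagged fraction to stay
within `[alpha/2, 2*alpha]`. No multiple-comparison correction is applied
across samples or channels, by design.

`aggregate_table()` reproduces the arithmetic used to summarise
per-participant accuracy tables (per-participant means across sessions,
column means/SDs/medians, pairwise "column A beats column B" counts and
percentages, and column-mean extremes). The package bundles published
reference tables from a 19-participant, 3-session oddball study as plain
TSV ([reference_tables()]); the test suite verifies the aggregation against
the summary statistics printed alongside those tables.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` validate the stack at sizes chosen
to exercise each property with comfortable statistical margins: full
280-target sessions for the headline accuracy band; 120-target sessions for
the ten CF-vs-SF replicate pairs and the gain ladder; 140-target sessions
for the transfer asymmetry; 40-target sessions, 3 per symbol count and 10
replicate batches, for the Kruskal-Wallis insensitivity check; 1000 epochs
at 10% contamination for rejection fidelity; 500 null ERPs for the KDE
level; and 200 replicates of a reduced (feature-matrix, 300-epoch) pipeline
with `m = 199` permutations for permutation calibration — sizes at which the
discrete permutation p-value grid is fine enough for the nominal level to
be attainable.

## Known limitations

* The simulator's per-channel independent noise understates real spatial
  correlation; CCA filters therefore have an easier denoising task than on
  real EEG.
* Epoch-edge attenuation from the long FIR filter slightly shrinks ERP
  amplitudes near the window boundaries; amplitude read-outs via
  [peak_amplitude()] are accurate in the 0.2-0.6 s analysis window.
* The stepwise scorer is one defensible choice among several (information
  criteria or Wilks' lambda are common alternatives); results are not
  sensitive to it on simulated data, but selections on real data may be.
* The BIDS reader targets the layout this package writes; it is not a
  general-purpose BIDS EEG reader.
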