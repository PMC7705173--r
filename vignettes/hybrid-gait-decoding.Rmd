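---
title: "Hybrid EEG-EMG gait decoding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid EEG-EMG gait decoding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Surface EMG decodes walking phases accurately while the muscles work
normally, but its usefulness collapses with fatigue or paresis. EEG
carries gait-locked cortical activity that survives muscular impairment,
but decodes walking far less accurately. `gaitfuse` implements a hybrid
interface that runs one decoder per modality and merges their decisions
by Bayesian belief weighting, so that whichever signal is currently
reliable dominates the decision.

The decoding problem is phrased per decision window over three fused
classes: `RIGHT` (right foot in swing), `LEFT` (left foot in swing) and
`STANCE` (double support). The EEG decoder only answers the coarser
question — swing of either leg versus double support — because
low-frequency scalp correlates of stepping lateralize poorly; the EMG
decoder resolves the side.

# The decision pipeline

## Windowing and features

Both signals are cut into 50 ms rectangular windows with 80% overlap,
one decision per 10 ms (a 100 Hz decision rate). Each window is
summarized by one scalar per channel, always computed from the trailing
20% of the window — the samples that are new relative to the previous
window — so consecutive decisions summarize disjoint signal. Window
labels use the same trailing block (majority vote; exact ties resolve
to `STANCE`, so ambiguity never commands a step).

The EEG path re-references each window to the common average, band-
passes to 1-8 Hz (zero-phase Butterworth, design order 4), z-scores
each channel within the window, and block-averages. The EMG path
band-passes to 10-250 Hz (design order 8), rectifies, smooths with a
6 Hz low-pass (design order 4), and block-averages. The EMG pipeline is
positively homogeneous — scaling the signal by `a > 0` scales every
feature by exactly `a` — which is precisely the mechanism by which
amplitude attenuation reaches the decoder.

## Numerical realization of the zero-phase filters

Zero-phase filtering is forward-backward application of the stated
design order. Three numerical choices matter on 50-sample windows and
are therefore spelled out:

* **Second-order sections.** The order-8 band-pass becomes an order-16
  polynomial whose direct transfer-function realization loses roughly
  ten significant digits on short windows (feature-level homogeneity
  errors around `1e-6`). All filters are designed analytically in
  zero-pole-gain form (Butterworth prototype poles plus bilinear
  transform) and run as cascaded biquads; homogeneity then holds to
  about `1e-11`.
* **End padding.** Each pass uses reflection padding of length
  `min(3 * (order + 1), w - 1)` with steady-state initial conditions
  scaled to the first padded sample. Band-pass stages use odd-symmetric
  reflection (the standard choice for zero-mean signals). The envelope
  low-pass, however, acts on a rectified — nonnegative — signal whose
  odd reflection `2 x[1] - x[k]` is strongly negative; with a filter
  whose settling time (about 170 samples at 6 Hz) exceeds the window,
  the result is a destructive startup transient (empirically the
  "envelope" then correlates *negatively* with the true envelope and
  75% of its values are negative). The envelope stage therefore uses
  constant padding, the natural assumption for a locally constant
  envelope; its correlation with the known synthetic envelope is then
  about 0.89 and the output is nonnegative.
* **Degenerate windows.** A channel with zero within-window variance
  yields a zero feature, not `NaN`. The variance floor is relative
  (`1e-10` times the raw window magnitude): after common-average
  referencing of identical channels the residue is pure rounding dust,
  and a plain `sd > 0` test would amplify it to unit variance.

## Decoders

Each modality feeds an LSTM sequence classifier (EEG: two layers of 250
and 150 units; EMG: one layer of 150 units) ending in a fully-connected
layer and softmax, one posterior per window. The implementation is the
package's own (batched forward/backward in R on BLAS, Adam, gradient
check in the test suite). Training uses contiguous non-overlapping runs
of 100 windows (1 s), cross-entropy loss, learning rate `2e-3`, batch
16, early stopping on validation loss. Features are standardized per
channel with training-set statistics stored in the decoder, so an
amplitude change in later data shifts the decoder's inputs exactly as
it shifts the features. All stochastic steps derive from one seed;
training is bit-reproducible.

The EEG decoder weights its loss by tempered inverse class frequency
(`(1/freq)^0.5`) by default. Swing occupies about 80% of walking time:
a briefly trained unweighted network settles into the trivial
always-swing solution, while *full* inverse-frequency weighting
overshoots the other way — the decoder over-predicts stance until its
validation precision falls below one half, at which point
`P(STANCE | e_EEG = STANCE) < P(SWING | e_EEG = STANCE)` and a stance
vote carries no evidence under the belief fusion (the fused stream then
degenerates to post-processed EMG, whatever the decoder's accuracy).
The square-root tempering sits between the two failure modes and keeps
the stance conditional informative. The EMG decoder, whose classes
separate easily, keeps weighting off.

Decoding of a validation or test stream is stateful by default (the
recurrent state carries across consecutive windows, emulating online
use); a stateless mode resetting every sequence is provided, and the
two agree on the first window of every sequence.

## Fusion

Each decoder's reliability is summarized by its confusion matrix on the
validation split: `n_ij` counts windows truly in class `i` predicted as
`j`. Column-normalizing gives `P(true = i | predicted = j)`. The fused
belief of class `c` given the two hard predictions is

```
Bel(c) = P_EEG(map(c) | e_EEG) * P_EMG(c | e_EMG) * P(c)
```

where `map` sends both `RIGHT` and `LEFT` to `SWING` — the EEG decoder
contributes the same evidence to either swing side, and only the EMG
decoder discriminates legs. The fused decision maximizes the belief.
Priors are uniform (cadence is unknown to the classifier), under which
the alternative prior weighting that divides by `P(c)^(K-1)` differs
only by a constant; both forms are implemented.

Two further choices the formulas leave open:

* **Smoothing.** A validation split on which a decoder never emits some
  class produces an all-zero column, whose conditional is undefined.
  Additive smoothing with `alpha = 1` (configurable, `alpha = 0`
  reproduces the raw normalization) turns such a column into a uniform
  — uninformative — conditional.
* **Ties.** Exactly equal beliefs (e.g. under an uninformative EMG
  table, where the repeated-SWING mapping forces
  `Bel(RIGHT) = Bel(LEFT)`) resolve by the fixed preference
  `STANCE > RIGHT > LEFT`: ambiguity never commands a step.

Fusion consumes hard per-window decisions, not posteriors;
posterior-weighted fusion is deliberately out of scope.

## Protocol

A session splits 60/15/25 into contiguous, time-ordered train /
validation / test segments; features are extracted per split, so
windows never straddle a boundary, and shuffled splits are deliberately
not offered (overlapping windows would leak gait-cycle context across
splits). Decoders are trained on the training split with validation
early stopping; fusion conditionals are estimated on the validation
split only; the decoders are then retrained on train+validation and
evaluated, together with the fused stream, on the test split only.

Retraining warm-starts from the calibrated network's weights rather
than refitting from scratch. The reason is statistical, not a speed
trick: the conditionals describe *one particular* decoder's error
structure, and an independently refitted network — especially its
extrapolation to attenuated, out-of-distribution inputs — can land in
a different optimum that the calibration no longer describes, at which
point the fusion corrects errors the test-time decoder does not make
and misses the ones it does. Continuing the same fit on the enlarged
data keeps calibration and deployment consistent. A cold refit remains
available (`retrain_on_train_plus_validation(init = NULL)`).

# Impairment regimes

*Temporary* (fatigue-like): the EMG amplitude is multiplied by a
retained fraction (study conditions 1.0, 0.9, 0.5, 0.3, 0.1 — an
"attenuation of 70%" means fraction 0.3) on the validation and test
splits only; decoders are trained on clean signals. Validation and test
fractions are independently configurable to express the robustness
protocol in which calibration and usage attenuation differ by ±10
percentage points.

*Permanent* (paresis-like): only the vastus medialis channel of each
leg survives; the retained channels are attenuated to 30% and Gaussian
noise is added at a target SNR (10, 3, 1.5, 1, 0.5, 0.1 dB), on all
three splits alike, and the decoders are retrained per condition. The
noise sd per channel is `sqrt(P_signal / 10^(SNR/10))` with `P_signal`
the channel's mean squared amplitude over the whole attenuated split —
the whole-signal reading of "signal power", since no procedure for
separating "informative" EMG activity is specified anywhere; noise is
added to the raw signal upstream of all processing.

# The synthetic walking generator

No public recording of synchronized EEG + EMG + foot-switch treadmill
walking is available to this package, so it ships a seeded generator
whose defaults define the study conditions.

**Gait model.** Right-leg heel strikes define cycles (mean 1.1 s,
cycle-to-cycle jitter sd 0.02 s, truncated at ±50%); each foot is in
contact for 60% of its cycle and the left leg lags by half a cycle.
Heel and toe traces cover the leading and trailing 70% of stance
(union = stance). Labels follow the contacts; samples that jitter
leaves with both feet off inherit the previous label (walking, not
running — parameter sets whose nominal swing intervals overlap are
rejected). With zero jitter the construction is exactly periodic, and
closed-form label fractions (40/40/20 at these defaults) are used as
test oracles.

**EMG.** Each muscle is a sum of Gaussian activation bumps on its leg's
cycle phase multiplying a 20-150 Hz band-limited carrier, plus white
baseline noise (burst gain 100 uV, baseline sd 8 uV). Timing follows
textbook activation: tibialis anterior through swing and around heel
strike, vastus medialis in early stance, biceps femoris in late swing.
These defaults put the clean EMG decoder at about 95% test accuracy,
matching what EMG gait classifiers typically reach on healthy walkers.

**EEG.** Channels share a gait-locked low-frequency component with a
channel-specific gain (a spatial bump peaked over the central midline,
peak 18 uV) on top of independent 1/f background noise (sd 4 uV); the
synthetic EEG emulates recordings *after* offline artifact cleaning,
which is why the background is modest and no artifact model is
included. The contrast parameter (default 2) scales three swing-stance
differences: a deterministic evoked-like bump 80 ms after each step
onset (the delay keeps the zero-phase bump inside the swing phase), a
higher carrier amplitude during swing, and a spectral shift of the
carrier inside the gait-locked band (delta-dominant in double support,
theta-dominant in swing). The spectral shift is load-bearing: the
within-window z-score of the EEG feature path makes the features
amplitude-blind, so a generator whose only class cue were band power
would be undecodable by the very pipeline that consumes it — waveform
structure is what survives. At contrast 0 the EEG is label-independent.
These defaults put the EEG decoder at roughly 85-90% swing/stance
accuracy under desk-scale training, a deliberately weaker decoder than
the EMG, as on real data.

**What the generator does not emulate** — and what passing tests
therefore do not show about real recordings: ocular/muscular/cable
artifacts and their removal, electrode impedance drift, treadmill-speed
effects beyond cycle duration, inter-subject variability (one seed =
one idealized "subject"), volume conduction structure beyond a shared
source with spatial gains, and any physiologic fatigue dynamics
(median-frequency shifts); the impairment regimes are imposed, not
emergent.

# Problem sizes and defaults of the shipped experiments

The packaged experiment runner and the acceptance script use one
10-minute synthetic session at 1 kHz (36,000 training windows), eight
training epochs for the EEG decoder and six for the faster-converging
EMG decoder plus a two-epoch warm-started retraining, batch 16 — sizes
chosen so a complete
two-regime replication (temporary sweep over five attenuation levels;
permanent sweep over a no-noise baseline plus three SNRs) runs on a
single CPU in well under half an hour while leaving both decoders
clearly above chance. The permanent sweep in the acceptance script uses
SNRs {10, 1, 0.1} dB — the ends and middle of the study's range — to
keep the per-condition retraining affordable; `run_config` accepts the
full six-level list. Longer sessions and more epochs sharpen all
numbers but change no conclusion.

# Known limitations

* The LSTM runs on BLAS-backed R matrix arithmetic; it is exact but not
  fast. Training at paper scale (20-minute sessions, convergence-length
  training) is minutes-long, not seconds-long.
* Fusion conditionals are estimated once per condition; online
  adaptation of the reliability tables mid-stream is out of scope.
* The decoders emit hard labels to the fusion; the softmax posteriors
  are exposed but unused by design.
* Statistical comparisons across subjects (Friedman/Kruskal-Wallis
  style analyses) are not reimplemented; `compare_conditions` exports
  the long-format table such analyses would consume.
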