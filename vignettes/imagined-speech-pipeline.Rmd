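---
title: "An imagined-speech EEG classification pipeline: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An imagined-speech EEG classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imspeech)
```

## The problem

A silent-speech brain-computer interface tries to decode which word a
subject is covertly repeating from scalp EEG alone. The setting emulated
here is a vocabulary of six command words plus a Silence (rest) class,
recorded over five sessions of two parts each, with each part containing
three tests; a test presents two words and Silence in `Nt = 20`
pseudorandom trials of one instance each at a fixed instance time
`Ti = 4` s, at 500 Hz over the 19 scalp channels of the 10-20 montage (the
earlobe references A1/A2 carry no scalp signal and are excluded from
analysis). Two synchronization channels mark the class and onset of every
instance.

Because EEG is nonstationary, the time separation between the recordings
that contribute the training and test samples matters as much as the
decoding method. The package therefore evaluates every classifier under
three *modes*:

* **long-time** — all instances of a word across the whole dataset form one
  class (intraclass time spans weeks);
* **short-time** — all classes are drawn from a single recording part
  (intraclass spans minutes);
* **mixed-time** — every class is drawn from its *own* part, pairwise
  distinct (interclass time is large, intraclass small).

Two-digit class codes make parts explicit: word `w` in part `r` is class
`10*w + r`, so "Left" (word 3) in part 2 is class 32, and Silence (7) in
part 2 is 72.

## The classifier

The core decision rule is a one-vs-one bank of soft-margin linear
support-vector machines: for `n` classes, one machine per unordered pair,
`n(n-1)/2` in total (21 for the seven-class problem). A sample is presented
to every machine and votes are tallied:

1. a unique maximum-vote class wins;
2. if exactly two classes tie for the maximum, the *specialist* machine
   trained on that very pair decides;
3. if three or more classes tie, the sample is assigned to the sentinel
   class *Unknown* (`C0`).

The specialist tie-break makes the rule behave sensibly in the common
two-words-plus-Silence case: if both word-vs-Silence machines are accurate,
a Silence sample is labelled Silence regardless of how the word-vs-word
machine votes. Unknowns are never dropped: they keep their place in the
confusion matrix (an extra column) and in the accuracy denominator, so an
undecidable sample counts as an error.

Binary machines are linear SVMs with cost `C = 1` (the `cost` argument of
every training function), fitted by `e1071::svm` and stored as explicit
weight vectors and biases. No probability calibration or decision-value
fallback is used — votes are hard, which is what makes the tie-break and
Unknown semantics well-defined.

## Evaluation

Accuracy is estimated by Monte-Carlo cross-validation: in each of `Nr`
iterations (default 30) the data are split per class into ~70% training and
30% test samples, a fresh bank is trained, and the test confusion matrix
`Cr` is accumulated. The per-iteration accuracy is `Ar = trace(Cr)/sum(Cr)`
(the sum includes the Unknown column), the final matrix is `C = sum(Cr)`,
and the reported accuracy is the mean `A` of the `Ar` with their population
standard deviation `sigma`. Because the stratified split has a fixed test
size, `A` equals the accuracy computed from the summed matrix `C` exactly;
the test suite asserts this identity.

Two statistical subtleties are worth recording:

* **Chance level with Unknowns.** On label-independent data the expected
  accuracy is not `1/n` but `(1-u)/n`, where `u` is the rate of undecidable
  vote patterns. `u` shrinks with feature dimension (pairwise hyperplanes
  decorrelate, making three-way vote cycles rare): at the pipeline's
  feature length 589 it is a few percent. `simulate_null_features()`
  generates matched null data for this measurement.
* **Standard errors of `A`.** Monte-Carlo iterations resample the same
  instances, so the variance of `A` has a data-sampling floor that does not
  shrink with `Nr`. Where the tests compare `A` to a nominal value they use
  `se^2 = sigma^2/Nr + p(1-p)/N` with `N` the number of distinct instances,
  rather than the anticonservative `sigma/sqrt(Nr)`.

For the mixed-time mode a full average over all injective assignments of
records to classes is impractical (there are `10!/3! = 604800` for seven
classes over ten records; `count_mixed_assignments()` computes the falling
factorial), so `evaluate_mode()` averages over a random sample of
assignments, drawn by `sample_mixed_assignments()`.

## Preprocessing

The chain is fixed: zero-phase low-pass filter, block-average downsampling,
sync-driven segmentation, energy-based artifact rejection — in that order
(filtering after decimation would alias the 50 Hz mains component into the
retained band; a test asserts the orders are not interchangeable).

* **Filter.** Butterworth low-pass at 32 Hz applied forward and backward
  (`signal::filtfilt`), which squares the magnitude response and cancels
  the phase exactly, so instance onsets stay sample-aligned. The prototype
  order is 8: after squaring, the passband stays within 5% of unity up to
  0.8x cutoff while 50 Hz is attenuated by more than 40 dB. A 4th-order
  prototype, often the reflex choice, loses ~15% of amplitude at 25.6 Hz
  once applied bidirectionally, which would distort the upper beta band
  the features retain.
* **Downsampling.** Each block of 5 consecutive samples is replaced by its
  average (500 to 100 Hz); trailing samples that do not fill a block are
  dropped. Block averaging is itself a crude low-pass, but the explicit
  filter before it is what provides the anti-aliasing.
* **Segmentation.** One segment per sync event, cropped or zero-padded *at
  the end* to exactly `Ti * fs` samples (400 at 100 Hz), so all instances
  are commensurate. Events whose onset lies beyond the data end are skipped
  with a warning.
* **Artifact rejection.** A segment's quality measure is its mean squared
  amplitude pooled over channels and samples; segments outside
  `[E/k, E*k]` of the batch mean `E` are rejected, with `k = 3` by default.
  The baseline is the plain mean, computed per record batch. This criterion
  is only class-neutral when class rhythms are a small fraction of total
  power — which holds for real EEG and for the default synthetic
  signatures — and `k` is deliberately a configuration knob, not a tuned
  constant. On clean synthetic data the rejection fraction is well below
  2%.

## Features

Each instance yields one vector of length `Lf = Nch * Nf`:

1. select the 19 scalp channels (A1/A2 refused by default);
2. keep a window of `Ts = 2.5` s starting `Tw = 1` s into the instance —
   `Tw` must cover stimulus playback (`Te <= 0.5` s) plus a short rest, and
   `Ts <= Ti - Tw`;
3. per channel, take the one-sided magnitude FFT (rectangular window; no
   taper) at native resolution `1/Ts = 0.4` Hz;
4. resample to 1 Hz resolution by averaging native bins whose centers fall
   in `[f - 0.5, f + 0.5)` for integer `f` in 0..32 (linear interpolation is
   available as an alternative); this makes the feature length independent
   of sampling rate and window duration;
5. divide the channel's 33 values by their maximum (an all-zero channel
   passes through as zeros), drop DC, keep 1..31 Hz, giving `Nf = 31`;
6. concatenate channel blocks in configuration order, `Lf = 589`.

Max-normalization makes features invariant to overall signal amplitude —
electrode gain and impedance differences cancel — and bounded in `[0, 1]`.
Normalization is per channel, *before* concatenation, because channels
differ in gain; a global maximum would let one high-gain channel suppress
the others. The retained band is 1–31 Hz by default: after the DC value is
excluded, 31 integer frequencies remain below the 32 Hz filter edge. The
band edges are configurable (`freq_lo_hz`/`freq_hi_hz`), including a
1–32 Hz variant, since the value at the cutoff frequency itself is
attenuated but not zero.

## The synthetic generator

No public imagined-speech corpus matches this acquisition design, so the
package ships a generator that emulates its *structure* rather than its
neurophysiology. Each class is a `class_signature`: 1/f^alpha Gaussian
background noise (default `alpha = 1`) plus a few sinusoidal peaks with
random phases per instance and channel. Silence is background-only. The
default word signatures place two disjoint peaks per word and keep peak
power under 10% of background power, so word and Silence instances have
comparable energy, as in real EEG.

Nonstationarity has two knobs:

* `drift_per_record` (per class): peak frequencies shift by this many Hz
  per unit record id, and optionally amplitudes scale via
  `drift_amp_per_record`. This makes the spectral distance between
  same-class instances grow monotonically with record distance.
* `record_drift` (per record): the background exponent of *every* class in
  record `r` is raised by `record_drift * r` — a spectral fingerprint
  shared by all classes of a recording part, emulating session-to-session
  changes in electrode placement and vigilance. This is the mechanism that
  makes mixed-time classification easiest: classes drawn from different
  records differ by their record fingerprints on top of their own
  signatures, while in short-time mode the shared fingerprint cancels.

Schedules are independent uniform permutations of the word set per trial
(any block of `Nc` consecutive instances contains each class exactly once),
back-to-back at `Ti` spacing; the generator warns when a test would exceed
a configurable duration cap, since over-long tests fatigue subjects. Sync
encoding is lossless: one row carries the class code as a level during the
instance, the other a 50 ms unit pulse at onset; `decode_sync_events()`
inverts it. All randomness is seeded, and a dataset-level master seed
derives per-record seeds so any record can be regenerated in isolation.

What the generator does *not* emulate: dipole/forward-model scalp
topographies (all channels receive the same class signal with independent
phases), eye-blink or muscle artifact morphology (only energy-scaled
artifacts via `inject_artifact()`), inter-trial rest gaps (instances are
back-to-back at `Ti` spacing), and any genuine linguistic structure.
Passing tests on this data therefore demonstrate that the pipeline's
mechanics are correct and that its qualitative behaviour under
nonstationarity matches expectation — not that the method achieves any
particular accuracy on real imagined-speech EEG.

## Experiment sizes used by the test suite

The test suite runs the generator at reduced but structurally faithful
sizes: full 500 Hz sampling and 4 s instances throughout; the
dataset-design checks use the complete 5x2x3 design with 20 trials; the
nonstationarity (mode-ordering) experiment uses two words plus Silence
with single peaks at 10 and 12 Hz, amplitude 1, noise RMS 3.5, class
frequency drift 0.3 Hz/record and record tilt 0.12/record over 10 records
of 10 trials; the peak-separation recovery experiment uses separations of
8, 2, 0.5 and 0 Hz at noise RMS 2.5 with 20 trials. Chance-level runs use
40 instances per class of 589-dimensional uniform null features and 30
Monte-Carlo iterations. These sizes were chosen as the smallest at which
the respective effects are comfortably resolved.

## Known limitations

* Energy-based rejection with a mean baseline is not robust to many
  simultaneous artifacts or to strongly class-dependent energy; a robust
  (median) baseline would change the documented semantics, so it was not
  substituted.
* The specialist tie-break requires the bank to contain the machine of the
  tied pair; this is guaranteed by construction but means partial banks are
  unsupported.
* Mixed-time averages depend on the sampled assignments; two runs agree
  only under a common seed.
* The linear kernel and `C = 1` follow the reference design; no kernel or
  regularization search is implemented, deliberately.
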