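---
title: "Detecting agonal breathing in bedroom audio: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting agonal breathing in bedroom audio: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Agonal breathing — the irregular, gasping respirations produced by a
brainstem reflex under severe hypoxia — is an audible biomarker of
cardiac arrest, present in roughly half of out-of-hospital arrests and
typically occurring at 3–6 gasps per minute. Because two thirds of these
arrests happen in private residences, often unwitnessed and frequently
in the bedroom, a passive acoustic monitor running on a smart speaker or
phone could summon help for victims who would otherwise have no chance
of survival.

`agonalert` implements such a monitor as a streaming pipeline:

1. **audio**: normalize to $[-1, 1]$, resample to 16 kHz, cut into
   2.5 s segments;
2. **features**: short-time Fourier transform, 64-band log-mel
   spectrogram, PCA projection to a 256-dimensional embedding;
3. **detector**: RBF-kernel support vector machine
   ($k(x,y) = e^{-\gamma\|x-y\|^2}$, $C = 10$) with Platt-calibrated
   probabilities;
4. **agonal_filter**: a temporal plausibility gate that converts
   per-segment positives into an alarm only when detections recur at the
   physiologic agonal rate (successive breath onsets 10–20 s apart).

Around the pipeline sit a Sign-Data LMS canceller that removes the
device's own known playback before classification, FMCW chirp
synchronization for over-the-air benchmark experiments, and a seeded
synthetic-scene generator that stands in for clinical audio.

## Why the data are synthetic

Real agonal breathing recordings come from 9-1-1 emergency calls, and
realistic negatives from polysomnography studies; neither corpus can be
redistributed. The package therefore ships a generator
(`make_agonal_gasp()`, `make_negative_track()`, `make_interference()`,
`render_scene()`) whose defaults define the study conditions used by
every test and by `scripts/acceptance.R`:

* **Gasps** are broadband noise bursts (band-shaped 200–2500 Hz) under a
  sharp-attack (50 ms), slow-decay (~150 ms time constant, several
  hundred ms support) envelope, mixed with a low-frequency harmonic
  component whose fundamental is drawn from 80–150 Hz. This is an
  engineering surrogate: no published spectral model of agonal breathing
  exists, so the template captures the qualitative description — a
  short, loud, voiced gasp — without claiming physiological validity.
* **Negative tracks** emulate the sleep-audio classes that make this a
  hard discrimination problem: snoring (low-frequency palatal buzz),
  normal breathing (band-limited breath noise at 6–30 cycles/min),
  hypopnea (amplitude-reduced cycles), central apnea (silent gaps of at
  least 10 s with no respiratory effort) and obstructive apnea (gaps
  with weak residual struggle bursts).
* **Interference** surrogates: speech-like (formant-band noise with
  syllabic-rate amplitude modulation), traffic-like (low-pass rumble
  with transients, >80 % of power below 500 Hz), white noise, and a
  narrowband "soundscape" like the river-current tracks people play to
  fall asleep.
* **Scenes** place events on a timeline, scale them by $1/r$ for a
  source at $r$ metres (1, 3 and 6 m are the standard conditions), add
  interference at a stated RMS dBFS and a Gaussian device-noise floor,
  and never clip (the mix is scaled down instead). Ground-truth segment
  labels follow a fixed rule: a segment is positive iff it overlaps at
  least 50 % of some gasp's support. All randomness flows from one
  integer seed through a counter-based split, so a spec renders to a
  bit-identical waveform every time.

What the generator does **not** model: room reverberation (distance is
amplitude-only), device microphone responses, codec artifacts, real
speech or music content, and — most importantly — the true acoustic
variability of agonal breathing. Passing tests therefore demonstrate
that the pipeline's machinery works and behaves as designed, not that
the published clinical accuracy would be reproduced on real 9-1-1
audio.

## Training corpora

`make_training_corpus()` renders balanced positive and negative scenes
(10 s each, four segments). Three choices matter:

* **Gasp placement.** Each positive segment contains one gasp at a
  uniformly random position inside the segment. The flattened log-mel
  embedding is position-sensitive, so a corpus with gasps always at the
  segment start fails on streaming audio where gasps arrive at arbitrary
  phase; randomized placement fixed this.
* **Distance and interference augmentation.** Sources cycle through 1,
  3 and 6 m; every second source carries a household interference track.
  With `augment_distances = TRUE` a source is rendered at all distances
  and the variants share one `source_id`, which is what the grouped
  cross-validation keys on.
* **Cancellation augmentation.** Every third source receives an
  additional variant that has been mixed with self-playback and passed
  through the LMS canceller. Cancellation leaves a characteristic
  misadjustment residue; a detector that has never seen it flags it as
  gasping. Cancellation-processed audio is a recording condition of the
  intended deployment (a speaker that plays soundscapes at night), so it
  belongs in the augmentation set alongside distance and interference.

## Featurization choices

The STFT uses a periodic Hann window, 25 ms frames, 10 ms hop and a
512-point FFT; the filterbank has 64 triangular mel bands between 125
and 7500 Hz, and energies are compressed as $\log(x + 0.01)$. These are
the conventions of widely used audio-event feature extractors, and all
of them are exposed in `mel_params()` rather than hard-coded. Each
2.5 s segment is
peak-normalized before analysis (the range normalization step of the
pipeline), which makes the embedding invariant to recording level and
hence to distance — without it, level dominates the principal components
and held-out sensitivity collapses.

One log-mel matrix per segment is flattened and projected by PCA to 256
dimensions. A per-patch embedding with pooling was the alternative
design; one flattened matrix per segment is the simpler reading of a
single 256-dimensional embedding per segment, and it keeps the temporal
structure of the gasp envelope in the feature vector. PCA is computed exactly via
the smaller Gram matrix ($XX^\top$ when $n < d$), with a deterministic
sign convention, and is **refit on each fold's training split only** —
the embedding basis must never see validation audio. The mel front end
is a fixed, data-independent transform, so log-mel features can safely
be computed once for all segments.

No whitening is applied by default: leaving component scales intact
keeps the RBF $\gamma$ heuristic ($1/(d \cdot \mathrm{Var})$, the
"scale" convention) interpretable.

## The classifier and its approximation

The SVM uses $C = 10$; $\gamma$ defaults to the scale heuristic, a
robust choice when no problem-specific value is known and one that
keeps its meaning as features are rescaled. Probabilities come from
libsvm's built-in
Platt sigmoid (fitted by internal cross-validation). The operating
threshold is chosen on training probabilities by maximizing Youden's
$J$; when the training classes separate completely, every threshold in
the empty score gap ties, and the midpoint of that gap is used — picking
the gap's edge (the smallest positive training probability) transfers
badly to held-out data.

For real-time scoring, `approximate_detector()` replaces the kernel
expansion with $D$ random Fourier features:
$z_i(x) = \sqrt{2/D}\,\cos(\omega_i^\top x + b_i)$ with
$\omega_i \sim N(0, 2\gamma I)$, so that
$z(x)^\top z(y) \to e^{-\gamma\|x-y\|^2}$ at the Monte-Carlo rate
$O(1/\sqrt{D})$. The linear weights are **mapped from the dual
coefficients** ($w = \sum_i \alpha_i z(\mathrm{sv}_i)$, bias $-\rho$)
rather than refit: a refit linear model agrees with the exact decision
boundary only near the data (97 % label agreement at $D = 4096$ on a
blob fixture), while the dual mapping converges to the exact decision
function everywhere (>99 % agreement), because far from the support
vectors the exact machine tends to $-\rho$ and so does the mapped
score.

Grouped 10-fold cross-validation assigns whole *sources* to folds,
stratified by class, so no recording — and no augmented variant of a
recording, since variants share the source id — ever straddles the
train/validation split.

## The agonal-rate filter

Detections become an alarm only when breath events chain at the
physiologic rate. The rules, stated exactly:

* positive segments within 5 s of the previous positive (two adjacent
  2.5 s segments) merge into one breath event, whose onset is the first
  segment's start — one gasp can straddle a segment boundary;
* a new breath event chains to the previous event iff the onset gap lies
  in $[10, 20]$ s (inclusive at both ends; $60/6 = 10$ and $60/3 = 20$);
* a gap outside the window — too fast as well as too slow — restarts the
  chain at the new event;
* when the chain reaches `breaths_required` (2 or 3) an alarm fires and
  the alarming event seeds the next chain.

Seeding the next chain with the alarming event (rather than clearing the
state) preserves the containment property
$\text{alarms}(3) \subseteq \text{alarms}(2) \subseteq \text{positives}$
on every stream, which is the monotone false-positive-reduction
guarantee of the cascade. Onset gaps, not segment indices, carry the
rate semantics, because "3–6 breaths per minute" is an inter-onset
rate.

## Self-interference cancellation

The Sign-Data LMS canceller predicts the echo of the device's own
playback from the last 100 reference samples and subtracts it:
$\hat y_k = w^\top \tilde x_k$, $e_k = d_k - \hat y_k$,
$w \leftarrow w + \mu\, e_k\, \mathrm{sign}(\tilde x_k)$ with
$\mu = 0.05$, zero initial weights, and $\mathrm{sign}(0) = 0$ (so a
zero reference is a strict no-op). The level convention is an
implementation choice: the tap vector is normalized by its running peak
**times the filter length**: one update then changes the predicted
output by at most $\mu|e_k|$ regardless of playback level or tap count.
This matters: with unit-peak normalization alone, $\mu = 0.05$ over 100
taps sits outside the sign-data stability region and the weights diverge
within seconds on realistic scenes. With the bounded-swing convention
the filter reduces a delayed echo by ~25 dB within 2 s, drives a
sub-100-tap echo path below 1 % residual power, and remains bounded over
$10^6$ samples.

The filter models echo-path delays only up to 100 samples (6.25 ms at
16 kHz); longer offsets must be removed beforehand, either from a known
playback offset or by chirp synchronization. Cancellation runs at the
stream rate (16 kHz) before segmentation.

Benchmark cells report *detection accuracy* in the played-clip sense:
the fraction of played gasp clips whose segment is classified positive
(and, for negative-clip cells, the fraction of a played negative stream
classified negative). Whole-stream per-segment accuracy is logged
alongside.

## Chirp synchronization

`make_chirp()` builds a linear 500–4000 Hz sweep, 100 ms long,
Hann-tapered over 10 % of each edge — the band sits inside telephony
bandwidth so 8 kHz material can be synchronized too. `locate_chirps()`
normalizes both the template and each recording window to unit energy,
so its threshold (default 0.5) is a level-independent similarity;
candidate peaks are accepted greedily, strongest first, subject to a
minimum separation (chirp plus one clip slot by default). Localization
is exact to the sample in the noiseless case and stays within 1 ms at
0 dB SNR.

## Numerical and reporting conventions

* **Resampling** is windowed-sinc polyphase: zero-stuffing, a Blackman
  low-pass of $80\max(p,q)+1$ taps at the tighter Nyquist limit, exact
  group-delay compensation (zero phase). An up-down round trip preserves
  3.5 kHz band-limited content with correlation above 0.99.
* **AUC** is the trapezoid over the tie-grouped empirical ROC, which
  equals the Mann–Whitney $U/(n_1 n_0)$ statistic exactly.
* **Confidence intervals** are Wald:
  $\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n}$, clipped to $[0,1]$ — this
  form reproduces the published operating-point intervals at the stated
  class counts. Wilson intervals were considered and rejected because
  they do not reproduce those printed values.
* **Percentages** are rounded half away from zero (`round_half_up()`),
  2 decimals for metrics, 5 for streaming false-positive rates.
* **Degenerate inputs**: silent clips normalize to themselves; a clip
  shorter than one segment yields an empty stream with a warning, not an
  error; a central-apnea track shorter than its own gap is all gap.

## Problem sizes

The test-suite and acceptance-script experiments use: 100 scenes per
class (10 s each, ~1060 segments) for grouped 10-fold cross-validation;
100 simulated one-hour streams for the false-positive cascade; 20
45-second scenes for the cancellation benchmark; 20 seeded trials for
noisy chirp localization. These sizes give stable statistics for the
properties being checked (mean fold AUC, cascade ordering, paired
accuracy wins) while a full run stays in the single-digit minutes on one
CPU.

## Known limitations

* The gasp template is a surrogate; its realism cannot be validated
  against clinical audio from here.
* Distance is amplitude-only; no reverberation or device coloration.
* The published headline numbers (AUC 0.9993, sensitivity 97.24 %,
  benchmark accuracies) describe real clinical data and are **not**
  reproduced by synthetic scenes; the package instead holds itself to
  property-level substitutes (separability above 0.95 AUC, the
  false-positive cascade ordering, cancellation wins, and exact
  reproduction of all printed arithmetic).
* Segment windows are non-overlapping by default (which makes
  segment-count accounting exact); an overlapping hop is a parameter,
  not a tested configuration.
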