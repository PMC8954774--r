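---
title: "ECG biometrics with heartprint: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECG biometrics with heartprint: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`heartprint` evaluates the electrocardiogram as a biometric trait in the
across-session setting: templates built from one acquisition session enroll a
subject, templates from a later session test whether the subject can be
re-identified (one-to-many) or verified (one-to-one). This vignette is the
package's own account of the models it implements, the parameters that
matter, and the choices made where the design was genuinely open. It states
no empirical result beyond what the package's test suite and
`scripts/acceptance.R` compute.

## The synthetic cohort model

Real two-session finger-ECG corpora are small, noisy, and carry no ground
truth for beat locations. The generator therefore substitutes a controlled
cohort with the same structure — by default 63 subjects, two sessions, 120 s
per record at 1 kHz — in which every downstream answer is checkable.

Each heartbeat is the sum of five Gaussian bumps (P, Q, R, S, T), each with
an amplitude (mV scale), a center offset relative to the R peak (s), and a
width (s). The canonical beat is a textbook sinus shape (R amplitude 1.0 mV,
T 0.35 mV at +0.26 s, P 0.15 mV at −0.18 s, Q/S small negative deflections)
at 75 bpm with 3 bpm of heart-rate variability. A Gaussian-bump beat is not
a dynamical model of the cardiac dipole, but it is differentiable, cheap,
and — crucially — its R-bump centers are exact ground truth for the
detector and segmenter.

* **Between-subject separation** (`between_subject_sd`, default 0.3):
  subject morphologies are log-normal perturbations of the canonical beat
  (multiplicative on amplitudes and widths, additive on centers and heart
  rate). 0.3 gives amplitude ratios spreading over roughly ±2× across
  subjects — distinct but overlapping morphologies, which is what makes the
  matching problem non-trivial rather than either degenerate extreme.
* **Inter-session drift** (`session_drift`, default 0.05): session 2 equals
  session 1 plus a zero-mean perturbation of the same family. The drift
  draws come from a stream that does not depend on the drift value, so
  cohorts at different drift levels share their underlying randomness and
  differ only in scale — this is what makes "accuracy non-increasing in
  drift" a clean comparison. The default 0.05 represents a low-drift
  regime: electrode placement and physiological change over months alter
  amplitudes by a few percent. Wave-order and amplitude-dominance
  invariants are enforced by truncating the perturbation draws at ±2.5 sd
  and clamping |Q|, |S| below 0.9 R, so any drift scale yields a valid
  morphology.
* **Noise** (defaults: baseline wander 0.2 mV below 0.4 Hz, 50 Hz powerline
  0.05 mV, white broadband 0.05 mV sd): the three canonical contaminants of
  dry-electrode ECG. Baseline wander is deliberately placed inside the
  filter's stopband so preprocessing must actually remove it; the powerline
  frequency is fixed at 50 Hz (European acquisition context). Broadband
  noise stands in for EMG; it is white rather than spectrally shaped, which
  makes it slightly *harder* for the 0.5–30 Hz bandpass than real EMG
  concentrated above 20 Hz.
* **Beat placement**: inter-beat intervals are Gaussian around 60/HR s with
  sd proportional to the heart-rate variability, truncated at ±3 sd and
  floored at 0.3 s so beats never overlap. R times are snapped to the
  sample grid, making the stored peak indices exact.
* **Reproducibility**: every record draws from its own stream derived from
  (seed, subject index, session index), so a cohort is byte-stable under
  regeneration and under subsetting to fewer subjects.

What the generator does **not** emulate: realistic HRV spectra, arrhythmia
or other pathology, electrode-motion transients, amplitude quantization
(the 12-bit ADC of real acquisitions), or T/P-wave morphology changes with
heart rate. Passing tests on this cohort therefore demonstrate that the
pipeline's machinery is correct and that its statistics behave as designed
— not that the headline accuracies transfer to real off-the-person
recordings, which are substantially harder.

## Preprocessing

* **Bandpass** 0.5–30 Hz, Butterworth, `order = 4` passed to the analog
  prototype (8 poles for the bandpass — the conventional reading of a
  "4th-order Butterworth bandpass"). The filter is applied
  forward–backward, so the effective gain is the squared single-pass
  magnitude and the phase is zero; zero phase matters because the 200/400
  segmentation window is anchored on the R peak and a causal IIR pass would
  shift it by several milliseconds. Each pass starts in steady state with
  respect to the first sample (the `lfilter_zi` construction), which
  removes the DC start-up transient exactly; plain forward–backward
  filtering with zero initial conditions leaves a transient comparable to
  the 0.5 Hz cut-off's multi-second settling time.
* **R-peak detection** is a derivative-energy detector: squared first
  difference, 150 ms moving-average smoothing, threshold at 0.2× the 99.5th
  percentile of the smoothed energy, one candidate per supra-threshold
  region, refinement to the signal's local maximum within ±25 ms, and a
  200 ms refractory period keeping the larger peak. The percentile-based
  threshold makes the detector scale-free (template matching later requires
  no amplitude calibration) and returns an empty set on silent input. The
  detector is a replaceable component behind a fixed interface; its
  contract is validated against the generator's ground truth (every true
  peak within 10 ms on noise-free records; sensitivity and positive
  predictivity ≥ 0.95 at default noise).
* **Segmentation** takes 600 samples per cycle — 200 before and 400 after
  the R peak — and silently drops peaks too close to a record boundary to
  supply the full window, so every template has identical length by
  construction.
* **Min–max normalization** rescales each cycle to [0, 1], discarding
  amplitude information that varies with electrode contact. A constant
  cycle cannot be rescaled; it is dropped with a warning rather than
  failing the record, since a flat segment is an acquisition artifact, not
  a data error.
* **Segment elimination** keeps the k cycles "most similar to each other":
  each cycle is scored by the sum of its Euclidean distances to all other
  cycles and the k lowest scores win, ties toward the earlier cycle. This
  is a deterministic O(n²) ranking, not the NP-hard minimum-total-distance
  subset; the brute-force recomputation in the test suite confirms the
  ranking semantics. Elimination operates on cycles in their current
  normalization state (the normalized arm eliminates on normalized
  waveforms), and the order "normalize, then eliminate" is the package
  default — the alternative order is available by composing the exported
  primitives, since neither order is canonical.

## Scalogram templates

The continuous wavelet transform uses the generalized Morse wavelet,
defined in the frequency domain as Ψ(ω) ∝ ω^β e^(−ω^γ) for ω > 0 with
γ = 3 and time-bandwidth product P² = 60, hence β = P²/γ = 20. γ = 3 gives
the most symmetric member of the family, well suited to transient cardiac
waveforms. Each scale's filter is unit-peak normalized; the peak radian
frequency is ω_p = (β/γ)^{1/γ}, which maps scales to center frequencies.
Twelve voices per octave span 1–40 Hz (65 scales), covering the filtered
band with margin; scales are stored highest-frequency first, matching the
conventional scalogram display. The transform is computed per cycle by FFT,
multiplying by each scale's filter on the non-negative frequency half-axis
(the wavelet is analytic) and inverse transforming — one `mvfft` per cycle.

Magnitudes are min–max normalized **per scalogram** (the template encodes
shape, not absolute voltage; a global scale would make every image's
dynamic range depend on the loudest cycle in the cohort), mapped through a
fixed five-anchor blue→cyan→green→yellow→red piecewise-linear colormap, and
bilinearly resized with half-pixel centers to 56×56 or 224×224. The
colormap only needs to be fixed and documented — any order-preserving
cold→hot map yields equivalent distances — and the resize convention is
pinned by a consistency property: rendering at 224 and downsampling to 56
agrees with direct 56 rendering within a mean absolute channel error of
0.05. A constant magnitude matrix (no dynamic range) maps to the colormap
midpoint.

## Concatenation and FastICA

Per-subject templates are concatenated into a subjects × features matrix:
template-major in temporal order; within an RGB image, row-major with
channel last. The convention is documented and invertible
(`unflatten_template()`), and a round-trip test enforces it. With the
standard configurations the feature lengths are 600 × 20 = 12,000 for cycle
templates and 3 × 56² × 20 = 188,160 / 3 × 224² × 20 = 3,010,560 for
scalograms.

FastICA is implemented in the package (deflation scheme, logcosh/tanh
contrast, tol 1e-4, max 500 iterations per component, seeded random
initial directions; non-convergence is reported as a warning, not an
error). Two arrangement choices deserve note:

* Subject rows are treated as observed **mixtures over the feature axis**,
  each row centred on its own mean, and whitened by PCA of the row-by-row
  covariance. Under this arrangement an n-subject matrix has numerical
  rank n (row-centring projects on the feature side), so a 63-subject
  matrix supports the full 63 independent components used by the standard
  configuration. Centring each feature column instead would cap the rank
  at 62 and make 63 components unattainable. Requests beyond the
  row-centred rank raise an error advising a smaller component count.
* The model is fitted on **session-1 rows only** and stored as the source
  matrix plus a projector; session-2 rows are transformed through it. The
  fit never sees presentation data (leakage-safe), and the session firewall
  is structural: no fitting routine in the package accepts session-2
  objects.

Transforming the training matrix recovers its mixing coefficients exactly
when the component count equals the training rank; the toy 3-source
recovery test (8 mixtures of known sources, matched |correlation| ≥ 0.95)
is the independent correctness check for the whole whitening/deflation
path.

## Identification

Classifier identification treats each 600-sample cycle as one observation
labelled with its subject. Classifiers are fitted on session-1 cycles and
every session-2 cycle is classified; the subject's predicted identity is
the majority vote over their cycles, with ties broken by the higher summed
classifier confidence, then the lexicographically first id. Subject-level
reporting matches the granularity at which closed-set accuracy is
meaningful here (one decision per enrolled person). Defaults where the
choice was open: kNN k = 3 with Euclidean distance; SVM with RBF kernel,
C = 1, γ = 1/(p · var); CART with Gini and default depth; LDA preceded by a
PCA projection onto at most (n − g − 1) components with a 1e-4 relative
sdev floor, because 600-sample waveforms are strongly collinear and the
pooled covariance must stay well conditioned. The PCA step is a rank
control, not a feature-selection tuning knob.

Distance identification is Manhattan 1-NN over reduced template rows:
Configuration 1/1 scores a subject correct when their single presentation
row's nearest enrollment row is their own; Configuration 1/3 requires at
least two of three presentation rows to agree. The three presentation
templates are formed by partitioning the 60 selected session-2 cycles into
three consecutive blocks of 20, concatenated and transformed with the same
ICA model — consecutive blocks preserve the temporal interpretation of a
"presentation". When no label reaches two votes the subject has failed;
the confusion matrix then records the smallest-distance non-self
prediction, keeping reported accuracy identical to the 2-of-3 rule.

A convolutional image classifier is included only as a pluggable surface
(`identify_with_cnn`): no deep-learning backend ships with the package, so
calling it without one raises a clear "component unavailable" error, and
any supplied backend is evaluated with the same majority-vote report. It
carries no accuracy contract.

## Authentication

The threshold for subject i is T_i = μ_i − σ_i, where the distance pool is
the set of Manhattan distances between subject i's presentation
template(s) and the enrollment templates of **all** subjects, self
included (the pool is a property of the presentation against the whole
gallery). σ_i is the population standard deviation (divide by n): the
threshold is a descriptive statistic of a fixed, fully observed pool, not
an inferential estimate from a sample — the sample convention remains
switchable (`sd = "sample"`), as does the self-exclusion
(`include_self = FALSE`) and the multiplier (`sigma_mult`).

Boundary conventions follow the rule's phrasing exactly: genuine
authentication accepts on "does not exceed" (≤ T_i), impostor flagging
requires strictly "below" (< T_i). Ties therefore resolve pro-genuine and
anti-impostor; with continuous distances the measure-zero boundary makes
this choice immaterial in practice, but it is fixed and tested.

Impostor evaluation is leave-one-out: each subject is held out, their
threshold is recomputed from distances to the n − 1 remaining enrollment
templates, and every remaining subject falling below it is an impostor of
the held-out subject (2-of-3 for Configuration 1/3). The impostor score is
the mean over subjects of the impostor count as a percentage of the n − 1
possible impostors. By construction a μ − σ threshold sits one standard
deviation below the mean impostor distance, so a double-digit impostor
percentage is an expected property of the rule itself, not a defect of the
templates; the test suite verifies the trade-off directly (μ − 2σ never
increases either the impostor score or the genuine-acceptance rate).

## Numerical choices and degenerate inputs

* Filtering: `signal::butter` coefficients; steady-state initialization
  per pass; stable at 1 kHz for the 0.5–30 Hz band (verified against a
  direct transfer-function evaluation, `filter_response()`).
* Detection: empty result on all-zero input; error below 2 s of signal
  (too short for an adaptive threshold to mean anything).
* Elimination: ties in the similarity score break toward the earlier
  cycle; selection is returned in temporal order; requesting more cycles
  than exist is an error naming the record.
* ICA: eigenvalue floor 1e-10 (relative) defines the numerical rank;
  deflation orthogonalizes against previously extracted components at
  every iteration.
* Images: constant magnitudes map to the colormap midpoint; resize clamps
  source coordinates at the grid edge.
* Thresholds: pools with zero spread give T = μ, so identical distances
  authenticate (≤) but never flag impostors (<).

## Problem sizes

The test suite exercises unit properties on 6–12-subject cohorts of
40–75 s records and runs the acceptance-scale checks — the 63-subject,
two-session, 120 s cohort — for the structural template dimensions, LDA
identification (Configuration 60/60) and threshold authentication over
seeds 1–5, plus a three-level drift sweep. `scripts/acceptance.R` repeats
the full-scale run for a single command-line seed. These sizes were chosen
so the complete suite and the acceptance script each run in minutes on a
single CPU while still covering the full study geometry.

## Known limitations

* Synthetic validation only: the cohort model omits the hardest features
  of real off-the-person ECG (motion artifacts, contact loss, pathological
  rhythms), so absolute accuracies here exceed what real data yield.
* The R-peak detector is deliberately simple; on real recordings a more
  robust detector (or an external toolkit) should be substituted behind
  the same interface.
* FastICA's deflation scheme may fail to converge within the iteration cap
  for high component counts; the model is still usable (the warning
  reports how many directions stopped early) but not bit-identical across
  BLAS implementations.
* Authentication thresholds depend on the presentation-time distance pool,
  so the system as specified is an evaluation protocol rather than a
  deployable verifier with pre-registered thresholds.
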