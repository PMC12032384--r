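---
title: "Models and methods: quantifying Pavlovian reward conditioning from four psychophysiological channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavcal)
```

## The problem

In differential reward conditioning, one visual cue (CS+) predicts a
primary reward (a sip of fruit juice, the US, delivered 5 s after CS+
onset on half of the CS+ trials) and a second cue (CS−) predicts its
absence. Learning — and, a week later, memory retention — is indexed by
the difference between the physiological responses the two cues evoke.
`pavcal` implements the full quantification chain for four candidate
response channels: heart period responses (HPR), skin conductance
responses (SCR), pupil size responses (PSR), and respiration amplitude
responses (RAR). The criterion throughout is *retrodictive validity*: a
manipulation known to have occurred (CS+ vs CS−) should be recovered
with as large a standardized effect size as possible; measures with
Hedges *g* > 0.5 are retained.

Because the package must be testable without human recordings, a forward
simulator generates complete synthetic cohorts with a known injected
effect, and every analysis stage is validated against that ground truth.

## The LTI model and its inversion

Each channel is modelled as a linear time-invariant (LTI) system: a
neural input of unknown amplitude at each CS onset, convolved with a
channel-specific response function (RF), produces the observed time
course. Amplitudes are estimated by inverting a general linear
convolution model (GLM): regressors are unit impulses at event onsets
convolved with the RF, and ordinary least squares recovers one amplitude
per trial (pupil, skin conductance — responses short enough to separate)
or per condition (heart period, respiration — responses outlasting the
inter-trial interval). Rank-deficient designs are an error, never a
silent pseudo-inverse, and the design's condition number is reported.

Two estimation details matter numerically:

* **Filter-matched regressors.** Wherever the data pass through a
  zero-phase band-pass (heart period 0.015–0.5 Hz, skin conductance
  0.0159–5 Hz, respiration amplitude 0.01–2 Hz), the regressor columns
  are passed through the same filter. Without this, the very low
  high-pass cutoffs would attenuate the slow kernels and bias amplitudes
  by far more than the 2% the recovery tests allow.
* **Resampling-matched regressors.** Heart period and respiration
  amplitude are only observed at beat / breath resolution. The data
  series is built by linear interpolation between those anchors, so the
  regressors are sampled at the same anchors (IBI interval midpoints;
  cycle peak/trough pairs) and interpolated identically before
  filtering. This removes the distortion that ~1-s (beats) and ~4-s
  (breaths) sampling of the kernels would otherwise introduce.

## Response functions

The kernel registry (`rf_registry()`) holds the published kernels:
`hprf_rew` (gamma, for heart period), `rarf_rew` (gamma, respiration),
and six pupil kernels `psr_rf1`–`psr_rf6` (gamma, Gaussian, empirical,
two-gamma mixture). Pupil extraction windows are 15 s (RF1), 3.5 s (RF2,
RF6) and 3 s (RF3–RF5).

**The θ convention.** The published parameter tables annotate the gamma
time-constant as a rate (s⁻¹), but no single reading places every
kernel's peak inside its extraction window. Each kernel therefore
carries an explicit per-kernel convention flag:

* RF1, RF2 and the respiration kernel treat θ as the gamma **scale** in
  seconds. Under this reading RF2 peaks at (κ−1)θ + t0 ≈ 1.76 s —
  consistent with its 3.5-s window — whereas the rate reading would put
  the peak at ≈ 709 s.
* The heart-period kernel (κ = 1.72, θ = 0.14, t0 = −17.61 s) treats θ
  as a **rate** (scale ≈ 7.14 s), giving a broad slow wave spanning
  roughly −18 s to +25 s around CS onset. The scale reading would
  compress the entire kernel into a 0.3-s spike 17.5 s *before* the
  stimulus, which is incompatible with conditioned bradycardia evolving
  over tens of seconds.

Negative-time support is retained: the zero-phase (bidirectional)
filtering used in preprocessing makes the whole analysis acausal, so a
kernel with pre-onset mass is representable, and the support is exposed
as a configurable field.

`psr_rf5` combines two gamma components as
`c·(g1(t−t0) − r·g2(t−t0))` with `gk` a gamma pdf of shape `ok/dk` and
scale `dk`; the combination rule is not defined by the published table,
so this convention is documented and swappable, and all fitting tests
use self-consistency rather than external bit-equality. `psr_rf4` and
`psr_rf6` are defined from empirical waveforms that can only be
regenerated from the original recordings; the registry ships clearly
labelled *synthetic stand-ins* built in code (their `provenance` fields
say so), sufficient to exercise every code path that consumes an
empirical kernel.

`rf_fit()` refits gamma/Gaussian kernels to condition-difference
waveforms by Nelder–Mead least squares with optional multistart; on its
own noiseless waveform it recovers the heart-period kernel's parameters
to better than 1%.

## Channel pipelines

**Heart period.** Beats → preceding inter-beat intervals; IBIs outside
50–150 bpm marked invalid; valid IBIs linearly interpolated in
chronological time at 100 Hz and band-pass filtered (0.015–0.5 Hz,
zero-phase). Heart *period* (ms), not rate, is the analysis variable
(autonomic input relates linearly to period). Because the response
outlasts the 5-s CS–US interval, only nonreinforced CS+ trials enter the
CS+ regressor; reinforced CS+ and US onsets are modelled as nuisance.
The band-pass is implemented as a cascaded 2nd-order high-pass plus
2nd-order low-pass (4 poles in total, applied bidirectionally): a direct
8-pole band-pass in transfer-function form is numerically unstable at a
normalized cutoff of 3·10⁻⁴. Invalid IBIs are bridged by interpolation
up to a 5-s gap cap, beyond which samples are flagged missing.

**Skin conductance.** Samples outside 0.05–100 μS or steeper than
10 μS/s are marked missing, interpolated for filtering, band-passed
(1st-order, 0.0159–5 Hz), and downsampled to 10 Hz. Trial-wise CS and
US/omission amplitudes are estimated with a *constrained linear GLM*: a
canonical bi-exponential kernel (1-s latency, 0.8-s rise, 4-s decay,
unit peak; configurable) locked to CS onset and to CS onset + 5 s. This
deliberately approximates the variational trial-wise estimator used with
real data — outputs are labelled `estimator = "constrained_glm"` — and
all trials are estimated jointly in one session-wide design rather than
per-trial windows, so neighbouring-trial overlap cannot bias estimates.
Amplitudes are normalized by each participant's mean CS− amplitude,
making them dimensionless and gain-invariant; the normalized CS− mean is
1 by construction.

**Pupil.** Validity filtering (plausible range 1.5–9 mm; dilation-speed
outliers by a median + 16·MAD criterion with a 10-mm/s absolute floor so
that near-noiseless recordings do not flag ordinary response slopes;
island and gap-edge trimming), gaze filtering (> 5° from screen centre),
a first-order cosine foreshortening correction (diameter divided by the
cosine of the gaze eccentricity — a simplification of the full
geometric correction), 50-Hz low-pass where applicable, resampling to
100 Hz, and z-scoring per block (the analysis units; a `zscore = FALSE`
switch keeps millimetres, used by the recovery tests). Trial amplitudes
are segment projections onto the kernel for RF2–RF6; RF1's 15-s support
equals the shortest trial spacing, so RF1 uses a session-wide trial-wise
GLM in which every trial is a regressor. Two peak-scoring baselines are
implemented: maximum over CS→US onset minus a 1-s pre-CS baseline, and
maximum over the final pre-US second minus a 2-s baseline. Exclusions:
trials with |estimate| > 6 mm or > 50% missing samples; participants
with > 50% of trials dropped.

**Respiration.** Cycles are detected at rising zero-crossings of the
band-limited belt signal; the per-cycle peak-to-trough amplitude
(implausible cycle durations outside 1–15 s discarded) is interpolated
at 10 Hz and band-passed (0.01–2 Hz). Condition-wise GLM with the
respiration gamma kernel, learning phase only by default (recall-phase
respiration is not analysed by convention, though the code permits it).

## The synthetic cohort generator

The generator's statistical core draws, per participant, a standardized
CS+/CS− amplitude difference `d_i ~ N(δ, σ_between²)` and per-trial
amplitudes `base + [CS+]·d_i + N(0, σ_trial²)`; each channel maps
standardized units into its own units with a fixed scale. Defaults are
the study conditions: 34 participants (the a priori sample size), δ =
0.6, σ_between = 1, σ_trial = 2, a 2-block 96-trial session with 50%
reinforcement, resting heart period 0.9 s, tonic skin conductance 5 μS,
pupil 4 mm, breathing at 0.25 Hz (15 breaths/min). Channel scales
(heart 15 ms, skin conductance 0.3 μS, pupil 0.1 mm, respiration 0.1
a.u. per standardized unit) and CS− base responses were chosen once to
sit in the physiological range of evoked responses; they are not tuned.
The implied true paired effect after trial averaging has the closed form
`δ / sqrt(σ_between² + σ_trial²(1/n₊ + 1/n₋))` (`true_paired_effect()`),
which the statistical calibration tests use as their oracle.

Waveforms are rendered forward through the same kernels the analysis
inverts: beats by integral pulse frequency modulation (integrate 1/h(t)
to 1 — chosen because it makes the IBI analysis consistent by
construction), pupil and skin conductance by direct kernel summation
with pink (spectrally shaped 1/f) measurement noise, respiration as a
carrier whose peak-to-trough envelope carries the responses. Blinks,
gaze excursions beyond 5°, and fast skin-conductance artifact spikes
exercise the respective artifact filters. The design includes 60-s rest
lead-in/lead-out so that the settling transients of the very-low-cutoff
zero-phase filters stay away from the trials, as in a real recording.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: non-LTI response saturation, habituation and
extinction dynamics within a phase (injected amplitudes are
condition-stationary unless configured otherwise), kernel mismatch
between participants (everyone shares the population kernel),
respiratory sinus arrhythmia coupling between channels, and slow tonic
drifts beyond the filters' stop-bands. Recovery tests therefore validate
the *estimator*, not the physiological adequacy of the kernels.

## Statistics

Condition estimates are compared with a classical paired t test and
converted to Hedges g via `g = (t/√n)·J(n−1)` with the exact correction
`J(df) = Γ(df/2)/(√(df/2)·Γ((df−1)/2))` (computed on the log scale).
The printed source equation for this conversion is typographically
mangled; this reading reproduces all published effect sizes to the
printed precision (see `analysis/04_published_conversions.R`).

Tests are **two-sided by default**. The sample-size rationale (n = 34
for 80% power at d = 0.5) is stated as one-sided in the source protocol,
but n = 34 is exactly what a two-sided paired test requires (one-sided
would need n ≈ 27), and the published p-values match two-sided tests
(t(36) = 2.48 → p = 0.02). The calibration suite asserts the two-sided
reading: 2000 null cohorts give a type-I error of 5% ± 1%, and cohorts
with a true paired effect of 0.5 give two-sided power 0.80 ± 0.03 (the
one-sided value, ≈ 0.89, is computed but not asserted).

Further layers: single-pass ±3 SD participant exclusion per condition
(non-pupil measures); early-trial subset scans g(n) over the first
1…n trials per condition — with the 1 CS+ : 2 CS− pairing where only
nonreinforced CS+ trials are retained, and a skip-first-pair variant for
the learning phase; halves analyses for condition-wise measures; and
step-down Holm–Bonferroni correction (via `stats::p.adjust`, with a
brute-force enumeration oracle in the tests).

## Numerical choices and degenerate inputs

* Zero-phase filtering is always bidirectional `filtfilt`; series are
  demeaned first (a ~900-ms DC heart-period level would otherwise drive
  large edge transients through the 0.015-Hz high-pass).
* The identical-vectors paired test returns t = 0, p = 1, g = 0; zero
  variance with a nonzero mean difference is an error.
* Trial randomization uses rejection sampling with a 10,000-draw budget
  per block for the run-length constraints ("no more than three
  same-CS, or reinforced, trials in a row" — the reinforced-run rule is
  read across conditions) and errors explicitly when infeasible. The
  first CS+ of each block is always reinforced; ITIs are uniform random
  integers on [9, 16] s; the feedback and swallow windows occur inside
  the ITI and do not extend it.
* Problem sizes in the bundled tests and scripts: unit tests run
  single-block mini-designs (3–8 trials per condition); the end-to-end
  recovery check uses 8 noiseless participants under the full 96-trial
  design; the statistical calibration uses 2000 amplitude-level cohorts
  of 34; the workflow scripts simulate 12 participants per phase. These
  sizes were chosen so the whole suite completes in about a minute while
  keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The SCR estimator is a linear approximation of the variational
  estimator used with real data; normalized condition means near 1 are
  expected by construction, and numerical identity with the original
  posterior estimates is explicitly not claimed.
* RF4/RF6 ship as synthetic stand-ins (see above); analyses selecting
  them exercise correct plumbing but not the original waveforms.
* The foreshortening correction is first-order cosine only.
* Condition means and SDs of the original experiments cannot be
  reproduced without the archived recordings; the package's claims are
  therefore property-based (recovery, calibration, self-consistency)
  plus exact reproduction of the published effect-size conversions.
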