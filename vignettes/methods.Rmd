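---
title: "Posture-resolved nocturnal HRV: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posture-resolved nocturnal HRV: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

posturehrv implements a complete analysis chain for nocturnal Holter
recordings carrying a built-in triaxial chest accelerometer: sleep-posture
classification in 30 s epochs, posture-resolved heart-rate-variability (HRV)
indices, an ECG-based sleep-apnea screen, nighttime eligibility rules, and
age/sex-stratified cohort statistics. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions taken where
the underlying methods leave latitude.

## Coordinate conventions and posture classification

The device is worn on the upper chest with its axes aligned to the body:
X along the head–foot axis (positive toward the head), Y along the
left–right axis (positive toward the subject's right), Z along the
front–back axis (positive out of the chest). At rest, the low-passed
accelerometer signal is the gravity *reaction* vector, which points skyward
with magnitude 1 g. This sign convention is the unique one under which the
classification rules below give supine for back-lying (sky along +Z) and
left-lateral for left-side lying (sky along +Y).

Classification proceeds in four stages (`classify_posture()`):

1. **Movement detection.** Each axis is band-passed at 2–3 Hz; an epoch is a
   movement epoch when the peak root-sum-of-squares magnitude of the three
   filtered axes reaches 20 mG (`movement_threshold_g = 0.020`). Movement
   epochs are never posture-labelled.
2. **Gravity extraction.** Each axis is low-passed at 0.1 Hz
   (`gravity_corner_hz`), zero-phase so the gravity estimate is not shifted
   against the epoch grid.
3. **Per-sample angle rules** (`sample_posture()`). With θ~A~ the angle
   between the gravity vector and body axis A: lying iff θ~X~ ∈ 84° ± 36°
   (i.e. [48°, 120°], boundaries inclusive — a measure-zero choice); within
   lying, left lateral iff θ~Y~ < 65°, right lateral iff θ~Y~ > 111°,
   otherwise supine iff θ~Z~ < 60° and prone otherwise. Inequalities are
   strict exactly as printed; a value sitting on a threshold falls through
   to the next clause.
4. **Epoch majority.** A non-movement epoch takes the posture covering
   > 50% of its samples (`majority_frac`); with no majority it is a
   `transition` epoch. A majority of non-lying samples gives `non_lying`.

One could equally classify an epoch-averaged gravity vector instead of the
instantaneous one; we classify per sample and then take the epoch
majority, the reading most consistent with a ">50% of the segment" rule.
Per-subject posture
percentages are computed over posture-labelled epochs only — movement,
transition and non-lying epochs are excluded from numerator and
denominator.

All filters in the package are second-order Butterworth designs run
forward–backward (fourth-order zero-phase magnitude response), except the
demodulation low-pass below. Signals are padded by odd reflection before
filtering: a plain double pass from zero state leaves a transient of
roughly the corner period, which at 0.1 Hz would corrupt the first epochs
of every recording.

## Time-domain indices

Only normal-to-normal (NN) intervals — both flanking beats labelled sinus —
enter any HRV computation. Per 30 s epoch, HR = 60000 / mean(NN ms) and
SDRR is the sample standard deviation (n−1). An epoch reports these only
with at least `min_nn_per_epoch = 10` NN intervals — there is no standard
minimum, and 10 bounds estimator variance while discarding few epochs at
normal heart rates.

## Frequency-domain indices by complex demodulation

The NN tachogram (interval value at its terminating beat time) is
interpolated with a cubic spline and resampled at 2 Hz. Annotation gaps
longer than `max_gap_s = 5` s mark the bridged span invalid; epochs
touching an invalid span report NA. For each band — VLF 0.003–0.04 Hz,
LF 0.04–0.15 Hz, HF 0.15–0.40 Hz — the mean-removed series is multiplied by
exp(−i2πf₀t) with f₀ the arithmetic band centre, low-pass filtered at half
the bandwidth (fourth-order Butterworth, zero-phase), and read off as

* amplitude 2|y(t)| (a sinusoid of peak amplitude A returns A), and
* instantaneous frequency f₀ + (1/2π)·dφ/dt from the unwrapped phase by
  central differences, clamped to the band edges; where the amplitude is
  numerically zero the frequency is reported at f₀.

Per-epoch values are the mean amplitude and the amplitude-weighted mean
instantaneous frequency (weighting is our choice; unweighted means differ
negligibly when amplitude is stable within an epoch). LF/HF defaults to the
squared amplitude ratio (`lfhf_convention = "power"`), matching the
customary power-ratio units; the plain amplitude ratio is also available
since both conventions circulate in the HRV literature.

Tone-recovery accuracy is limited by the demodulation low-pass: with the
fourth-order design, a tone in the middle 60% of a band is recovered within
about 2% of its amplitude, degrading toward the band edges where the filter
rolls off. Note also that respiratory oscillations near the top of the HF
band approach the beat-sampling Nyquist rate at slow heart rates, so the
spline tachogram itself attenuates them before demodulation sees them; this
is a property of tachogram analysis, not of the demodulator.

## Respiratory-frequency stability (Hsi)

Hsi measures how concentrated HF-band spectral power is around its peak.
The 2 Hz series is cut into overlapping 256 s (512-point) windows stepped
by 30 s; each window is linearly detrended, Hann-tapered, and Fourier
transformed (bin width 1/256 Hz ≈ 0.0039 Hz). Hsi is 100 × (power within
±5 bins of the HF peak bin) / (total HF-band power), assigned to the 30 s
epoch at the window centre. The ±5-bin half-width (≈ ±0.0195 Hz) is the
package default; implementations of HF-concentration indices differ on
this constant, so it is a configuration knob (`hsi_halfwidth_bins`) and
the package's own tests assert relative behaviour (monotone decrease under
respiratory jitter), not absolute Hsi values. The numerator is intersected with the HF
band so Hsi stays within [0, 100] when the peak sits at a band edge. For
white noise, Hsi settles near 100·11/64 ≈ 17% (64 HF bins), slightly above
because the peak bin is chosen as the maximum.

## CVHR detection and apnea screening

Cyclic variation in heart rate (CVHR) appears as trains of transient RR
shortenings accompanying apnea episodes. Clinical CVHR screening has
historically relied on proprietary waveform-analysis detectors; this
package implements an open baseline-subtraction detector and validates it
by parameter recovery on synthetic data — bit-for-bit agreement with any
proprietary detector is out of scope.

1. The 2 Hz tachogram is low-passed at `cvhr_smooth_hz = 0.1` Hz to remove
   respiratory oscillation. Without this stage, respiratory sinus
   arrhythmia troughs — and chance alignments of VLF, LF and HF troughs —
   masquerade as deep narrow excursions and corrupt nadir and width
   measurement; a 10–120 s dip passes the filter essentially intact.
2. A 130 s moving-median baseline (`cvhr_baseline_s`) is subtracted.
3. Excursions at least `cvhr_depth_min_ms = 50` ms below baseline whose
   full width at half depth lies in `cvhr_width_s = [10, 120]` s become dip
   candidates. Threshold crossings closer than half the minimum inter-dip
   interval are merged first: no pair of genuine dips can be that close,
   while residual ripple can split one dip into two crossings.
4. Dips count as CVHR only within trains: consecutive dips linked by
   inter-dip intervals in `cvhr_interdip_s = [25, 130]` s, with
   neighbouring intervals within a factor of 2 of each other
   (`cvhr_ratio_range`), in runs of at least three dips.

The estimated apnea–hypopnea index (AHI) is the number of train-member
dips with nadirs inside nighttime lying epochs divided by the hours of
lying epochs; 15/h and above classifies as moderate-to-severe sleep apnea
(boundary inclusive). Each epoch is flagged apnea-positive when a member
nadir falls inside it, so a dip straddling a boundary counts once.

## Eligibility and aggregation

A subject is analysed only when (i) more than 5 h of posture-labelled lying
epochs start inside the 22:00–08:00 night window and (ii) at least 80% of
the beats inside those epochs are sinus. The 80% rule is interpreted on a
beat-count basis; a time-covered basis is available
(`sinus_frac_basis = "time"`) because the original basis is not stated.
Times are seconds since midnight, continuing past 86 400 after midnight, so
the night window is simply [79 200, 115 200). Per-posture index means
require at least `min_epochs_per_posture = 10` epochs (again our bound; the
source states none). The per-posture CVHR rate is apnea-positive epochs in
the posture divided by hours spent in it.

## Cohort statistics

Ages are binned into decades (AGE10), capped at 90. Cohort cells
(sex × AGE10 × posture) report mean, sample SD and n per index. Effect
sizes use η² = SS~effect~/SS~total~ from the one-way decomposition, with p
from the one-way F-test. Posture effects within subjects use the textbook
one-within-factor repeated-measures ANOVA (`aov` with an `Error(subject)`
stratum), complete-case over the four postures, with an optional
between-subject factor for posture × group interactions. Large clinical
cohorts are often analysed with multi-way unbalanced GLMs (Type III sums
of squares); this package deliberately restricts itself to the
one-within-factor model, which is sufficient for validating recovery of
injected effects and keeps the decomposition fully transparent. When an
effect sum of squares is exactly zero in a zero-variance input the
F statistic is reported as 0 rather than 0/0.

## The synthetic-data generator

Clinical Holter databases with concurrent actigraphy are not publicly
redistributable, so every stage is validated against a generator with
known ground truth:

* **Acceleration** (`gen_accel()`): per posture interval, the canonical
  gravity vector rotated by a fixed random rotation up to
  `orientation_jitter_deg` (emulating device placement and body obliquity;
  ≥ 30° would be ambiguous near decision boundaries and is rejected), plus
  white noise (default sd 0.005 g). Movement bursts add a 2.5 Hz, 0.05 g
  oscillation with 1 s on/off ramps. Every interior posture boundary gets
  an automatic 30 s burst: a real posture change is itself a movement, and
  an instantaneous gravity flip without one is physically impossible —
  this also keeps truth labels consistent with what any movement detector
  must flag.
* **Beats** (`gen_beats()`): RR(t) = mean + one sinusoid per band + CVHR
  dips, evaluated recursively at beat times (beat~k+1~ = beat~k~ +
  RR(beat~k~)/1000). Respiratory frequency can wander as an AR(1) process
  with a 30 s correlation time (`jitter_sd_hz`), reflected at the HF band
  edges. CVHR dips are negative-going Gaussians parameterised by depth and
  full width at half depth — the tachycardic phase that dip detectors
  target; a preceding bradycardic bump is optional. Ectopic beats (default
  probability 0.02, matching a predominantly sinus clinical night) get
  label V and a 30% shortened interval, guaranteeing exclusion by the NN
  rule.
* **Cohorts** (`gen_cohort()`): epoch-aligned posture bouts of 12–30 min
  (the first four bouts cover all four postures so per-posture minima are
  met), basal HR ~ N(62, 4) bpm, and injectable per-posture HR offsets
  implemented as piecewise mean-RR shifts, with all generating parameters
  recorded in a truth table. Default nights are 6 h from 22:00 — above the
  5 h eligibility floor once movement epochs are removed.

The generator emulates band structure, posture schedules, CVHR trains and
ectopy; it does **not** emulate sleep stages, waveform-level ECG noise,
non-stationary amplitude modulation, arrhythmic rhythms beyond isolated
ectopy, or oblique/transient postures. Passing tests therefore demonstrate
correctness of the pipeline's mechanics and recoverability of injected
effects — not clinical performance on real recordings.

## Validation problem sizes

The package's validation suite uses: a classifier validation set of about
205 truth epochs per posture (jitter ≤ 10°, noise sd 0.005 g); 50 random
tones for demodulation recovery; a five-point respiratory-jitter sweep with
20 replicates per point for Hsi; 3 h synthetic nights with eight injected
dip trains (and a dip-free night for false alarms) for CVHR; 100 replicates
of an n = 40 cohort with a −3 bpm left-lateral offset (between-posture sd
2 bpm) for the repeated-measures power check plus a 500-replicate
within-subject permutation null; and an end-to-end cohort of 24 subjects
with 6 h nights across two age decades. These sizes were chosen so each
property is measured with comfortable statistical margin while the whole
suite stays quick to run.

## Known limitations

* The CVHR detector is a transparent open design; agreement with
  proprietary clinical detectors is untested and untestable here.
* Hsi's peak-window width is a package default, not a community constant.
* The repeated-measures ANOVA deliberately omits multi-way unbalanced
  GLM (Type III) machinery.
* Postures are assigned from threshold rules on the gravity angle; oblique
  or transient positions have no dedicated class beyond `transition`.
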