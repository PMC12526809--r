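# posturehrv

Sleep posture is an under-appreciated modulator of autonomic nervous
system activity during sleep: heart rate and heart-rate-variability (HRV)
indices differ systematically between the left and right lateral
positions, and these differences matter when interpreting nocturnal HRV
from wearable or Holter ECG. **posturehrv** is an R package for analysts
working with Holter recordings that carry a built-in triaxial chest
accelerometer. It classifies sleep posture epoch by epoch, computes
posture-resolved HRV indices, screens for sleep apnea from the heart
rhythm alone, and aggregates cohorts by age decade and sex — plus a
synthetic-data generator with known ground truth so the entire chain is
testable without access to clinical data.

## What it computes

Per 30 s epoch, from the accelerometer (31.25 Hz, axes aligned to the
body's head–foot X, left–right Y, front–back Z):

* **Movement**: peak root-sum-of-squares of the 2–3 Hz band-passed axes
  ≥ 20 mG.
* **Posture** from the 0.1 Hz low-passed gravity vector g, with
  θ_A = ∠(g, axis A): lying iff θ_X ∈ 84° ± 36°; then left lateral iff
  θ_Y < 65°, right lateral iff θ_Y > 111°, else supine iff θ_Z < 60°,
  prone otherwise. Epochs take the posture covering > 50% of samples.

Per 30 s epoch, from the normal-to-normal (NN) RR intervals:

* **HR** = 60000 / mean(NN) bpm and **SDRR** (sample SD, ms).
* **VLF / LF / HF amplitude and instantaneous frequency** by complex
  demodulation of the 2 Hz cubic-spline tachogram: y(t) = x(t)·e^(−i2πf₀t),
  low-passed at half the bandwidth; amplitude 2|y|, frequency
  f₀ + φ′/2π. Bands: 0.003–0.04, 0.04–0.15, 0.15–0.40 Hz. **LF/HF** as the
  squared amplitude ratio.
* **Hsi**, the HF spectral power concentration index: share of HF-band FFT
  power within ±5 bins of the HF peak, over sliding 256 s windows — a
  proxy for respiratory-frequency stability.
* **CVHR**: trains of transient RR dips (depth ≥ 50 ms below a 130 s
  moving-median baseline, width 10–120 s, cyclic spacing 25–130 s). The
  estimated apnea–hypopnea index is train dips per lying hour; ≥ 15/h
  flags moderate-to-severe sleep apnea.

Per subject: nighttime eligibility (> 5 h lying between 22:00 and 08:00,
≥ 80% sinus beats), posture percentages, per-posture index means, CVHR
rate per posture. Per cohort: sex × age-decade × posture tables,
η² = SS_effect/SS_total effect sizes, and one-within-factor
repeated-measures ANOVA for posture effects.

## Worked example

Simulate one 6 h night with a known posture schedule, band-structured RR
dynamics and three injected CVHR trains, then run the full pipeline:

```r
library(posturehrv)
t0 <- 22 * 3600  # 22:00, seconds since midnight
sched <- posture_schedule(data.frame(
  start_s    = t0 + c(0, 1, 2, 3) * 5400,
  duration_s = 5400,
  posture    = c("supine", "left_lateral", "right_lateral", "prone")))
night <- gen_accel(sched, seed = 1)
model <- rr_model(
  mean_rr_ms = 1000,
  vlf  = list(amp_ms = 25, freq_hz = 0.02),
  lf   = list(amp_ms = 20, freq_hz = 0.10),
  hf   = list(amp_ms = 30, freq_hz = 0.25, jitter_sd_hz = 0.01),
  cvhr = list(dip_depth_ms = 150, dip_width_s = 30, inter_dip_s = 60,
              train_starts = c(1200, 4200, 7200), dips_per_train = 10),
  ectopic_prob = 0.02)
beats <- gen_beats(model, 6 * 3600, start_time = t0, seed = 2)
rec <- analyze_subject(night$accel, beats$beats,
                       meta = list(subject_id = "demo", age = 57, sex = "female"))
summary(rec)
```

```
<subject_record> demo: 720 epochs, eligible: TRUE (ok)
  posture %: supine 25.1, right_lateral 24.9, left_lateral 24.9, prone 25.1
  estimated AHI 5.0 /h (normal_to_mild)
per-posture means:
        posture n_epochs hr_bpm sdrr_ms vlf_amp_ms lf_amp_ms hf_amp_ms
1        supine      179  61.26   35.60      36.48     20.33     28.73
2 right_lateral      178  60.04   30.09      25.19     20.08     28.66
3  left_lateral      178  60.64   32.95      30.93     20.05     28.66
4         prone      179  60.06   30.14      24.86     20.16     28.63
  hf_freq_hz  lf_hf hsi_pct
1     0.2505 0.5098   94.24
2     0.2522 0.4969   93.60
3     0.2503 0.4951   93.51
4     0.2479 0.5049   93.26
```

Reading the output: the classifier recovered the four scheduled 90 min
posture blocks (about 25% each; the few remaining epochs are the movement
bursts at posture changes). HR sits at the generated 60 bpm, HF amplitude
near the generated 30 ms respiratory sinus arrhythmia, the HF frequency
at the generated 0.25 Hz, and Hsi is high because the respiratory
frequency was nearly stable. The 30 injected dips over ~6 lying hours
yield an estimated AHI of 5/h — below the 15/h moderate-to-severe cutoff.

Cohort-level use follows the same pattern with `gen_cohort()` /
`analyze_cohort()`; see the methods vignette (`vignettes/methods.Rmd`)
for the models, parameter meanings and design decisions.

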