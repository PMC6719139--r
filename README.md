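# vcgbeat

Heart-rate monitoring and individual beat detection from chest-worn
inertial sensors, for researchers working on non-invasive
mechanocardiography.

Cardiac contraction vibrates the sternum. An inertial measurement unit at
the xiphoid process records those vibrations as seismocardiography (SCG —
linear acceleration, dominated by the dorsoventral **aZ** axis) and
gyrocardiography (GCG — angular velocity, dominated by rotation about the
longitudinal axis, **gX**). Each cardiac cycle leaves fiducial marks in
these waveforms; the aortic-opening (**AO**) peak inside the first heart
sound is a standard surrogate for the ECG R peak. `vcgbeat` turns raw,
jittery accelerometer + gyroscope recordings into an averaged heart-rate
stream (1 Hz refresh) and a list of per-beat AO timestamps, with an ECG
Pan-Tompkins reference path and a full evaluation harness.

## The algorithm

For each rolling 10 s buffer, per axis (aZ and −gX):

1. **Resample** to a uniform 200 Hz grid (shape-preserving pchip) and
   **high-pass** at 0.4 Hz (per-buffer brick-wall filter).
2. **VarWin** enhancement: at each sample, the amplitude range over a
   ~250 ms window, gated to zero unless the window contains both a local
   maximum and a local minimum — oscillation complexes (S1) light up,
   trends vanish.
3. **Windowed autocorrelation**: for window lengths n = 2..10 s, the
   beat-to-beat interval T is the shortest autocorrelation peak lag whose
   harmonics are also peaks; per-window rates 60/T are fused by a weighted
   mean with weights 1/n.

The two axis rates are consolidated: within 10 bpm of each other →
averaged (cross-verified); otherwise the axis closer to the previous
measurement wins. The averaged rate then drives beat detection: a
forward-looking VarWin variant (with post-minimum suppression of
second-heart-sound structure) yields AO candidates under a minimum
spacing of 0.75 × (60/HR) s; candidates are consolidated across windows
and buffers, and an SCG beat is kept only if a GCG peak falls within
25 ms. Detection quality is scored against ECG R peaks by one-to-one
matching within 250 ms:

    TPR = TP / (TP + FN)        PPV = TP / (TP + FP)

plus the squared Pearson correlation r² and Bland-Altman 95% limits of
agreement for the derived heart rates.

No public dataset pairs ECG with 6-axis sternal vibration, so the package
includes a synthetic generator (`simulate_recording`) producing
ground-truth-annotated ECG + SCG + GCG recordings with realistic rhythm
(HRV, respiratory modulation, exercise-recovery decay), S1/S2 waveform
structure, baseline wander, noise and timestamp jitter.

## Worked example

```r
library(vcgbeat)

sim <- simulate_recording(sim_config(duration = 60, mean_hr = 70, seed = 42))
res <- detect_recording(sim$recording)
res
#> <ada_result> 51 refresh instants, 70 beats, median HR 69.8 bpm

head(res$hr[, c("time", "hr_bpm", "hr_scg", "hr_gcg", "source")], 3)
#>        time   hr_bpm   hr_scg   hr_gcg     source
#> 1  9.999985 67.92088 68.06989 67.77186 both-agree
#> 2 10.999985 66.65310 66.60375 66.70245 both-agree
#> 3 11.999985 69.75629 69.83054 69.68205 both-agree

evaluate_detection(res$beats, sim$truth$ao_times, tol = 0.25)
#>   beats TP FP FN TPR PPV        r2
#> 1    70 70  0  0   1   1 0.9799444
```

One measurement is produced per second once the first full 10 s buffer
has accrued (51 refreshes for a 60 s recording). `hr_scg` and `hr_gcg`
are the per-axis autocorrelation rates; `source` records how they were
consolidated (`both-agree` = within 10 bpm, averaged). All 70 true beats
are recovered with no false detections at the 250 ms matching tolerance,
and the instantaneous heart rate from detected AO–AO intervals correlates
with the ground-truth rhythm at r² = 0.98 — on this low-variability
resting rhythm most of the residual is interpolation-grid quantisation.

A command-line interface wraps the same functions:

```sh
exec/vcgbeat simulate --out rec.csv --truth-ao ao.txt --duration 60 --hr 70
exec/vcgbeat detect --in rec.csv --hr-out hr.csv --beats-out beats.csv \
    --ann-out beats.txt --rpeaks-out rpeaks.txt
exec/vcgbeat evaluate --beats beats.txt --ref rpeaks.txt
exec/vcgbeat sweep --in rec.csv --rates 50,100,150,200,250
```

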