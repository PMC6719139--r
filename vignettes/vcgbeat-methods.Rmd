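---
title: "Heart-rate monitoring and beat detection from sternal vibrations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate monitoring and beat detection from sternal vibrations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Every heartbeat shakes the chest. A MEMS inertial unit taped over the
xiphoid process records the cardiac-induced linear acceleration of the
sternum — seismocardiography (SCG), strongest on the dorsoventral aZ axis —
and the coupled angular velocity — gyrocardiography (GCG), strongest as
rotation about the longitudinal axis, gX. Together the six degrees of
freedom form a vibrational cardiography (VCG) measurement. Within each
cardiac cycle the SCG waveform carries fiducial points tied to valve
events: during the first heart sound (S1) the aortic opening (AO) peak,
the isovolumetric-contraction (IC) trough and the rapid-ejection (RE)
bump; during the second heart sound (S2) the aortic-closing (AC) and
mitral-opening (MO) complex. The AO peak is a standard surrogate for the
ECG R peak, so a reliable AO detector turns a $5 accelerometer into a
beat-by-beat heart-rate monitor.

Two things make this hard. The waveform morphology varies with subject,
posture and sensor placement, so fixed amplitude thresholds do not
transfer; and the S2 complex looks enough like S1 to produce spurious
detections. `vcgbeat` implements a windowed-autocorrelation architecture
that first estimates an *averaged* heart rate robustly, then uses it as a
prior to pick out individual AO beats, exploiting the fact that SCG and
GCG fail differently: the S2 complex is markedly weaker on the gyroscope
axis, so simultaneity across the two axes filters S2-induced errors.

## Averaged heart rate

Processing emulates a real-time monitor: a rolling buffer of the most
recent 10 s is analysed once per second (`buffer_span`, `step`). Each
buffered channel is

1. resampled to a uniform 200 Hz grid by shape-preserving pchip
   interpolation (`resample_uniform`) — acquisition timestamps jitter, and
   a non-overshooting interpolant will not invent extrema;
2. high-pass filtered at 0.4 Hz by an ideal ("brick-wall") filter
   realised in the frequency domain over the buffer
   (`highpass_brickwall`), removing baseline wander and respiration-locked
   drift;
3. passed through **VarWin** (`varwin_hr`), an irreversible transfer
   function that, at every sample, measures the amplitude range within a
   centred ~250 ms window and gates it to zero unless the window interior
   contains both a strict local maximum and a strict local minimum. A peak
   in the output therefore marks a genuine oscillation — the S1 complex —
   while trends and one-sided excursions map to zero. The operator is
   scale-covariant and offset-invariant, which is what makes it transfer
   across subjects without amplitude calibration.

The enhanced waveform is then autocorrelated (`hr_from_window`) over
analysis windows of n = 2..10 s, each processed independently so that
short windows track recent changes while long windows stabilise the
estimate. The beat-to-beat (BTB) interval is read off the autocorrelation
as the shortest candidate lag whose integer multiples (±5%) are also
peaks — the *spacing of the harmonic train*, not the tallest peak, judges
the period, which resists half- and double-rate errors. Candidate peaks
must reach 0.3 of the zero-lag value (`prominence_floor`), and lags beyond
half the window length are not searched because the unbiased estimator is
too noisy there; a 2 s window therefore legitimately abstains at 40 bpm
and the remaining windows carry the estimate. Per-axis estimates are fused
by a weighted mean with weights 1/n (`fuse_windows`).

The SCG and GCG rates are consolidated (`consolidate_axes`): agreement
within 10 bpm is a cross-verified measurement and the two are averaged;
on disagreement the previous measurement — the last known rate, trusted
because consecutive 1 s refreshes of a quasi-periodic rhythm change
little — arbitrates, the closer axis winning (SCG on ties and before any
previous rate exists, reflecting its empirically higher single-axis
accuracy). The feedback reference initialises at the first cross-verified
agreement.

## Beat identification

The beat stage (`varwin_beat`, `detect_ao_candidates`) modifies VarWin in
two ways. The variation window becomes strictly forward-looking, `[i, i +
span]`, so enhancement rises *ahead* of each oscillation complex; and
output directly after a *deep* local minimum is suppressed, which removes
the RE bump that rides on the recovery from the IC trough and blanks the
lead-in of the trailing AC–MO complex. Two numerical choices matter here:

* **Deep minima only.** Broadband noise scatters three-point minima every
  few samples; a literal "after any local minimum" rule would blank the
  entire record. A minimum triggers suppression only if its value lies in
  the bottom 30% of the signal's amplitude range (`min_depth_frac`), a
  relative criterion that preserves scale covariance.
* **Suppression span.** The span defaults to the full VarWin span
  (250 ms), which blanks the AC lead-in completely at resting rates. At
  high rates a fixed 250 ms would swallow the next beat's own lead-in, so
  the pipeline shortens it to `suppress_frac` (0.3) of the prevailing BTB
  interval — the averaged HR is already available when the beat stage
  runs.

Local maxima of the enhanced waveform are admitted greedily in descending
amplitude under a minimum spacing of 75% of the average BTB interval
implied by the measured heart rate (`min_frac`), so the rate estimate acts
as a spacing prior that rejects S2 peaks. Because the forward-looking
window peaks before the AO point itself — and suppression truncates that
plateau differently on aZ and −gX — each admitted candidate's timestamp is
refined to the maximum of the underlying high-passed waveform within the
forward span it scanned: the AO fiducial peak proper. This pins both axes
to the same physical landmark, which the 25 ms cross-verification then
compares meaningfully. (GCG is processed as −gX, where the beat complex
points the same way as on aZ.)

Candidates from the nine analysis windows are pooled and single-linkage
clustered at 100 ms (`consolidate_candidates`); cluster centroids become
per-buffer SCG and GCG beat lists. Cross-verification (`cross_verify`)
retains only SCG timestamps with a GCG peak within 25 ms — the gyroscope
vetoes but never injects, and SCG timing stays authoritative. Finally,
per-buffer beats are merged across the overlapping buffers, and retained
beats must fit the BTB interval indicated by the HR measurement in their
timeframe, clusters supported by more buffers winning conflicts. Inverse
intervals of the final beat list give the instantaneous heart rate.

## ECG reference

`pan_tompkins` implements the canonical QRS detector used as the timing
reference: 5–15 Hz band-pass (a zero-phase second-order Butterworth, so no
group-delay bookkeeping), five-point derivative, squaring, 150 ms
moving-window integration, dual adaptive thresholds with a 200 ms
refractory period, T-wave slope discrimination, and 1.66×RR search-back.
The integration lobe of one QRS carries several ripple maxima, so
candidate fiducials are first thinned to the tallest peak per 200 ms
neighbourhood; accepted detections are refined to the raw-signal maximum
within ±50 ms.

## Evaluation harness

`match_beats` scores detections against reference peaks by one-to-one
matching within 250 ms (`ref_match_tol`). The assignment is a
maximum-cardinality matching (scan detections in order, claim the earliest
unclaimed reference in range — optimal for tolerance windows on a line),
so TP + FN always equals the reference count; TPR = TP/(TP+FN) and
PPV = TP/(TP+FP) follow. Instantaneous-rate agreement pairs inverse AO–AO
intervals with the matching inverse R–R intervals, dropping pairs broken
by a missed or spurious beat; `agreement` reports the squared Pearson
correlation and Bland–Altman 95% limits of agreement (mean difference
± 1.96 sample standard deviations). Averaged-HR agreement holds the
ECG-derived instantaneous rate to each refresh instant by previous-value
hold (`reference_hr_series`) — the alignment a 1 Hz display would show.

## Synthetic recordings

No public corpus of simultaneous ECG + SCG + GCG exists, so the package
generates its own ground-truth-annotated recordings (`sim_config`,
`simulate_recording`). The generator emulates the statistical structure
the algorithm relies on:

* **Rhythm.** RR intervals follow
  `RR = baseRR(t) · (1 + hrv_sd·ε) · (1 + resp_mod·sin(2π·resp_rate·t))`
  with Gaussian `ε`; `baseRR` is constant (rest) or an exponential
  recovery profile (start → end bpm with time constant τ). Defaults:
  3% HRV, 3% respiratory modulation at 0.25 Hz.
* **Morphology.** Channels are sums of per-beat Gaussian wavelet packets.
  ECG carries PQRST with the T offset scaling as √RR. The AO point trails
  R by a fixed 0.10 s pre-ejection period; IC trails AO by 0.1·√RR s; the
  AC point trails AO by a systolic interval that shortens with rate
  (0.446 − 0.0021·HR s, a standard systolic-time-interval regression —
  ≈0.32 s at 60 bpm, ≈0.17 s at 132 bpm; a fixed offset would collide with
  the next beat at high rates). S2 amplitude is 0.5× S1 on aZ but 0.2× on
  gX — the crosstalk asymmetry the fusion logic exploits, and itself
  configurable to stress-test AC rejection.
* **Nuisance structure.** Baseline wander at 0.08 Hz and the respiration
  rate (both below the 0.4 Hz cutoff), white noise at a configurable SNR
  (default 15 dB), and Gaussian timestamp jitter (0.4 ms) on a nominal
  250 Hz grid.

What the simulator does **not** model: motion artifacts beyond stationary
supine recording, inter-subject morphology variation, sensor misplacement,
and electromechanical delay variability (the pre-ejection period is
fixed). Tests passing on these recordings demonstrate that the
implementation realises the intended algorithm under its stated
assumptions — not that the algorithm attains the same accuracy on human
data, where waveform variability dominates.

## Numerical and design choices

* **Brick-wall filtering** zeroes DFT bins below 0.4 Hz per buffer. The
  DFT treats the buffer as circular, and slow wander makes the
  first-to-last-sample jump large, ringing across the buffer edges; the
  line through the window endpoints (bridge detrending, itself sub-cutoff
  trend content) is therefore subtracted first. The filter is exactly
  idempotent up to this detrending (measured RMS change on refiltering
  < 0.02%).
* **VarWin plateaus.** Runs of equal values are compressed; an extremum is
  the first sample of its run; the first and last runs are never extrema.
  For candidate *detection* a leading plateau that the signal falls away
  from also counts as a peak — a beat whose enhancement is already maximal
  at the buffer's first sample would otherwise be invisible (it has no
  three-point maximum), which matters exactly once, in the first buffer.
* **Fast path = naive path, bit for bit.** Rolling window extrema use the
  van Herk/Gil-Werman two-scan algorithm (comparisons only, no
  arithmetic), so the optimised VarWin equals an O(n·w) sliding-window
  scan exactly; the test suite asserts `identical()` on seeded noise.
* **Tie-breaks.** Equidistant axis disagreement resolves to SCG;
  equal-amplitude candidate peaks admit the earlier timestamp; matching
  ties claim the earlier reference.
* **Degenerate inputs.** All-zero enhanced windows, empty candidate lists,
  missing channels and absent heart-rate priors all degrade to absent
  results rather than errors; a recording without gX runs SCG-only
  (strict mode yields no cross-verified beats unless `permissive_gcg` is
  set, since the verification rule presumes both channels).
* **Problem sizes.** The test suite exercises 60 s recordings at
  40/60/100/132 bpm across ten seeds for parameter recovery, and the
  acceptance script uses 60 s batteries plus two 120 s rest/recovery
  recordings for the agreement statistics; these sizes give a few
  thousand evaluated beats while keeping a full run in minutes.

## Known limitations

* The first beat of a recording is frequently missed: its VarWin lead-in
  precedes the first sample, and no later buffer revisits it. Similarly,
  no measurements are emitted during the initial 10 s warm-up (beats
  inside the first buffer are still detected when it completes).
* Averaged-HR r² against ECG is attenuated on recordings with little
  heart-rate variance (correlation is variance-normalised); the
  instantaneous measure is the more informative statistic there.
* At rates above ~150 bpm the S2 complex of one beat and the S1 lead-in of
  the next overlap within the 250 ms VarWin span and detection degrades;
  the physiological bounds default to 30–200 bpm but accuracy was
  characterised at 36–140 bpm.
* Block (per-buffer) brick-wall filtering is non-causal within its buffer;
  the package replays recordings offline and makes no latency claims.
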