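---
title: "Methods: slow circulatory oscillations from raw ECG and blood pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slow circulatory oscillations from raw ECG and blood pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(circwave)
```

## The problem

Continuous arterial blood pressure and ECG recordings carry slow
oscillations — periods of tens of seconds to tens of minutes — that reflect
autonomic and vascular regulation.  `circwave` implements a complete chain
for studying them in perioperative recordings:

1. reduce each raw 400 Hz channel to beat-to-beat variables: systolic blood
   pressure (SBP, the per-cycle maximum of the pressure wave), heart rate
   (HR = 60/RR, with RR the interval between consecutive R-peaks), and
   R-wave amplitude (the per-beat ECG maximum, which varies with ventricular
   preload — the Brody effect — and therefore belongs alongside SBP and HR);
2. interpolate these irregular event series to uniform 10 Hz series (iSBP,
   iHR, iAmp);
3. characterise their frequency content over periods of 10–1,024 s with the
   Morlet continuous wavelet transform, summarised as average wavelet power
   spectra, and locate shared oscillations of two variables with
   cross-wavelet spectra and a surrogate significance test;
4. decompose each series into three band-limited Loess components and
   quantify lead/lag relations between variables with the cross-correlation
   function (CCF).

Because clinical recordings of this kind are rarely shareable, the package
ships a synthetic generator (`sim_config()`, `generate_recording()`) that
renders raw ECG/BP (optionally PPG and laser-Doppler flow) channels from a
known beat train with known modulations, and returns a ground-truth ledger.
Every downstream stage is validated by recovery against that ledger.

## The synthetic generator

**Beat placement.** The instantaneous heart rate is the configured baseline
plus all HR-targeted sinusoidal modulations (including respiratory sinus
arrhythmia and, optionally, a stochastic background term).  Its time
integral is accumulated on the raw sample grid and a beat fires at each
whole cycle (an integrate-and-fire rule).  Each RR interval therefore
integrates the instantaneous rate to exactly one beat, so the downstream
definition HR = 60/RR recovers the injected modulation by construction.
Only beats whose QRS template fits inside the recording are kept.

**Waveform templates.** Only per-beat maxima matter downstream, so the
templates are deliberately simple: a Gaussian QRS of width 10 ms whose peak
equals the per-beat R amplitude, and an arterial pulse with a fast systolic
upstroke peaking 150 ms after the R-peak (a gamma-like rise–decay) scaled
between the diastolic baseline and the per-beat systolic value.  Per-beat
SBP is evaluated at the systolic instant rather than the R-peak time — that
is where the value becomes observable in the pressure channel, and it keeps
the extracted iSBP series phase-aligned with the generator's truth.

**Modulations and lags.** A `modulation_spec()` applies one sinusoid to any
subset of HR, SBP, R-amplitude and PPG-amplitude with a per-target lead:
target values are `depth * sin(2*pi*(t + lead)/period)`, so a target with a
larger lead oscillates earlier.  The worked emulation used throughout the
tests (`sim_preset("slow25")`) injects a 25-s oscillation with HR leading
SBP by 3.5 s and SBP leading R-amplitude by 8.2 s, depths of 5 bpm, 5 mmHg
and 10%.  This preset emulates exactly one oscillatory component:
respiratory modulation is switched off in it, because the aliasing of
respiration into the ~1 Hz beat-domain sampling biases CCF lag estimates by
a few tenths of a second — a property of beat-to-beat sampling worth knowing
about, but not part of the condition under test.

**Respiration.** Respiration is modelled as a fixed-period amplitude
modulation of the beat-to-beat values.  Spontaneous breathing (4 s period)
modulates HR (2 bpm), SBP (2 mmHg) and amplitude (3%).  Mechanical
ventilation (`resp_spec("mechanical")`, 5 s period) suppresses the HR term
and strongly modulates SBP (8 mmHg) and the amplitude channels (25%) — the
regime in which respiration dominates the amplitude variables.

**Stochastic background.** Real circulatory series ride on a continuum of
slow fluctuations.  An optional AR(1) (Ornstein–Uhlenbeck) background
(`background = list(hr_sd, sbp_sd, amp_sd, tau)`) adds that continuum; it is
off by default so that the default configuration contains no slow structure
beyond what was asked for, and on (2 bpm / 2 mmHg / 2%, tau = 30 s) in the
ventilated preset, where the scientific claim being emulated — "no distinct
amplitude peak during mechanical ventilation" — is only meaningful against a
realistic background.

**Noise.** White measurement noise defaults to 1% of each channel's
amplitude scale, keeping peak detection trivially correct in clean tests
while leaving room for robustness tests.  Transient noise episodes
(`inject_noise_episodes()`) superimpose high-amplitude white-noise bursts —
default 3x the channel's pulse scale, emulating movement or cable artifacts —
inside stated intervals of the ECG and BP channels; the `"artifact"` preset
places three 5-s episodes 800 s apart.  Episode amplitude and duration are
free choices of this package (no quantitative description of such artifacts
was available); the defaults were set so that a typical episode corrupts
beat detection locally, which is the mechanism by which periodic artifacts
imprint a long-period signature on the extracted series.

**What the generator does not emulate:** arrhythmia and ectopy (the intended
regime is sinus rhythm), realistic multi-lead ECG morphology, pulse-wave
propagation and reflection, drug effects, and nonstationary changes of the
modulation parameters within a recording.  Passing recovery tests on these
synthetic recordings therefore shows the pipeline's internal consistency,
not robustness to every feature of bedside data.

## Beat extraction

* **Baseline wander** is removed by subtracting a Savitzky–Golay smooth
  (window 1.0 s, order 3) of the ECG.  The long, low-order window follows
  the slow baseline but not the 10-ms QRS, so subtraction leaves beat
  morphology intact.
* **R-peaks**: local maxima above a threshold set per 10-s chunk at 40% of
  the chunk's 99.5th percentile, with an absolute noise floor of 10 robust
  scale units (`mad`) — pure noise yields no detections — and a 250-ms
  refractory period that keeps the largest candidate per beat.  Peaks are
  refined by a 5-point local parabola, which interpolates the sub-sample
  apex and averages sampling noise at the maximum; without this refinement
  the raw one-sample maximum carries a positive noise bias of the same
  order as a 1% measurement noise.
* **Systolic peaks** use the same detector on the pressure signal centred by
  a 1-s running median; the reported value is the raw pressure at the
  refined peak.  The noise floor is lower (1 robust scale unit) because the
  centred pulse waveform itself, not noise, dominates the robust scale.
* **HR** is 60/RR.  Each HR value is stamped at the *midpoint* of its RR
  interval (`compute_hr(..., at = "midpoint")`): HR estimates the average
  rate over the interval, and midpoint stamping makes the iHR series
  phase-accurate.  Stamping at the interval start — an equally common
  convention, kept as an option — advances the whole series by RR/2
  (≈0.4 s at 70 bpm), a systematic bias larger than the 0.1-s lag grid.
* **Outliers**: a beat is dropped when it deviates from its ±30-beat window
  median by more than 4 window MADs; the screen repeats until nothing is
  flagged, making it idempotent.  Windows with zero MAD flag nothing.
  Removed beats are deleted before interpolation, not interpolated over.
* **Interpolation**: a natural cubic spline through the surviving events,
  evaluated on a 10 Hz grid aligned to whole multiples of 0.1 s and spanning
  first to last event (no extrapolation).  Clock-aligned grids mean series
  from different channels share sample times; `align_series()` trims them to
  the common span for pairwise analyses.
* **PPG** follows the identical path as the pressure channel; **LDF** is
  low-pass filtered (4th-order Butterworth, 4 Hz cutoff, applied
  forward-backward for zero phase) and decimated to 10 Hz.

## Wavelet analysis

The Morlet wavelet (central frequency `omega0 = 6`, the conventional
compromise between time and frequency resolution) is applied on a log2
period grid from 10 to 1,024 s with 12 voices per octave.  The transform is
computed by FFT with zero-padding to the next power of two; each series is
mean-removed and variance-scaled first so that spectra of variables with
different units are comparable (`standardize = FALSE` disables the variance
scaling, restoring the quadratic amplitude dependence of power).  The cone
of influence marks, per time point, the longest period free of edge
effects (one wavelet e-folding time from the boundary); `average_power()`
excludes those cells by default.

**Peak reading.** A "distinct oscillatory peak" is defined statistically:
a local maximum of the average spectrum that exceeds the local continuum
(a running median over ±1.5 octaves) times the upper 99% quantile of a
chi-squared fluctuation model whose degrees of freedom,
`nu = 2*sqrt(1 + (n*dt/(2.32*s))^2)`, count the independent wavelet samples
entering the time average at scale `s`.  Periods pooling fewer than
`min_dof = 10` degrees of freedom are never reported: on a 30-min record
that excludes periods beyond roughly 300 s, where a single background lump
or a few transient noise events are indistinguishable from a genuine
oscillation — exactly the failure mode in which noise spaced ~800 s apart
is read as an 800-s rhythm.  Long-period structure can still be *examined*
(e.g. via band power with `exclude_coi = FALSE`); it is only the automated
"distinct peak" claim that is restricted to scales the record can support.

**Cross-wavelet spectra.** `cross_wavelet()` forms `W_a * Conj(W_b)`; the
magnitude localises shared oscillations, the argument is the phase
difference, with positive phase meaning the first series leads.  (Note the
deliberate difference from the CCF sign convention below.)  Significance is
assessed against simulated surrogate pairs — independent white noise by
default, AR(1) matched to the data's lag-1 autocorrelation with
`null = "red"` — using the per-period upper 5% quantile of cross power,
pooled over time (edges included) and thinned for memory.  With 100
surrogates and ~18,000 time points the pooled quantile is stable; the null
depends on series length only weakly, so `cw_null()` results are reusable
across same-length series (the pipeline caches them, accepting lengths
within 2%).  `phase_to_lag()` converts a phase difference at one period
into seconds; `xwt_band_lag()` summarises a spectrum's lag at a period by a
power-weighted circular mean over significant, edge-free cells.

## Decomposition and lags

**Loess decomposition.** Three passes of degree-2 tricube Loess with
strictly decreasing spans; each pass smooths the current residual and is
subtracted before the next.  Components #1–#3 are the smooths (slowest
first) and components plus residual reconstruct the input exactly — a
telescoping identity that holds by construction and is asserted, not
clipped, in the tests.  A degree-2 local smoother transmits an oscillation
essentially unattenuated only while its window is at most about half the
oscillation's period; the default spans (0.3, 0.06, 0.012 of an 1,800-s
series, i.e. windows of 540, 108 and 21.6 s) were set by that rule so the
slow/mid/fast bands land in components #1/#2/#3.  Wider spans (e.g. 0.5,
0.1, 0.02) attenuate the slowest component and push its remainder into the
next pass, degrading separation markedly.

**Cross-correlation.** Pearson correlation of overlapping segments at every
displacement on the native 0.1-s grid, each overlap normalised by its own
mean and variance; degenerate overlaps give `NA` rather than a fabricated
value.  Positive `lag_at_max` means the first series lags the second, so
`cross_correlation(iSBP, iHR)` on the 25-s emulation reports +3.5 s (iHR
leads).  Within one oscillatory band, lags are only identifiable modulo the
period; the pipeline therefore bounds the CCF search at half the dominant
peak period by default.  Pairwise lags from a common band compose
additively (`compose_lags()`): 8.2 s plus 3.5 s places the amplitude series
11.7 s behind HR.  Whether the CCF is better computed on the raw series or
on a band-limited Loess component is situation-dependent; both are
supported and the pipeline default is the raw series.

## The pipeline

`run_pipeline()` maps the chain over labelled 30-min situations
(preoperative A; postoperative ventilated B; post-extubation C; next
morning D), producing per-variable average spectra and peaks, cross-wavelet
and CCF results for the pairs (iAmp, iSBP) and (iSBP, iHR), and a
processing log (beats detected, outliers removed, seeds).  A failure in one
situation is recorded and does not stop the others.
`compare_situations()` tabulates, for each baseline peak, whether a peak of
the same variable within one voice step exists in each other situation —
an explicit, configurable proxy for the visual judgement that an
oscillation was "lost" after surgery.  Configurations can be written in
YAML (`read_pipeline_config()`); recordings, spectra, masks and CCF curves
round-trip through plain delimited text (`write_recording()`,
`write_report()`).

## Numerical choices and problem sizes

Tests and the acceptance script run the actual study geometry — 30-min
recordings at 400 Hz, 10 Hz series of ~18,000 samples, 81 wavelet scales —
with surrogate counts of 50–100 and, in unit tests, shorter 300–900 s
segments where the property under test does not need the full record.
Determinism is end-to-end: every stochastic component draws from the seed
in its configuration, and identical seeds give bit-identical recordings,
ledgers and reports.

Known limitations worth restating: beat-domain sampling aliases respiration
into the slow band and can bias lag estimates when respiratory and slow
components coexist; long-period (>~300 s) features of a 30-min record are
reported only as band power, never as detected peaks; the CCF assumes one
dominant shared band within the search window; and the generator's
simplified morphology means detector performance on real, artifact-laden
signals must be established separately.
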