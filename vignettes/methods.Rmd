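---
title: "Methods: short-segment autoregulation and neurovascular coupling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: short-segment autoregulation and neurovascular coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadenza)
```

## The model

Dynamic cerebral autoregulation (dCA) is treated as a linear,
time-invariant system from mean arterial pressure (MAP) to middle
cerebral artery blood velocity (MCAv). Its efficiency is summarised by
the Autoregulation Index (ARI), a 0–9 grade defined through the Tiecks
second-order model: for a normalized pressure deviation

$$dP_n = \frac{\mathrm{MAP}_n - \mathrm{MAP}_{base}}{\mathrm{MAP}_{base} - \mathrm{CrCP}},$$

the model states evolve as

$$x_{2,n} = x_{2,n-1} + \frac{x_{1,n-1} - 2 D\, x_{2,n-1}}{f\,T},\qquad
  x_{1,n} = x_{1,n-1} + \frac{dP_n - x_{2,n-1}}{f\,T},$$

and the velocity is $V_n = V_0\,(1 + dP_n - K\,x_{2,n})$. One
$(T, D, K)$ triplet per grade is shipped in
`inst/extdata/tiecks_parameters.csv` (time constant $T$ in seconds,
damping $D$, autoregulatory gain $K \in [0,1]$; grade 0 has $K = 0$,
absent autoregulation). The package treats these as external constants
and validates them on load; tests assert only structural properties
(completeness, $K_0 = 0$, monotone $K$, the closed-form step-response
fixed point $V_{ss}/V_0 = 1 + d\,(1-K)$), never re-derived numbers.

Estimation inverts this model spectrally. Welch transfer function
analysis (TFA) of the normalized pressure (input) and fractional
velocity change (output) yields gain, phase and magnitude-squared
coherence; the impulse response is the inverse FFT of the complex
frequency response, its running integral is the velocity response to a
sustained unit pressure step, and the ARI is the grade whose template
step response fits best over a 0–10 s window.

Assumptions worth keeping in view: linearity and stationarity over the
analysed record; velocity as a flow surrogate (constant vessel
diameter); and additivity of the task-evoked neurovascular coupling
(NVC) response on top of the pressure-driven component. Task recordings
violate stationarity by design — that is precisely why the short-segment
settings and the acceptance gates below exist.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Task-recording segment length | 256 samples (51.2 s) | – | 3-min records cannot support conventional segments; 6 half-overlapped windows from 180 s |
| Baseline segment length | 512 samples (102.4 s) | – | conventional setting for 5-min rest recordings |
| Taper | Hann (raised cosine) | – | the standard "cosine window" of the TFA literature |
| Overlap | 50% | – | standard Welch practice |
| Coherence band | 0.15–0.25 Hz | Hz | band where the pressure-velocity relation is reliably coherent; gate for accepting ARI |
| Coherence limit alpha | 0.05 | – | 95% confidence limit |
| NMSE acceptance limit | 0.3 | – | published critical limit for the template fit |
| Template fit window | 0–10 s | s | covers the autoregulatory recovery; configurable |
| CrCP | 12 | mmHg | critical closing pressure of the original model convention; the source protocol never states it |
| Spike width limit | 100 | ms | only narrower artefacts are interpolated |
| Low-pass | 20 Hz, order 8, zero-phase | – | noise removal far above the <0.5 Hz band of interest |
| Lag search (CCF) | ±5 | s | NVC latency range; configurable |
| VR windows | 30 s pre / 30 s post onset | s | matches the normalization window length |
| Classifier thresholds | CCF₉₀ = 0.53, VR₉₀ = 2.59 | – | published 90% null-distribution limits; recalibration provided |

## Numerical choices

**NMSE normalization.** The template fit error is
$\mathrm{NMSE} = \overline{(s - t)^2} / \overline{s^2}$ over the fit
window, i.e. normalized by the *mean square* of the measured step
response rather than its variance. The denominator does not influence
which template wins; it only scales the 0.3 acceptance gate. A variance
denominator degenerates for flat responses — the ARI-0 step response is
essentially constant over the window, so even a perfect fit would be
rejected — while the mean-square denominator is scale-free, stable for
every grade, and still rejects step responses uncorrelated with the
templates (their NMSE concentrates near or above 1).

**Euler oversampling.** At 5 samples/s the smallest template time
constants put the explicit Euler recursion near its stability margin
($f\,T = 3.25$ for grade 9). When $f\,T < 5$ the recursion runs at an
internally oversampled rate (sample-and-hold input, decimated output);
$f\,T \le 1$ after oversampling is an error.

**Spectral edges.** The DC bin of the frequency response is not
estimable from detrended segments and is set to the nearest estimated
low-frequency gain with zero phase; the Nyquist bin is forced real;
Hermitian symmetry is enforced before the inverse FFT so the impulse
response is real by construction.

**Per-segment detrending.** Segment means are removed before tapering;
otherwise constant offsets dominate the input auto-spectrum at DC.
Power spectra are window-power normalized (unbiased for white noise).

**Zero-phase filtering.** Butterworth filters are designed at the stated
order and applied forward-backward (the magnitude response is squared).
Odd-reflection padding is sized from the slowest filter pole so start-up
transients decay below 1e-9 before the data proper.

**Spike detection.** Artefacts are runs of samples deviating from a
running-median baseline (window four times the maximum spike width) by
more than $k = 8$ robust standard deviations. For smooth, heavily
oversampled signals the residual is exactly zero at most samples and
its MAD degenerates, so the scale is floored at half the 80th percentile
of the absolute residual — still robust to ~20% artefact contamination,
while clearing the residual shoulder of pulsatile waveforms. Spikes
touching the record edge defeat a running median and are instead
detected from outsized first differences and held at the nearest good
value. More than 10% flagged samples rejects the signal.

**Coherence confidence limit.** The closed form
$1 - \alpha^{1/(L-1)}$ holds for $L$ *non-overlapping* windows;
overlapping windows invalidate it, so the default limit is calibrated by
seeded Monte-Carlo surrogates: independent band-limited (0.02–0.45 Hz)
Gaussian noise pairs of the actual record length pushed through the
identical Welch settings, with the $(1-\alpha)$ quantile of the
band-mean coherence as the limit. Results are cached per parameter set;
the analytic form remains available for cross-checks.

## Design decisions on genuinely open points

* **Which data feed the task-segment TFA.** Sixty seconds of task data
  alone cannot support more than one 51.2 s window, so task recordings
  are analysed whole (rest + task + recovery, 6 windows) with the
  256-sample setting, and dedicated 5-min baseline recordings with the
  512-sample setting. Group comparisons therefore contrast
  baseline-recording ARI with task-recording ARI.
* **Full-spectrum inversion.** Gain and phase are inverted over the full
  estimated spectrum (matching "inverse FFT of the gain and phase")
  rather than band-averaged first.
* **Step polarity and scaling.** Templates are generated for a unit
  positive pressure step; measured responses come from TFA of the
  normalized pressure and fractional velocity, so template and
  measurement share units and polarity and no rescaling is needed.
* **Leave-one-out coherent averages.** The cross-correlation template
  for subject *i* excludes subject *i*, avoiding self-correlation
  inflation; the grand average is available behind a flag, and a fixed
  external template can be supplied.
* **ICC variant.** "Model (1,1) for absolute agreement" is implemented
  as the Shrout–Fleiss one-way random-effects single-measure ICC, with
  the two-way mixed ICC(3,1) available via `model = "twoway"` because
  the two conventions are often conflated; the p-value is the one-way
  F-test of between- over within-subject mean squares.
* **Baseline-only normalization.** Recordings without a task annotation
  normalize MCAv against their first 30 s.
* **R-R gating.** Besides the absolute physiologic gate (0.3–2.0 s),
  intervals beyond 1.66× (or below 0.5×) the median R-R are flagged:
  a missed beat produces a doubled interval that is physiologically
  legal but rhythmically impossible, and flags feed the programmatic
  manual-correction hook.

## What the synthetic generator emulates — and what it does not

The generator produces the study conditions: 3-min task recordings
(1 min rest / task / recovery) and 5-min baselines; MAP around
89 mmHg with a ~0.1 Hz Mayer wave (2 mmHg), band-limited 0.02–0.45 Hz
1/f variability (3 mmHg SD), a small broadband floor (0.3 mmHg SD), and
a smooth task-evoked rise (4 mmHg); MCAv generated *through the Tiecks
forward model* at a known ARI — grade 6 at rest, optionally depressed
(default grade 4) during the task minute, crossfaded over 2 s; a
task-evoked NVC rise for responders (default 6.9%, 3 s ramp to plateau,
5 s decay); HR 71 → +6 bpm and EtCO₂ 36.5 → −0.6 mmHg task profiles;
~85% responders. The raw mode adds a zero-mean intra-beat pressure pulse
gated on beat times integrated from the HR trajectory, Gaussian-QRS ECG,
pulsatile velocity, a plateau-train capnogram, and optional injected
spikes. The broadband MAP floor is deliberate: a strictly band-limited
input leaves the high-frequency bins of the estimated transfer function
undefined (0/0) and corrupts the impulse response.

Not emulated: baroreflex and respiratory–cardiac coupling, nonlinear or
time-varying autoregulation, CO₂ reactivity feedback on MCAv,
probe/measurement drift, and real artefact morphology beyond rectangular
spikes and dropouts. Passing tests therefore demonstrate correctness of
the estimators under the stated generative model — linear autoregulation
plus additive noise — not robustness to every failure mode of real
transcranial Doppler data.

The task-ARI switch is a labelling device, not mechanism: the generator
tests whether the pipeline *resolves* a between-segment difference in
true ARI; it does not model how neural activation produces it.

## Problem sizes used in validation

The bundled tests and `scripts/acceptance.R` use: all ten grades
noise-free for exact recovery; 50 seeds × grades 2–8 at 10%-of-signal-SD
velocity noise for the median-error bound; 2000 surrogate pairs for the
coherence-limit calibration and 2000 fresh pairs for its exceedance
check; 2000 null curves for classifier recalibration and 2000 fresh
nulls for false-positive rates; 2000 replicates for the variance-ratio
F-distribution check; and a 16-subject, two-visit cohort for the
end-to-end task-activation contrast. These sizes keep the full
validation within a few minutes on one CPU while leaving Monte-Carlo
error well inside the asserted tolerances.

## Known limitations

* Multivariate TFA (e.g. EtCO₂-corrected) and wavelet/time-varying
  variants are out of scope.
* The ARI is reported as an integer grade; no continuous interpolation
  between templates.
* Acceptance-gated estimates are excluded from group means but retained
  with flags; heavily gated conditions can leave few pairs for ICC/CV.
* The NMSE gate rejects recordings whose task-evoked NVC transient
  dominates the pressure-velocity relation — a real phenomenon of
  short-segment task TFA, visible on synthetic responders with large
  NVC amplitudes.
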