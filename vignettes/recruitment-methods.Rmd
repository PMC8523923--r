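---
title: "Quantifying auditory-nerve response recruitment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying auditory-nerve response recruitment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recruitpipe)
```

## The problem

Recruitment is the combination of an elevated hearing threshold with
abnormally fast growth of response with sound level, such that responses to
loud sounds end up within the normal range.  In animal work it is measured
physiologically ("response recruitment") from auditory-nerve potentials
recorded at the round window.  Two measures cover the frequency range:

* **ANOW** (auditory nerve overlapped waveform) for low frequencies
  (≤ 1 kHz), where the compound action potential to a tone burst is not
  separable but phase-locked firing is strong.  Tone bursts are presented
  in alternating polarity; averaging a +/− pair cancels the cochlear
  microphonic (which follows the stimulus and inverts with it) and
  superimposes the neural volleys from the two phases, moving the neural
  signature to **twice** the stimulus frequency.  The second-harmonic
  component is the neural measure.
* **CAP** N1–P1 peak-to-peak amplitude for mid and high frequencies, from
  the polarity-balanced grand average.

`recruitpipe` implements the full chain from epoch matrices to the
recruitment statistics, plus a seeded synthetic generator so everything is
testable without animal recordings.

## Signal model and estimators

### Second-harmonic estimation

Each overlapped waveform $y(t)$ is fit by weighted least squares with the
two-parameter model

$$ y(t) \approx a\,\cos(2\pi\,2f\,t) + b\,(-\sin(2\pi\,2f\,t)), $$

with time origin at stimulus onset and per-sample weights in $\{0, 1\}$
(0 at artifact samples).  Zero-weighted samples drop out of the normal
equations, which removes short transients without cutting the waveform and
without spectral splatter from edge discontinuities.  With uniform weights
over an integer number of cycles the estimate equals the scaled DFT bin
($a = \tfrac{2}{N}\mathrm{Re}\,Y_k$, $b = \tfrac{2}{N}\mathrm{Im}\,Y_k$, R's
FFT sign convention), a property the test suite asserts to $10^{-10}$.

Per-pair coefficients are aggregated as a complex mean (the signal) with
the standard error of that mean as the noise floor, combined across axes
as $\sqrt{\mathrm{SEM}_{re}^2 + \mathrm{SEM}_{im}^2}$.  SEM-of-magnitude
conventions are avoided because magnitudes are biased at low SNR.
Electrode magnitudes are reported in dB re 1 µV using the RMS magnitude
(amplitude$/\sqrt2$); microphone components in dB SPL re 20 µPa using the
component amplitude.  Noise floors scale as $1/\sqrt{n}$ in the number of
pairs — 3 dB per doubling — which the acceptance suite verifies.

### Conditioning

Epochs are band-limited by linear-phase Kaiser-window FIR kernels
(600–1,600 Hz for the ANOW path, 150–1,500 Hz for CAP) and advanced by the
kernel group delay so filtered features stay aligned with the input time
axis; the half-kernel at each end is marked invalid.  `fir1` places its
−6 dB point at the cutoff, so the design widens the cutoffs by the Kaiser
transition half-width and then *measures* the realized response: passband
ripple beyond ±1 dB is an error (with a suggested tap count), while
achieved stopband attenuation is stored on the kernel and enforced only on
request.  A deep stopband one octave below a 150 Hz edge at 96 kHz needs
~3,000 taps — longer than a CAP epoch — so the default 1,025-tap CAP
kernel trades low-side attenuation for a usable group delay, and the
kernel object reports what it actually achieves.

Artifacts are flagged by a pooled Tukey fence: the absolute deviation of
every sample from a pointwise median waveform is pooled, and samples
beyond $Q_3 + 3\,\mathrm{IQR}$ are flagged (fence configurable).  One
refinement over the plain ensemble median: with alternating polarity the
ensemble median is near zero while every epoch deviates by the full
microphonic amplitude, which would blind the fence; the detector therefore
takes the median within each epoch's own polarity class by default, which
is stimulus-invariant and identical in distribution for noise-only data.
The ANOW path keeps flagged samples at weight 0 (information elsewhere in
the waveform is preserved); the CAP path removes the whole epoch *and its
polarity partner*, keeping the microphonic cancellation exact.  An epoch is
flagged whole when more than 10% of its samples are flagged (configurable
constant).

Because the synthetic artifacts are single-sample displacements, a long
FIR smears them across its main lobe, and masking only the original sample
cannot excise them after filtering.  The artifact-robustness analysis
therefore detects and fits on unfiltered epochs (`anow_response(kernel =
NULL)`) — appropriate whenever the noise background is already white or
band-limited, as the generator's is.  On real recordings with low-frequency
biological noise the band-pass is applied first and transients are flagged
in the filtered domain, where genuine artifacts are many samples long.

### CAP peaks

The grand average over retained epochs is searched for N1 (most negative
local extremum, default window 0.5–6 ms post onset) and P1 (most positive
local extremum within 5 ms after N1), with 3-point parabolic refinement of
latency and amplitude below sample resolution; exact ties resolve to the
earliest latency.  A flat or extremum-free window returns a *no response*
value rather than an error, and the quality flag drops when |N1| is below
3 pre-onset RMS (note that the most negative of ~500 noise samples sits
near 3.5σ by selection, so for noise-only traces a stricter bar is
appropriate).  The windows suit guinea-pig CAP morphology and are all
configurable.

### Otoacoustic emissions

The double-evoked residual `mean(probe) + mean(suppressor) − mean(both)`
is computed per repetition (retaining scatter for the SEM floor).  Any
response linear in its stimuli cancels identically; for a compressive
source the residual holds the emission component suppressed by the second
tone.  Components at the probe frequency or at $2f_1-f_2$ use the same
least-squares sinusoid estimator with uniform weights on the steady-state
portion of each frame.  For a weak cubic nonlinearity $y = x - cx^3$
driven by two tones the $2f_1-f_2$ component is exactly
$\tfrac34 c A_1^2 A_2$ and the suppressed-probe residual component is
$\tfrac32 c A_p A_s^2$; both closed forms anchor the tests.

### Growth functions and the recruitment slope

Per-level responses (ANOW dB re 1 µV RMS, or CAP peak-to-peak µV) with
their noise floors give per-level SNR.  The analysis then:

1. **Threshold** — lowest tested level whose SNR meets the 6 dB criterion
   at that level *and the next* (a run-of-2 rule; a single-level excursion
   is ignored).  Absence is a value, `NA`, and propagates — it never
   becomes a number downstream.
2. **Spline fit** — a natural cubic smoothing spline minimizing
   $$ p \sum_i w_i\,(y_i - g(L_i))^2 + (1-p)\int g''(t)^2\,dt $$
   with smoothing coefficient $p = 0.005$.  *Convention note:* $p \to 1$
   interpolates and $p \to 0$ tends to the weighted straight line; some
   software inverts this.  Weights are the SNR in dB floored at zero and
   exactly zero below 6 dB, so sub-criterion points are provably inert
   (asserted bit-for-bit in the tests).  The solver is the Reinsch scheme
   (solve a banded system for interior second derivatives); affine data
   are reproduced exactly for any $p$ and any positive weights because
   lines are in the penalty's null space.  The fit and its analytic
   derivative are evaluated on a 1-dB grid spanning the tested levels,
   with natural-spline linear extrapolation outside the weighted support.
3. **Median slope** — the recruitment metric: the median of the derivative
   over grid levels at and above threshold (midpoint convention for even
   counts).  Units: dB/dB for ANOW, µV/dB for CAP; kinds are never mixed.
4. **Statistics** — OLS of median slope on threshold across ears of one
   frequency, with the two-sided $t$ p-value for the slope and its
   t-based 95% CI; low-frequency aggregation averages slopes and
   thresholds over frequencies ≤ 1 kHz (cutoff 1,020 Hz so the 1,020 Hz
   stimulus, conventionally labelled 1 kHz, qualifies) and references
   threshold shifts to the control-cohort mean.

An independent check of the spline lives in the test helpers: the same
objective is discretized on a 0.25 dB grid and solved as a sparse
quadratic program; the two routes agree to better than $10^{-3}$ dB.  One
caveat worth knowing: with weights equal to SNR in dB (which here reach
the hundreds on synthetic series), the effective penalty per point
$(1-p)/(p\,w_i)$ is small and the fit tracks the data closely, so
pointwise errors approach the measurement noise; recovery contracts are
therefore stated in RMS over the interior of the grid rather than in
max-norm.

## The synthetic generator

The generator is first-class, tested code; it produces the inputs every
stage is validated against.

* **Epoch level** — tone bursts (default 33.3 ms, 92 repetitions for ANOW;
  13.9 ms, 1 ms ramps, 128 repetitions with an appended silence interval
  for CAP; 96 kHz) with raised-cosine ramps and a recorded onset sample.
  Each epoch sums a polarity-following microphonic, a polarity-invariant
  neural term at $2f$ (gated by the stimulus envelope; optionally a
  half-wave-rectified drive rescaled to the same $2f$ amplitude), i.i.d.
  Gaussian noise, and optional single-sample transients of ±`scale`·σ at
  uniformly random positions whose ground-truth locations are returned
  for detector validation.  Seeded generation is bit-reproducible.  ANOW
  rise/fall defaults to 5 ms — a compromise between onset splatter and
  steady-state duration that still leaves ≥ 20 cycles of $2f$ at 480 Hz.
* **Series level** — `gen_growth_series()` draws per-pair complex
  coefficients around the scenario's true amplitude and pushes them
  through `aggregate_response()`, so magnitudes, SEM floors and their
  $1/\sqrt{n}$ scaling are inherited from the estimator rather than
  re-modelled.  `noise_sigma` is interpreted at the generator's
  granularity: per-sample µV for epochs, per-pair coefficient SD per axis
  for series.
* **Cohort level** — control ears grow compressively (0.33 dB/dB above a
  20 dB SPL knee, reaching 20 dB re 1 µV amplitude at 80 dB SPL); hydropic
  ears draw a low-frequency threshold shift from N(22, 10) dB truncated to
  [2, 42] (endolymphatic-hydrops cohorts show low-frequency losses from a
  few dB to ~40 dB) and grow *linearly* from threshold so as to converge
  to the control amplitude at 80 dB SPL.  Convergence plus shift therefore
  *determine* the slope — a +20 dB shift implies ~0.55 dB/dB and large
  shifts approach 1 dB/dB — which is the generative form of recruitment.
  High frequencies receive no shift in either group (the cochlear base is
  spared), and the CAP growth template uses a fixed 70 dB dynamic span so
  threshold jitter translates the curve without steepening it: the
  negative control carries no built-in coupling.

What the generator does **not** emulate: realistic biological background
noise spectra (noise is white), neural adaptation and latency dispersion
within the burst, multi-source OAE fine structure, middle-ear and probe
acoustics, and level-dependent microphonic distortion.  Passing tests
therefore demonstrate the correctness of the estimators and statistics
under the stated statistical structure, not field performance on raw
animal recordings.

## Numerical choices and degenerate inputs

* Weighted LSQ requires ≥ 10 cycles of the analysis frequency under
  nonzero weight; less is an error naming the effective duration.
* SEM aggregation requires ≥ 2 coefficients; identical coefficients give a
  zero SEM, reported at a configurable dB floor (−40 dB re 1 µV).
* The quartile detector requires ≥ 4 epochs; identical epochs yield zero
  deviations, zero IQR, and no flags.
* Spline fitting requires ≥ 4 positively weighted levels; all-equal
  thresholds make the slope regression degenerate (an error), and fewer
  than 3 complete points refuse to regress.
* Exact ties in peak picking resolve to the earliest latency; parabolic
  refinement is skipped when the curvature denominator is zero.
* Levels are quantized at the tested 5 dB steps, so thresholds are too;
  this is visible as errors-in-variables attenuation in slope-vs-threshold
  regressions at small effect sizes.

## Problem sizes in the test suite

Deterministic seeds throughout.  The heavier simulations use 200 seeded
runs for the artifact-robustness comparison (92 epochs × ~3,600 samples
each), 200 simulated cohorts of 26 ears × 6 frequencies for the
recruitment contrast, 200 runs each for noise-floor scaling, spline
recovery and CAP picking accuracy, and 1,000 replicates for the regression
null calibration.  The full suite runs in a few minutes on one core.

## Known limitations

* The CAP artifact path removes whole epochs; no interpolation or robust
  re-weighting is attempted for partially corrupted CAP epochs.
* Phase-delay growth functions are supported as a measurement kind
  (weights inherited from the paired magnitude series via `snr_override`)
  but no phase-unwrapping heuristics beyond highest-level-down unwrapping
  are provided.
* The probe-microphone calibration enters only as an optional
  frequency-response correction applied to extracted components;
  calibration measurement itself is out of scope.
* The smoothing coefficient is treated as a fixed analysis constant, not
  re-estimated per ear; sensitivity to it is the user's to explore
  (`fit_growth_spline(smoothing = ...)`).
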