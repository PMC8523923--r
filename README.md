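# recruitpipe

Analysis of **auditory-nerve response recruitment** from round-window
electrophysiology: elevated thresholds with abnormally steep response
growth that converges to normal amplitudes at high sound levels, the
physiological counterpart of loudness recruitment in ears with reduced
cochlear amplification (e.g. endolymphatic hydrops).

The package is written for auditory physiologists who record epoch-resolved
evoked potentials and want a tested, reproducible pipeline from raw epoch
matrices to recruitment statistics:

* **ANOW** (auditory nerve overlapped waveform): averaging
  alternating-polarity tone-burst responses cancels the cochlear
  microphonic and moves the phase-locked neural signature to twice the
  stimulus frequency; a weighted least-squares fit
  `y(t) ≈ a·cos(2π·2f·t) + b·(−sin(2π·2f·t))` with 0/1 sample weights
  estimates that second harmonic per pair, and the complex mean ± SEM of
  the per-pair coefficients gives the response and its noise floor.
* **CAP**: polarity-balanced grand averages with automated N1/P1 picking
  (parabolic sub-sample refinement, quality flags, "no response" as a
  value).
* **Conditioning**: linear-phase Kaiser FIR band-limiting (600–1,600 Hz
  ANOW, 150–1,500 Hz CAP) with group-delay correction, and quartile-fence
  artifact detection (`Q3 + 3·IQR` on deviations from a per-polarity
  ensemble median) — flagged samples are zero-weighted on the ANOW path
  and whole epochs (plus polarity partners) are dropped on the CAP path.
* **OAE**: double-evoked SFOAE residuals and 2f1−f2 DPOAE components with
  SEM noise floors in dB SPL.
* **Growth analysis**: per-level SNR, a run-of-2 6-dB threshold rule,
  SNR-weighted natural cubic smoothing splines minimizing
  `p·Σ wᵢ(yᵢ−g(Lᵢ))² + (1−p)·∫g″²` with `p = 0.005`, evaluation and
  differentiation on a 1-dB grid, the **median-slope recruitment metric**
  (median derivative at and above threshold), and slope-vs-threshold OLS
  with t-based p-values and 95% CIs, plus low-frequency aggregation.
* **Synthetic generator**: seeded, bit-reproducible epochs, level series
  and cohorts (compressive controls vs threshold-shifted hydropic ears
  whose growth converges to control at 80 dB SPL, coupling shift to
  slope), with ground-truth artifact bookkeeping.

## Worked example

```r
library(recruitpipe)

# one synthetic ANOW measurement: 480 Hz, 60 dB SPL, 92 epochs,
# 1 uV neural component, 10 uV microphonic, 1% transient corruption
spec <- anow_burst(480, level = 60)
scen <- scenario_config(cm_amplitude = 10,
                        neural_amplitude_fn = function(level) rep(1, length(level)),
                        noise_sigma = 0.5, artifact_rate = 0.01,
                        artifact_scale = 50, seed = 42)
epochs <- gen_anow_epochs(spec, scen)
epochs
#> <epoch_matrix> 92 epochs x 4733 samples @ 96000 Hz
#>   stimulus: 480 Hz, 60 dB SPL, 33.3 ms
#>   onset sample 768 (0-based), invalid edge 0 samples

anow_response(epochs)   # quartile masking on, fit at 2f = 960 Hz
#> <complex_response> |-2.998| dB (1.001 amp), phase -1.572 rad, floor -40 dB, n = 46, f = 960 Hz
```

The injected 1 µV component is recovered as 1.001 µV (−3.0 dB re 1 µV
RMS) despite the 50σ transients, because flagged samples carry zero weight
in the fit; the SEM noise floor sits at the −40 dB reporting floor.

```r
# a simulated cohort: 18 hydropic + 8 control ears, 4 ANOW + 2 CAP frequencies
cohort <- simulate_cohort(seed = 1)
stats <- cohort_statistics(cohort)

stats$group_mean_slopes
#> $control  : 0.34
#> $hydropic : 0.542

stats$per_frequency[["480"]]     # slope vs threshold across hydropic ears
#> <regression_result> y = 0.01206x + 0.1587, R^2 = 0.8371, p = 1.055e-07, 95% CI [0.009243, 0.01488], n = 18

stats$low_freq_regression        # aggregated low-frequency slope vs threshold shift
#> <regression_result> y = 0.01272x + 0.3508, R^2 = 0.9288, p = 2.827e-15, 95% CI [0.01124, 0.01421], n = 26
```

Control ears grow compressively (median slope ≈ 0.34 dB/dB); hydropic ears
are steeper (≈ 0.54 dB/dB at the default +22 dB mean shift), and the
slope-vs-threshold regression is strongly positive at shifted frequencies
— the recruitment signature — while high frequencies, where the generator
applies no shift, show none.

A thin CLI wraps the same functions
(`inst/exec/recruitpipe simulate|anow|cap|oae|growth|regress|all`), logging
parameters as line-delimited JSON and stamping every results file with the
configuration hash.

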