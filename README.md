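# mcgica — adaptive ICA denoising for multichannel OPM magnetocardiography

Magnetocardiography (MCG) records the heart's magnetic field — tens of
picotesla — with arrays of optically pumped magnetometers (OPMs). The
recordings mix the cardiac signal with mains tones, broadband noise and
other interference, and the standard cleanup is independent component
analysis (ICA): separate the channels into independent components, keep
the cardiac ones, reconstruct. In practice two steps are done by hand —
choosing how many components to keep, and judging which ones are cardiac.
`mcgica` automates both, for researchers processing multichannel MCG (or
similar quasi-periodic biomagnetic) recordings.

## Method

For a recording `X` (channels × samples, model `X = A S`):

1. **Preprocess**: zero-phase 0.5–100 Hz Butterworth bandpass; mains
   removal by spectral interpolation (magnitude around each 50 Hz harmonic
   replaced by interpolation of the flanking bands, phase kept);
   Daubechies-4 wavelet-band reconstruction (detail levels 5–7 ≈ 4–31 Hz)
   for R-wave enhancement; Pan-Tompkins-style R-peak detection on the
   most heartbeat-dominated (maximum-kurtosis) channel.
2. **How many components** — beat-based SNR:
   `SNR = Σᵢⱼ var_peak(i,j) / Σᵢⱼ var_mid(i,j)` over channels `i` and
   beats `j`, with `var_peak`/`var_mid` the sample variances in short
   windows at the R-peaks and RR midpoints. The implied signal-variance
   proportion `SNR/(1+SNR)` becomes the cumulative variance-contribution
   threshold, and `N` is the smallest number of principal components that
   reaches it.
3. **Which components** — after PCA whitening and fixed-point ICA
   (tanh contrast, symmetric decorrelation), each component `C_m` is
   scored by its normalized autocorrelation `Ac(t)`:
   * **AIP** (autocorrelation integral power): `var(Ac(t))` over a lag
     window;
   * **IPR**: `AIP over [τ₁, τ₂] / AIP over [τ₃, τ₄]`, the RR-interval lag
     window against a sub-period reference window — large only for
     quasi-periodic cardiac components. The max-IPR component is the
     **template**;
   * **CFE** (cross-correlation function extremum):
     `max R(t)(C_temp, C_k)` for `|t| ≤ τ_delay` — high for any component
     sharing the cardiac cycle (P/QRS/T fragments), at the sampling floor
     for noise.
   Components are ranked by CFE; the top `N` are retained and
   back-projected to reconstruct the denoised array.

A numerical phantom (`phantom_experiment()`) emulates a coil-driven
64-channel validation experiment — 90 bpm quasi-periodic heartbeat with
heart-rate variability and respiratory modulation, a 12 Hz in-band tone or
0–100 Hz band-limited Gaussian noise at a designed input SNR, random
sensor gains/polarities, small per-channel lags, 0.5 pT sensor floor —
with full ground truth for end-to-end evaluation.

## Worked example

```r
library(mcgica)

scene <- phantom_experiment(phantom_config(interference = "pli",
                                           snr_db = 7, seed = 1))
res <- run_adaptive_ica(scene$mixed)
print(res)
```

```
<adaptive_ica_result>
  input: 64 channels x 100000 samples @ 1000 Hz
  R-peaks: 149 on reference channel 38
  intervals: tau1=0.590 tau2=0.763 t_avg=0.668 tau_delay=0.334 s
  estimated SNR 17.5 (12.42 dB) -> variance threshold 0.94586
  working dimension d=4 (cutoff 0.999); adaptive retained count N=3
  ICA converged after 25 iterations (seed 0)
  template component 1 (IPR 35.65); retained {1,2,4}; excluded {3}
```

Reading the log: the beat-window SNR estimate (17.5, i.e. 12.42 dB) says
~94.6 % of the variance is signal, which the cumulative eigenvalue curve
reaches at `N = 3` components. Component 1 has an autocorrelation integral
power ratio of 36 — a strong cardiac recurrence signature — and becomes
the template; component 3 (the 12 Hz interferer, CFE ≈ 0.02) is excluded.

```r
report <- evaluation_report(res$denoised, scene$clean_channels,
                            res$annotations, snr_in_db = 7)
print(report)
```

```
<evaluation_report> SNR in 7.00 dB -> out 38.95 dB (imp 31.95 dB); corr mean 0.9983, max 0.9984
```

The reconstructed array correlates with the clean ground-truth channels at
0.998 on average, and the pooled beat-window output SNR is 39 dB.

A thin command-line front end wraps the same functions:

```sh
inst/cli/mcgica simulate --out scene.csv --interference bwn --snr-db 7
inst/cli/mcgica run --input scene.csv --out-dir results/
inst/cli/mcgica evaluate --input results/denoised.csv --truth scene.csv.truth
inst/cli/mcgica sweep --out sweep.tsv --snr 0,3,5,7 --seeds 10
```

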