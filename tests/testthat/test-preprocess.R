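fs <- 1000
tax <- function(dur) (seq_len(dur * fs) - 1) / fs

test_that("bandpass removes DC and drift but passes in-band tones", {
  t20 <- tax(20)
  rec <- mcg_recording(rbind(
    dc    = rep(5, length(t20)),
    tone  = sin(2 * pi * 10 * t20),
    drift = sin(2 * pi * 0.1 * t20)), fs = fs)
  out <- bandpass_filter(rec, 0.5, 100)
  mid <- 5000:15000   # steady-state section away from filter transients
  expect_lt(abs(mean(out$data[1, mid])) / 5, 1e-4)
  expect_lt(mean(abs(out$data[1, mid])) / 5, 1e-3)
  amp_tone <- max(abs(out$data[2, mid]))
  expect_gt(20 * log10(amp_tone / 1), -1)           # within 1 dB
  amp_drift <- max(abs(out$data[3, mid]))
  expect_lt(20 * log10(amp_drift / 1), -20)         # >= 20 dB down
  expect_error(bandpass_filter(rec, 0.5, 600), "fs/2")
})

test_that("spectral interpolation notches mains harmonics, not the rest", {
  t10 <- tax(10)
  set.seed(42)
  x <- sin(2 * pi * 50 * t10) + 0.7 * sin(2 * pi * 100 * t10) +
    0.01 * rnorm(length(t10))
  rec <- mcg_recording(matrix(x, 1), fs = fs)
  out <- remove_powerline(rec, 50, 2, 1)
  for (f in c(50, 100)) {
    before <- periodogram_power(rec$data[1, ], fs, f - 0.2, f + 0.2)
    after <- periodogram_power(out$data[1, ], fs, f - 0.2, f + 0.2)
    expect_lt(10 * log10(after / before), -30)
  }
  # input without energy near the harmonics passes through almost unchanged
  y <- sin(2 * pi * 17 * t10)
  recy <- mcg_recording(matrix(y, 1), fs = fs)
  outy <- remove_powerline(recy, 50, 2, 1)
  expect_lt(sqrt(mean((outy$data - recy$data)^2)) / sqrt(mean(y^2)), 0.01)
  expect_error(remove_powerline(rec, 50, 10L, 1), "DC or Nyquist")
})

test_that("db4 pyramid transform reconstructs perfectly with all levels", {
  set.seed(7)
  x <- rnorm(2048)
  pyr <- mcgica:::dwt_pyramid(x, 7L)
  back <- mcgica:::idwt_pyramid(pyr$approx, pyr$details)
  expect_lt(max(abs(back - x)), 1e-10)
  # orthonormality: energy is preserved across the decomposition
  energy <- sum(pyr$approx^2) + sum(unlist(lapply(pyr$details, function(d) sum(d^2))))
  expect_equal(energy, sum(x^2), tolerance = 1e-10)
})

test_that("wavelet band reconstruction keeps the QRS band only", {
  t20 <- tax(20)
  keep <- mcg_recording(matrix(sin(2 * pi * 20 * t20), 1), fs = fs)
  drop <- mcg_recording(matrix(sin(2 * pi * 1 * t20), 1), fs = fs)
  zero <- mcg_recording(matrix(numeric(length(t20)), 1) + 0, fs = fs)
  expect_gt(sqrt(mean(wavelet_band_reconstruct(keep)$data^2)) /
            sqrt(mean(keep$data^2)), 0.5)
  expect_lt(sqrt(mean(wavelet_band_reconstruct(drop)$data^2)) /
            sqrt(mean(drop$data^2)), 0.1)
  expect_equal(wavelet_band_reconstruct(zero)$data, zero$data)
  short <- mcg_recording(matrix(rnorm(256), 1), fs = fs)
  expect_error(wavelet_band_reconstruct(short), "shorter")
})

test_that("impulse trains are localized exactly and flat signals rejected", {
  n <- 10 * fs
  x <- numeric(n)
  truth <- seq(400, n - 400, by = 800)
  x[truth] <- 1
  ann <- detect_r_peaks(mcg_recording(matrix(x, 1), fs = fs))
  expect_identical(ann$r_peaks, as.integer(truth))
  expect_error(detect_r_peaks(mcg_recording(matrix(0 * x, 1) + 0, fs = fs)),
               "zero")
})

test_that("R-peaks on clean synthetic heartbeats match ground truth", {
  hb <- synth_heartbeat(duration_s = 30, fs = fs, seed = 11)
  rec <- mcg_recording(matrix(50 * hb$series, 1), fs = fs)
  wb <- wavelet_band_reconstruct(rec)
  ann <- detect_r_peaks(wb)
  expect_lt(abs(length(ann$r_peaks) - length(hb$r_truth)), 2)
  # median |offset| below 20 ms
  offs <- vapply(ann$r_peaks, function(p) min(abs(p - hb$r_truth)), numeric(1))
  expect_lt(median(offs) / fs, 0.020)
})

test_that("detector recall/precision vs ground truth stay above 0.98", {
  # property over seeds and both interferers at the hardest designed SNR
  for (seed in 1:5) {
    for (intf in c("pli", "bwn")) {
      sc <- test_scene(intf, snr_db = 0, seed = seed, duration_s = 40)
      wb <- wavelet_band_reconstruct(remove_powerline(bandpass_filter(
        sc$mixed, 0.5, 100)))
      ann <- detect_r_peaks(wb)
      tol <- 0.05 * 1000
      hits <- vapply(sc$r_truth, function(r)
        any(abs(ann$r_peaks - r) <= tol), logical(1))
      claimed <- vapply(ann$r_peaks, function(p)
        any(abs(sc$r_truth - p) <= tol), logical(1))
      expect_gte(mean(hits), 0.98)      # recall
      expect_gte(mean(claimed), 0.98)   # precision
    }
  }
})

test_that("interval parameters follow the RR statistics", {
  ann <- beat_annotations(c(1, 1001, 2101, 3051), n_samples = 4000)
  iv <- derive_intervals(ann, fs = 1000)
  expect_equal(iv$tau1, 0.95)
  expect_equal(iv$tau2, 1.1)
  expect_equal(iv$t_avg, mean(c(1, 1.1, 0.95)))
  expect_equal(iv$tau_delay, iv$t_avg / 2)
  expect_equal(c(iv$tau3, iv$tau4), c(0.15, 0.80))
  # invariants hold: 0 < tau3 < tau4 < tau1 <= t_avg <= tau2
  expect_true(0 < iv$tau3 && iv$tau3 < iv$tau4 && iv$tau4 < iv$tau1 &&
              iv$tau1 <= iv$t_avg && iv$t_avg <= iv$tau2)
  expect_lte(iv$tau_delay, iv$t_avg / 2)

  unif <- beat_annotations(c(1, 668, 1335, 2002), n_samples = 2500)
  ivu <- derive_intervals(unif, fs = 1000)
  expect_equal(ivu$tau1, ivu$tau2)
  expect_equal(ivu$tau1, ivu$t_avg)

  expect_error(beat_annotations(c(500), n_samples = 1000), "two R-peaks")
  two <- beat_annotations(c(100, 300), n_samples = 1000)
  expect_error(derive_intervals(two, fs = 1000), "2 RR intervals")
  short <- beat_annotations(c(1, 201, 401, 601), n_samples = 1000)
  expect_error(derive_intervals(short, fs = 1000), "reference interval")
})

test_that("epoch segmentation drops boundary beats and keeps the rest", {
  rec <- mcg_recording(matrix(rnorm(2 * 5000), 2), fs = 1000)
  ann <- beat_annotations(c(10, 1000, 2000, 3000, 4900), n_samples = 5000)
  ep <- segment_epochs(rec, ann, pre_s = 0.1, post_s = 0.2)
  expect_equal(dim(ep), c(3, 2, 301))     # first and last beats dropped
  expect_identical(attr(ep, "dropped"), 2L)
  expect_equal(ep[1, , ], rec$data[, 900:1200])
  expect_error(segment_epochs(rec, beat_annotations(c(5, 4998),
               n_samples = 5000), pre_s = 0.1, post_s = 0.2), "no complete")
})
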