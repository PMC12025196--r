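# Numerical phantom emulating a coil-driven OPM-MCG validation experiment:
# a quasi-periodic cardiac source, one interferer (in-band sinusoidal
# "powerline-type" tone or band-limited Gaussian white noise), and a
# per-sensor noise floor, mixed into an Nc-channel array at a designed input
# SNR with full ground truth retained.

# Cardiac cycle morphology: sum-of-Gaussians P-QRS-T template. Centres are
# seconds relative to the R-peak, widths are Gaussian sigmas; amplitudes are
# in units of the R-peak. Typical adult sinus-rhythm intervals at ~90 bpm.
hb_morphology <- list(
  centre_s = c(P = -0.110, Q = -0.025, R = 0, S = 0.025, T = 0.165),
  width_s  = c(P = 0.025,  Q = 0.010,  R = 0.011, S = 0.010, T = 0.045),
  amp      = c(P = 0.12,   Q = -0.12,  R = 1.00, S = -0.20, T = 0.35))

#' Synthesize a quasi-periodic heartbeat source
#'
#' Sum-of-Gaussians P-QRS-T morphology repeated with RR intervals drawn as
#' `Normal(60/hr_bpm, hrv_sd_s)` (so beat times follow a random walk around
#' the nominal rhythm, like real heart-rate variability) and sinusoidal
#' respiratory amplitude modulation. The ground-truth R-peak sample indices
#' are returned alongside the series.
#'
#' @param duration_s record length in seconds.
#' @param fs sampling rate in Hz.
#' @param hr_bpm mean heart rate in beats per minute (default 90).
#' @param hrv_sd_s standard deviation of the RR interval in seconds
#'   (default 0.03).
#' @param resp_rate_hz respiratory modulation rate (default 0.25 Hz).
#' @param resp_depth fractional amplitude modulation depth (default 0.1).
#' @param seed integer seed; the series is a pure function of the arguments
#'   and the seed.
#' @return List with `series` (length `duration_s * fs`, R-peak amplitude 1)
#'   and `r_truth` (1-based R-peak sample indices).
#' @export
synth_heartbeat <- function(duration_s = 100, fs = 1000, hr_bpm = 90,
                            hrv_sd_s = 0.03, resp_rate_hz = 0.25,
                            resp_depth = 0.1, seed = NULL) {
  rr0 <- 60 / hr_bpm
  if (duration_s < 3 * rr0) stop("duration must cover at least 3 beats")
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- round(duration_s * fs)
  # beat times: random walk of RR intervals
  r_times <- numeric(0)
  tt <- 0.4
  while (tt < duration_s - 0.4) {
    r_times <- c(r_times, tt)
    rr <- rr0 + if (hrv_sd_s > 0) stats::rnorm(1L, 0, hrv_sd_s) else 0
    if (rr <= 0) stop("hr/hrv parameters produced a non-positive RR interval")
    tt <- tt + rr
  }
  x <- numeric(n)
  tax <- (seq_len(n) - 1L) / fs
  mor <- hb_morphology
  for (r in r_times) {
    amod <- 1 + resp_depth * sin(2 * pi * resp_rate_hz * r)
    for (k in seq_along(mor$amp)) {
      c0 <- r + mor$centre_s[k]; w0 <- mor$width_s[k]
      i0 <- max(1L, floor((c0 - 5 * w0) * fs) + 1L)
      i1 <- min(n, ceiling((c0 + 5 * w0) * fs) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      x[idx] <- x[idx] + amod * mor$amp[k] *
        exp(-(tax[idx] - c0)^2 / (2 * w0^2))
    }
  }
  list(series = x, r_truth = round(r_times * fs) + 1L)
}

#' Synthesize a powerline-type sinusoidal interferer
#'
#' @param duration_s,fs record length (s) and sampling rate (Hz).
#' @param freq_hz tone frequency (default 12 Hz: deliberately inside the
#'   cardiac band, so it cannot be removed by mains-frequency filtering and
#'   must be rejected by component selection).
#' @param phase initial phase in radians.
#' @param amplitude peak amplitude.
#' @return Numeric series.
#' @export
synth_pli <- function(duration_s, fs, freq_hz = 12, phase = 0,
                      amplitude = 1) {
  if (freq_hz >= fs / 2) stop("`freq_hz` must be below Nyquist")
  tax <- (seq_len(round(duration_s * fs)) - 1L) / fs
  amplitude * sin(2 * pi * freq_hz * tax + phase)
}

#' Synthesize band-limited Gaussian white noise
#'
#' Gaussian white noise confined to `band_hz` with an ideal (FFT-domain)
#' filter with a short raised-cosine rolloff, then rescaled to unit standard
#' deviation. The band limit gives the autocorrelation its characteristic
#' sinc-like decay.
#'
#' @param duration_s,fs record length (s) and sampling rate (Hz).
#' @param band_hz length-2 band `(lo, hi)`, `0 <= lo < hi <= fs/2`.
#' @param seed integer seed.
#' @param edge_hz width of the raised-cosine band edge (default 5 Hz).
#' @return Numeric series with unit standard deviation.
#' @export
synth_bwn <- function(duration_s, fs, band_hz = c(0, 100), seed = NULL,
                      edge_hz = 5) {
  lo <- band_hz[1L]; hi <- band_hz[2L]
  if (!(lo >= 0 && lo < hi && hi <= fs / 2)) stop("require 0 <= lo < hi <= fs/2")
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- round(duration_s * fs)
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freq <- (seq_len(n) - 1L) * fs / n
  freq <- pmin(freq, fs - freq)              # two-sided -> folded frequency
  H <- numeric(n)
  H[freq >= lo & freq <= hi] <- 1
  ramp <- freq > hi & freq <= hi + edge_hz
  H[ramp] <- 0.5 * (1 + cos(pi * (freq[ramp] - hi) / edge_hz))
  if (lo > 0) {
    ramp <- freq < lo & freq >= lo - edge_hz
    H[ramp] <- 0.5 * (1 + cos(pi * (lo - freq[ramp]) / edge_hz))
  }
  y <- Re(stats::fft(X * H, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Scale a noise series to a designed SNR against a signal series
#'
#' Rescales `noise` so that `mean(signal^2) / mean(noise_scaled^2) =
#' 10^(target_db/10)`.
#'
#' @param signal,noise numeric series (both non-zero).
#' @param target_db designed SNR in dB.
#' @return The rescaled noise series.
#' @export
scale_to_snr <- function(signal, noise, target_db) {
  ps <- mean(signal^2); pn <- mean(noise^2)
  if (ps <= 0 || pn <= 0) stop("signal and noise must both be non-zero")
  noise * sqrt(ps / (pn * 10^(target_db / 10)))
}

# Uniform mid-tread quantizer with clipping, emulating an ADC.
quantize_adc <- function(x, bits, full_scale) {
  step <- 2 * full_scale / 2^bits
  q <- step * round(x / step)
  pmax(pmin(q, full_scale), -full_scale)
}

#' Mix ground-truth sources into a synthetic sensor array
#'
#' Draws per-channel gains (random magnitude and polarity, emulating the
#' spatial falloff and orientation of sensors around the source), applies
#' optional small per-channel propagation/response lags to the heartbeat
#' source, adds an optional per-sensor white noise floor, rescales the
#' interference gains so the array-level heartbeat-to-interference power
#' ratio equals `designed_snr_db` exactly, and optionally quantizes like an
#' ADC.
#'
#' @param sources matrix `n_sources x T`, heartbeat source in row 1.
#' @param n_channels number of sensors (>= `n_sources`).
#' @param seed integer seed for gains, lags and sensor noise.
#' @param fs sampling rate in Hz.
#' @param designed_snr_db array-level input SNR (heartbeat power over
#'   interference power); `NULL` leaves the drawn gains untouched.
#' @param r_truth ground-truth R indices carried into the scene.
#' @param lag_max_s per-channel heartbeat lag bound in seconds (lags drawn
#'   uniformly in `[-lag_max_s, lag_max_s]`; 0 disables).
#' @param sensor_noise_sd per-channel white noise floor sd, in output units.
#' @param peak_amplitude gain scale: median channel R-peak amplitude (pT).
#' @param adc_bits optional ADC resolution (e.g. 16); `NULL` disables
#'   quantization.
#' @param volts_per_nT optional calibration factor recorded in the scene.
#' @return An object of class `synthetic_scene`: `sources`, `mixing`
#'   (`n_channels x n_sources` gains), `clean_channels` (heartbeat-only
#'   channel data, lags and gains applied, no floor), `mixed` (an
#'   [mcg_recording()]), `designed_snr_db`, `seed`, `r_truth`,
#'   `channel_lags_s`, `sensor_noise_sd`.
#' @export
mix_to_array <- function(sources, n_channels, seed = NULL, fs = 1000,
                         designed_snr_db = NULL, r_truth = NULL,
                         lag_max_s = 0.010, sensor_noise_sd = 0,
                         peak_amplitude = 50, adc_bits = NULL,
                         volts_per_nT = NULL) {
  sources <- as.matrix(sources)
  ns <- nrow(sources); T <- ncol(sources)
  if (n_channels < ns) stop("need at least as many channels as sources")
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)

  # gains: magnitude in [0.3, 1] of the peak scale, random polarity
  draw_gains <- function()
    stats::runif(n_channels, 0.3, 1) * sample(c(-1, 1), n_channels, TRUE)
  A <- matrix(0, n_channels, ns)
  for (s in seq_len(ns)) A[, s] <- draw_gains()
  if (qr(A)$rank < ns) {                   # essentially impossible; redraw
    message("rank-deficient mixing draw; redrawing")
    for (s in seq_len(ns)) A[, s] <- draw_gains()
  }
  # scale heartbeat gains so the median channel R-peak is `peak_amplitude`
  A[, 1L] <- A[, 1L] * peak_amplitude / stats::median(abs(A[, 1L]))
  lags <- if (lag_max_s > 0)
    round(stats::runif(n_channels, -lag_max_s, lag_max_s) * fs) else
    integer(n_channels)

  shift_series <- function(x, k) {
    if (k == 0L) return(x)
    if (k > 0L) c(numeric(k), x[seq_len(T - k)])
    else c(x[(-k + 1L):T], numeric(-k))
  }
  hb_ch <- t(vapply(seq_len(n_channels),
                    function(i) A[i, 1L] * shift_series(sources[1L, ], lags[i]),
                    numeric(T)))
  int_ch <- if (ns >= 2L) A[, -1L, drop = FALSE] %*% sources[-1L, , drop = FALSE]
            else matrix(0, n_channels, T)

  if (!is.null(designed_snr_db) && ns >= 2L) {
    cur <- sum(hb_ch^2) / sum(int_ch^2)
    fac <- sqrt(cur / 10^(designed_snr_db / 10))
    int_ch <- int_ch * fac
    A[, -1L] <- A[, -1L] * fac
  }
  floor_ch <- if (sensor_noise_sd > 0)
    matrix(stats::rnorm(n_channels * T, 0, sensor_noise_sd), n_channels) else 0
  X <- hb_ch + int_ch + floor_ch
  if (!is.null(adc_bits))
    X <- quantize_adc(X, adc_bits, full_scale = 1.2 * max(abs(X)))

  structure(list(sources = sources, mixing = A, clean_channels = hb_ch,
                 mixed = mcg_recording(X, fs = fs, units = "pT"),
                 designed_snr_db = designed_snr_db, seed = seed,
                 r_truth = r_truth, channel_lags_s = lags / fs,
                 sensor_noise_sd = sensor_noise_sd,
                 volts_per_nT = volts_per_nT),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d sources -> %d channels, %d samples, designed SNR %s dB, seed %s\n",
              nrow(x$sources), n_channels(x$mixed), n_samples(x$mixed),
              format(x$designed_snr_db), format(x$seed)))
  invisible(x)
}

#' Default phantom configuration
#'
#' The study conditions of the numerical phantom: a 100 s, 1 kHz, 90 bpm
#' heartbeat with heart-rate variability and respiratory modulation, one
#' interferer (in-band 12 Hz tone or 0-100 Hz band-limited white noise) at a
#' designed array SNR, 64 sensors with random gains/polarities, small
#' per-channel heartbeat lags (max +/-10 ms) and a 0.5 pT rms per-sensor
#' noise floor.
#'
#' @param duration_s,fs,hr_bpm,hrv_sd_s,resp_rate_hz,resp_depth see
#'   [synth_heartbeat()].
#' @param interference `"pli"` or `"bwn"`.
#' @param snr_db designed input SNR in dB (default 7).
#' @param n_channels number of sensors (default 64).
#' @param pli_freq_hz tone frequency for `"pli"` (default 12).
#' @param bwn_band_hz noise band for `"bwn"` (default `c(0, 100)`).
#' @param lag_max_s,sensor_noise_sd,peak_amplitude,adc_bits,volts_per_nT see
#'   [mix_to_array()].
#' @param seed integer seed; the scene is a pure function of config + seed.
#' @return Named list of class `phantom_config`.
#' @export
phantom_config <- function(duration_s = 100, fs = 1000, hr_bpm = 90,
                           hrv_sd_s = 0.03, resp_rate_hz = 0.25,
                           resp_depth = 0.1, interference = c("pli", "bwn"),
                           snr_db = 7, n_channels = 64, pli_freq_hz = 12,
                           bwn_band_hz = c(0, 100), lag_max_s = 0.010,
                           sensor_noise_sd = 0.5, peak_amplitude = 50,
                           adc_bits = NULL, volts_per_nT = NULL, seed = 1) {
  interference <- match.arg(interference)
  structure(as.list(environment()), class = "phantom_config")
}

#' Generate a complete phantom scene
#'
#' Assembles [synth_heartbeat()], [synth_pli()]/[synth_bwn()],
#' [scale_to_snr()] and [mix_to_array()] into the end-to-end numerical
#' phantom under the given configuration.
#'
#' @param config a [phantom_config()].
#' @return A `synthetic_scene`.
#' @export
phantom_experiment <- function(config = phantom_config()) {
  if (!inherits(config, "phantom_config")) stop("expected a `phantom_config`")
  cf <- config
  hb <- synth_heartbeat(cf$duration_s, cf$fs, cf$hr_bpm, cf$hrv_sd_s,
                        cf$resp_rate_hz, cf$resp_depth,
                        seed = derive_seed(cf$seed, 1L))
  int <- switch(cf$interference,
    pli = {
      set.seed(derive_seed(cf$seed, 2L))
      synth_pli(cf$duration_s, cf$fs, cf$pli_freq_hz,
                phase = 2 * pi * stats::runif(1L))
    },
    bwn = synth_bwn(cf$duration_s, cf$fs, cf$bwn_band_hz,
                    seed = derive_seed(cf$seed, 2L)))
  int <- scale_to_snr(hb$series, int, cf$snr_db)
  mix_to_array(rbind(hb$series, int), cf$n_channels,
               seed = derive_seed(cf$seed, 3L), fs = cf$fs,
               designed_snr_db = cf$snr_db, r_truth = hb$r_truth,
               lag_max_s = cf$lag_max_s, sensor_noise_sd = cf$sensor_noise_sd,
               peak_amplitude = cf$peak_amplitude, adc_bits = cf$adc_bits,
               volts_per_nT = cf$volts_per_nT)
}

# Derived sub-seeds, kept within 32-bit integer range.
derive_seed <- function(seed, k) (as.integer(seed) * 101L + k) %% 214748329L
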