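# Shared fixtures: phantom scenes and pipeline runs are expensive, so they
# are built once per session and cached by their parameters.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

test_scene <- function(interference = "pli", snr_db = 7, seed = 1,
                       duration_s = 40, ...) {
  key <- paste("scene", interference, snr_db, seed, duration_s,
               paste(deparse(list(...)), collapse = ""), sep = "|")
  cached(key, phantom_experiment(phantom_config(
    interference = interference, snr_db = snr_db, seed = seed,
    duration_s = duration_s, ...)))
}

test_run <- function(interference = "pli", snr_db = 7, seed = 1,
                     duration_s = 40, ...) {
  key <- paste("run", interference, snr_db, seed, duration_s,
               paste(deparse(list(...)), collapse = ""), sep = "|")
  cached(key, run_adaptive_ica(
    test_scene(interference, snr_db, seed, duration_s, ...)$mixed))
}

# interval_params fixture without running detection
make_intervals <- function(tau1 = 0.59, tau2 = 0.76, t_avg = 0.667,
                           guard = 0.15) {
  structure(list(tau1 = tau1, tau2 = tau2, t_avg = t_avg,
                 tau_delay = t_avg / 2, tau3 = guard, tau4 = tau1 - guard),
            class = "interval_params")
}

periodogram_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1L) * fs / n
  sel <- freq >= f_lo & freq <= f_hi & freq <= fs / 2
  sum(p[sel])
}
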