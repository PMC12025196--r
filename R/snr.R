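#' Beat-based SNR estimate
#'
#' Estimates the SNR of a multichannel recording before any decomposition,
#' from the beat structure alone: signal power is the sample variance in a
#' short window around each R-peak (where the QRS dominates), noise power
#' the variance in the same-width window around the midpoint between
#' consecutive R-peaks (where the cardiac signal sits at baseline, so only
#' noise fluctuates). Using the within-window variance makes the estimate
#' insensitive to any window-local baseline offset. Both are summed over all
#' channels and beats and the ratio is returned, linear and in dB
#' (10*log10).
#'
#' The estimate drives the automatic choice of how many components to retain:
#' see [snr_to_variance_threshold()] and [retained_component_count()].
#'
#' @param rec an [mcg_recording()] (already bandpassed, hence ~zero-mean).
#' @param ann a [beat_annotations()] object.
#' @param win_s window half-width in seconds (default 0.05, i.e. a 100 ms
#'   window centred on the R-peak / midpoint).
#' @return An object of class `snr_estimate` with fields `signal_power`,
#'   `noise_power`, `ratio`, `db`.
#' @export
estimate_snr <- function(rec, ann, win_s = 0.05) {
  stopifnot_recording(rec)
  if (!inherits(ann, "beat_annotations")) stop("expected `beat_annotations`")
  pooled <- snr_windows_power(rec$data, ann, rec$fs, win_s)
  if (pooled$noise <= 0)
    stop("degenerate input: zero noise power at RR midpoints")
  ratio <- pooled$signal / pooled$noise
  structure(list(signal_power = pooled$signal, noise_power = pooled$noise,
                 ratio = ratio, db = 10 * log10(ratio), n_beats = pooled$n_beats,
                 win_s = win_s),
            class = "snr_estimate")
}

#' @export
print.snr_estimate <- function(x, ...) {
  cat(sprintf("<snr_estimate> ratio %.4g (%.2f dB) from %d beats\n",
              x$ratio, x$db, x$n_beats))
  invisible(x)
}

# Shared beat-window power accounting. Power is the population variance of
# the samples within each window (per channel, per beat): a window-local
# baseline offset -- e.g. the DC shift a high-pass filter leaves on a pulse
# train during diastole -- carries no information about either QRS energy or
# noise and must not enter the ratio. Returns sums over channels and beats
# near R-peaks and near RR midpoints, plus the per-channel sums.
snr_windows_power <- function(data, ann, fs, win_s) {
  w <- round(win_s * fs)
  if (w < 1L) stop("`win_s` too small for this sampling rate")
  T <- ncol(data)
  r <- ann$r_peaks
  mids <- floor((r[-length(r)] + r[-1L]) / 2)
  use <- r[-length(r)]                       # beat j pairs R_j with midpoint_j
  ok <- use - w >= 1L & use + w <= T & mids - w >= 1L & mids + w <= T
  use <- use[ok]; mids <- mids[ok]
  if (length(use) < 1L) stop("no beat windows fit inside the recording")
  nch <- nrow(data)
  sig_ch <- numeric(nch); noi_ch <- numeric(nch)
  win_var <- function(block) {
    mu <- rowMeans(block)
    rowMeans(block^2) - mu^2
  }
  for (j in seq_along(use)) {
    sig_ch <- sig_ch + win_var(data[, (use[j] - w):(use[j] + w), drop = FALSE])
    noi_ch <- noi_ch + win_var(data[, (mids[j] - w):(mids[j] + w), drop = FALSE])
  }
  list(signal = sum(sig_ch), noise = sum(noi_ch),
       signal_ch = sig_ch, noise_ch = noi_ch, n_beats = length(use))
}

#' Map an SNR ratio to a PCA variance-contribution threshold
#'
#' The proportion of signal variance to total variance implied by a linear
#' SNR ratio `s` is `s / (1 + s)`; this proportion is used as the cumulative
#' variance-contribution threshold for dimensionality selection. Strictly
#' increasing and bounded in (0, 1).
#'
#' @param snr_ratio positive linear SNR ratio.
#' @return Proportion in (0, 1).
#' @examples
#' snr_to_variance_threshold(1)       # 0 dB -> 0.5
#' snr_to_variance_threshold(10^0.7)  # 7 dB -> ~0.8337
#' @export
snr_to_variance_threshold <- function(snr_ratio) {
  if (!is.numeric(snr_ratio) || length(snr_ratio) != 1L ||
      !is.finite(snr_ratio) || snr_ratio <= 0)
    stop("`snr_ratio` must be a positive finite scalar")
  snr_ratio / (1 + snr_ratio)
}

#' Number of principal components needed to reach a variance threshold
#'
#' Returns the smallest `N` whose cumulative variance-contribution rate
#' reaches `threshold`.
#'
#' @param explained_variances non-negative variances in descending order.
#' @param threshold proportion in (0, 1].
#' @return Integer count `N >= 1`.
#' @examples
#' retained_component_count(c(4, 3, 2, 1), 0.5)  # 2
#' @export
retained_component_count <- function(explained_variances, threshold) {
  v <- as.numeric(explained_variances)
  if (length(v) == 0L) stop("empty variance list")
  if (any(!is.finite(v)) || any(v < 0)) stop("variances must be finite and >= 0")
  if (length(v) > 1L && any(diff(v) > 1e-8 * max(v, 1)))
    stop("`explained_variances` must be in descending order")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("`threshold` must lie in (0, 1]")
  tot <- sum(v)
  if (tot <= 0) stop("all variances are zero")
  cum <- cumsum(v) / tot
  if (threshold >= 1) return(sum(v > 0))
  as.integer(which(cum >= threshold - 1e-12)[1L])
}
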