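#' Beat-based output SNR, per channel and pooled
#'
#' Applies the same window-power accounting as [estimate_snr()] to a
#' (typically denoised) recording: per-channel SNR is the ratio of summed
#' mean-square power near R-peaks to summed power near RR midpoints for that
#' channel; the pooled (array) SNR sums over channels before taking the
#' ratio. Reported in dB (10*log10).
#'
#' @param denoised an [mcg_recording()].
#' @param ann a [beat_annotations()] object.
#' @param win_s window half-width in seconds (default 0.05).
#' @return List with `array_db`, `per_channel_db`, `array_ratio`.
#' @export
output_snr <- function(denoised, ann, win_s = 0.05) {
  stopifnot_recording(denoised)
  p <- snr_windows_power(denoised$data, ann, denoised$fs, win_s)
  if (p$noise <= 0) stop("degenerate input: zero midpoint power")
  per <- 10 * log10(p$signal_ch / p$noise_ch)
  list(array_db = 10 * log10(p$signal / p$noise), per_channel_db = per,
       array_ratio = p$signal / p$noise)
}

#' Per-channel correlation with ground truth
#'
#' Pearson correlation between each denoised channel and the corresponding
#' clean ground-truth channel. Channels with zero variance on either side are
#' reported `NA` and excluded from the mean with a warning. The mean across
#' channels is the headline metric; the maximum is also reported.
#'
#' @param denoised an [mcg_recording()] or channels-by-samples matrix.
#' @param clean_truth matching clean channel data (same shape).
#' @return List with `per_channel`, `mean`, `max`.
#' @export
channel_correlation <- function(denoised, clean_truth) {
  X <- if (inherits(denoised, "mcg_recording")) denoised$data else
    as.matrix(denoised)
  Y <- if (inherits(clean_truth, "mcg_recording")) clean_truth$data else
    as.matrix(clean_truth)
  if (!all(dim(X) == dim(Y))) stop("denoised and truth must have the same shape")
  r <- vapply(seq_len(nrow(X)), function(i) {
    sx <- stats::sd(X[i, ]); sy <- stats::sd(Y[i, ])
    if (sx == 0 || sy == 0) NA_real_ else stats::cor(X[i, ], Y[i, ])
  }, numeric(1L))
  if (anyNA(r))
    warning(sprintf("%d zero-variance channel(s) excluded from the mean",
                    sum(is.na(r))))
  list(per_channel = r, mean = mean(r, na.rm = TRUE), max = max(r, na.rm = TRUE))
}

#' Full evaluation report against ground truth
#'
#' @param denoised denoised [mcg_recording()].
#' @param clean_truth clean heartbeat-only channel data (same shape).
#' @param ann [beat_annotations()] used for the SNR windows.
#' @param snr_in_db input SNR in dB (e.g. the designed phantom SNR or an
#'   [estimate_snr()] of the raw data).
#' @param win_s window half-width in seconds.
#' @return Object of class `evaluation_report`: `snr_in_db`, `snr_out_db`,
#'   `snr_imp_db`, `per_channel_snr_db`, `corr_per_channel`, `corr_mean`,
#'   `corr_max`.
#' @export
evaluation_report <- function(denoised, clean_truth, ann, snr_in_db,
                              win_s = 0.05) {
  o <- output_snr(denoised, ann, win_s)
  r <- channel_correlation(denoised, clean_truth)
  structure(list(snr_in_db = snr_in_db, snr_out_db = o$array_db,
                 snr_imp_db = o$array_db - snr_in_db,
                 per_channel_snr_db = o$per_channel_db,
                 corr_per_channel = r$per_channel,
                 corr_mean = r$mean, corr_max = r$max),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> SNR in %.2f dB -> out %.2f dB (imp %.2f dB); corr mean %.4f, max %.4f\n",
              x$snr_in_db, x$snr_out_db, x$snr_imp_db, x$corr_mean, x$corr_max))
  invisible(x)
}

#' Butterfly-plot export: beat-aligned single-cycle traces
#'
#' Builds the long-format table behind a butterfly plot: for every complete
#' beat and every channel, the windowed trace around the R-peak, with sample
#' times relative to R. Overlaying `value` against `time_s` per channel
#' (optionally averaged over beats) gives the butterfly rendering.
#'
#' @param rec an [mcg_recording()].
#' @param ann a [beat_annotations()] object.
#' @param pre_s,post_s window extent around R in seconds.
#' @return `data.frame` with columns `beat`, `channel`, `time_s`, `value`.
#' @export
butterfly_export <- function(rec, ann, pre_s = 0.3, post_s = 0.5) {
  ep <- segment_epochs(rec, ann, pre_s, post_s)
  dm <- dim(ep)
  tg <- attr(ep, "time_s")
  data.frame(
    beat = rep(seq_len(dm[1L]), times = dm[2L] * dm[3L]),
    channel = rep(rep(seq_len(dm[2L]), each = dm[1L]), times = dm[3L]),
    time_s = rep(tg, each = dm[1L] * dm[2L]),
    value = as.vector(unclass(ep)))
}
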