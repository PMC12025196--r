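# Component scoring: which independent components carry the heartbeat?
#
# Two statistics drive the selection. The IPR (autocorrelation integral
# power ratio) contrasts the variance of a component's normalized
# autocorrelation function over the RR-interval lag window [tau1, tau2]
# (where a quasi-periodic cardiac component shows a strong recurrence peak)
# with the variance over a sub-period reference window [tau3, tau4] (where
# it is near zero). Sinusoidal interference is equally oscillatory in both
# windows (IPR ~ 1) and band-limited noise is flat in both, so a large IPR
# singles out the cardiac template. The CFE (cross-correlation function
# extremum) then measures, for every other component, the maximum normalized
# cross-correlation with that template within +/- tau_delay -- components
# sharing the cardiac cycle (P/QRS/T fragments) align within a cycle and
# score high, noise scores at the sampling floor.

#' Normalized autocorrelation function
#'
#' `Ac(t) = (1/(T-t)) * sum_i (x_i - xbar)(x_{i+t} - xbar) / sigma^2` with
#' the population variance `sigma^2 = (1/T) sum (x - xbar)^2`, so that
#' `Ac(0) = 1` exactly. Computed for lags `0..max_lag_samples` via FFT
#' (identical to the direct sum to ~1e-12). The function is even in the lag;
#' the one-sided series is returned.
#'
#' @param seq numeric series (non-constant).
#' @param max_lag_samples largest lag, in samples (< `length(seq)`).
#' @return Numeric vector of length `max_lag_samples + 1`, lags 0..max_lag.
#' @examples
#' autocorrelation(c(1, 2, 3, 4), 1)  # c(1, 1/3)
#' @export
autocorrelation <- function(seq, max_lag_samples) {
  x <- as.numeric(seq)
  T <- length(x)
  max_lag_samples <- as.integer(max_lag_samples)
  if (max_lag_samples < 0L || max_lag_samples >= T)
    stop("`max_lag_samples` must lie in [0, length(seq))")
  xc <- x - mean(x)
  s2 <- mean(xc^2)
  if (s2 <= 0) stop("degenerate component: constant sequence")
  raw <- fft_raw_crosscov(xc, xc, max_lag_samples)$pos  # sum_i x_i x_{i+t}
  raw / (T - 0:max_lag_samples) / s2
}

# Raw lagged cross-sums via one zero-padded FFT:
#   pos[t+1] = sum_{i=1}^{T-t} a_i b_{i+t},  neg[t] = sum_{i=1}^{T-t} b_i a_{i+t}
fft_raw_crosscov <- function(a, b, max_lag) {
  T <- length(a)
  n2 <- stats::nextn(T + max_lag, 2)
  A <- stats::fft(c(a, numeric(n2 - T)))
  B <- stats::fft(c(b, numeric(n2 - T)))
  cc <- Re(stats::fft(Conj(A) * B, inverse = TRUE)) / n2
  pos <- cc[1:(max_lag + 1L)]
  neg <- if (max_lag >= 1L) rev(cc[(n2 - max_lag + 1L):n2]) else numeric(0)
  list(pos = pos, neg = neg)   # neg[t] corresponds to lag -t, t = 1..max_lag
}

# Direct O(T * lag) reference implementations, used as the in-suite oracle
# for the FFT path.
autocorrelation_direct <- function(seq, max_lag_samples) {
  x <- as.numeric(seq); T <- length(x)
  xc <- x - mean(x); s2 <- mean(xc^2)
  vapply(0:max_lag_samples, function(t) {
    i <- seq_len(T - t)
    sum(xc[i] * xc[i + t]) / (T - t) / s2
  }, numeric(1L))
}

cross_correlation_direct <- function(template, other, max_lag) {
  x <- as.numeric(template); y <- as.numeric(other); T <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(mean(xc^2)); sy <- sqrt(mean(yc^2))
  pos <- vapply(0:max_lag, function(t) {
    i <- seq_len(T - t); sum(xc[i] * yc[i + t]) / (T - t) / (sx * sy)
  }, numeric(1L))
  neg <- vapply(seq_len(max_lag), function(t) {
    i <- seq_len(T - t); sum(yc[i] * xc[i + t]) / (T - t) / (sx * sy)
  }, numeric(1L))
  out <- c(rev(neg), pos)
  names(out) <- as.character(-max_lag:max_lag)
  out
}

#' Autocorrelation integral power (AIP)
#'
#' Population variance of the normalized autocorrelation function over a lag
#' interval given in seconds. The autocorrelation is even, so the one-sided
#' variance over `[a, b]` equals the two-sided variance over the symmetric
#' interval.
#'
#' @param ac autocorrelation series from [autocorrelation()] (lag 0 first).
#' @param interval_s length-2 numeric `(a, b)` in seconds, `0 <= a < b`.
#' @param fs sampling rate in Hz.
#' @return Non-negative scalar.
#' @export
aip <- function(ac, interval_s, fs) {
  a <- round(interval_s[1L] * fs); b <- round(interval_s[2L] * fs)
  if (a < 0 || b <= a) stop("`interval_s` must satisfy 0 <= a < b")
  if (b + 1L > length(ac)) stop("interval extends beyond computed lags")
  idx <- (a:b) + 1L
  if (length(idx) < 2L) stop("interval contains fewer than 2 lag samples")
  v <- ac[idx]
  mean((v - mean(v))^2)
}

#' Autocorrelation integral power ratio (IPR)
#'
#' `IPR = AIP over [tau1, tau2] / AIP over [tau3, tau4]`: the RR-interval lag
#' window against the sub-period reference window. Large for
#' heartbeat-dominated components. A zero denominator yields `+Inf`, which
#' marks the component as excluded from template candidacy.
#'
#' @param ac autocorrelation series from [autocorrelation()].
#' @param intervals an `interval_params` object from [derive_intervals()].
#' @param fs sampling rate in Hz.
#' @return Positive scalar (possibly `Inf`).
#' @export
ipr <- function(ac, intervals, fs) {
  if (!inherits(intervals, "interval_params")) stop("expected `interval_params`")
  num <- aip(ac, c(intervals$tau1, intervals$tau2), fs)
  den <- aip(ac, c(intervals$tau3, intervals$tau4), fs)
  if (den <= 0) return(Inf)
  num / den
}

#' Template selection by maximum IPR
#'
#' Returns the index of the largest finite IPR; ties break to the lowest
#' index. Components flagged `Inf` (degenerate reference interval) are not
#' template candidates.
#'
#' @param ipr_values numeric vector of per-component IPR values.
#' @return Integer index (1-based).
#' @export
select_template <- function(ipr_values) {
  v <- as.numeric(ipr_values)
  fin <- is.finite(v)
  if (!any(fin)) stop("no finite IPR values: cannot select a template")
  v[!fin] <- -Inf
  which.max(v)
}

#' Bilateral normalized cross-correlation
#'
#' For lag `t >= 0`:
#' `R(t) = (1/(T-t)) sum_{i=1}^{T-t} (x_i - xbar)(y_{i+t} - ybar) / (sx sy)`
#' with population standard deviations; negative lags swap the roles of the
#' two series. Computed by FFT; equals the direct sums to ~1e-12.
#'
#' @param template,other equal-length non-constant numeric series.
#' @param max_lag largest lag magnitude in samples.
#' @return Named numeric vector over lags `-max_lag..max_lag`.
#' @export
cross_correlation <- function(template, other, max_lag) {
  x <- as.numeric(template); y <- as.numeric(other)
  if (length(x) != length(y)) stop("series must have equal length")
  T <- length(x)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L || max_lag >= T) stop("`max_lag` must lie in [0, T)")
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(mean(xc^2)); sy <- sqrt(mean(yc^2))
  if (sx <= 0 || sy <= 0) stop("degenerate component: constant sequence")
  cc <- fft_raw_crosscov(xc, yc, max_lag)
  pos <- cc$pos / (T - 0:max_lag) / (sx * sy)
  neg <- if (max_lag >= 1L) cc$neg / (T - seq_len(max_lag)) / (sx * sy)
         else numeric(0)
  out <- c(rev(neg), pos)
  names(out) <- as.character(-max_lag:max_lag)
  out
}

#' Cross-correlation function extremum (CFE)
#'
#' Maximum of the bilateral cross-correlation over lags within
#' `[-tau_delay, +tau_delay]`. The signed maximum (not `max |R|`) is used;
#' the decomposition's sign normalization makes cardiac deflections positive
#' so aligned cardiac components correlate positively.
#'
#' @param r lag-indexed series from [cross_correlation()] (symmetric lags).
#' @param tau_delay_s search half-width in seconds.
#' @param fs sampling rate in Hz.
#' @return Scalar extremum.
#' @export
cfe <- function(r, tau_delay_s, fs) {
  L <- (length(r) - 1L) %/% 2L
  k <- round(tau_delay_s * fs)
  if (k < 0 || k > L) stop("`tau_delay_s` outside the computed lag range")
  centre <- L + 1L
  max(r[(centre - k):(centre + k)])
}

#' Rank components by CFE and build the keep mask
#'
#' Keeps the `N` components with the highest CFE (the template, whose CFE is
#' 1 by construction, always ranks first); ties break to the lower component
#' index.
#'
#' @param cfe_values per-component CFE vector (template position included).
#' @param N number of components to retain, `1 <= N <= length(cfe_values)`.
#' @param template_index index of the template component.
#' @return An object of class `component_scores` skeleton: list with `order`
#'   (CFE-descending component indices), `keep_mask`, `n_retained`,
#'   `template_index`. [score_components()] returns the fully populated
#'   object.
#' @export
rank_and_mask <- function(cfe_values, N, template_index) {
  v <- as.numeric(cfe_values)
  d <- length(v)
  if (N < 1L || N > d) stop(sprintf("N must lie in 1..%d", d))
  ord <- order(v, decreasing = TRUE)         # stable: ties keep lower index
  keep <- rep(FALSE, d)
  keep[ord[seq_len(N)]] <- TRUE
  structure(list(order = ord, keep_mask = keep, n_retained = as.integer(N),
                 template_index = as.integer(template_index)),
            class = "component_scores")
}

#' Score all independent components and build the retention mask
#'
#' Runs the full selection stage on a decomposition: per-component
#' autocorrelation up to `tau2 + guard` lags, AIP over the RR window and the
#' reference window, IPR, template by maximum IPR, bilateral
#' cross-correlation of every component against the template within
#' `+/- tau_delay`, CFE, CFE-descending ranking and the top-`N` keep mask.
#'
#' @param ica an `ica_decomposition` from [ica_decompose()].
#' @param intervals an `interval_params` from [derive_intervals()].
#' @param fs sampling rate in Hz.
#' @param n_keep number of components to retain (the adaptive `N`).
#' @param guard_s guard added to `tau2` for the autocorrelation lag range.
#' @return A `component_scores` object: `table` (data.frame with columns
#'   `component`, `aip_rr`, `aip_ref`, `ipr`, `cfe`, `rank`, `kept`),
#'   `template_index`, `keep_mask`, `order`, `n_retained`.
#' @export
score_components <- function(ica, intervals, fs, n_keep, guard_s = 0.15) {
  if (!inherits(ica, "ica_decomposition")) stop("expected `ica_decomposition`")
  S <- ica$sources
  d <- nrow(S)
  max_lag_ac <- round((intervals$tau2 + guard_s) * fs)
  aip_rr <- numeric(d); aip_ref <- numeric(d); ipr_v <- numeric(d)
  for (m in seq_len(d)) {
    ac <- autocorrelation(S[m, ], max_lag_ac)
    aip_rr[m] <- aip(ac, c(intervals$tau1, intervals$tau2), fs)
    aip_ref[m] <- aip(ac, c(intervals$tau3, intervals$tau4), fs)
    ipr_v[m] <- if (aip_ref[m] <= 0) Inf else aip_rr[m] / aip_ref[m]
  }
  tmpl <- select_template(ipr_v)
  max_lag_cc <- round(intervals$tau_delay * fs)
  cfe_v <- numeric(d)
  for (m in seq_len(d)) {
    if (m == tmpl) { cfe_v[m] <- 1; next }
    r <- cross_correlation(S[tmpl, ], S[m, ], max_lag_cc)
    cfe_v[m] <- cfe(r, intervals$tau_delay, fs)
  }
  sk <- rank_and_mask(cfe_v, n_keep, tmpl)
  rank_of <- integer(d); rank_of[sk$order] <- seq_len(d)
  sk$table <- data.frame(component = seq_len(d), aip_rr = aip_rr,
                         aip_ref = aip_ref, ipr = ipr_v, cfe = cfe_v,
                         rank = rank_of, kept = sk$keep_mask)
  sk
}

#' @export
print.component_scores <- function(x, ...) {
  cat(sprintf("<component_scores> template %d, %d of %d retained\n",
              x$template_index, x$n_retained, length(x$keep_mask)))
  if (!is.null(x$table)) {
    tb <- x$table
    tb$ipr <- signif(tb$ipr, 4); tb$cfe <- signif(tb$cfe, 3)
    print(utils::head(tb[order(tb$rank), c("component", "ipr", "cfe", "rank",
                                           "kept")], 10L), row.names = FALSE)
  }
  invisible(x)
}

#' Export a component-scores table to a delimited file
#'
#' @param scores a `component_scores` object from [score_components()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return Invisibly, `path`.
#' @export
write_scores <- function(scores, path, sep = "\t") {
  if (is.null(scores$table)) stop("scores object carries no table")
  utils::write.table(scores$table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
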