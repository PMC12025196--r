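#' PCA whitening and dimensionality reduction
#'
#' Centers each channel, eigendecomposes the channel covariance, keeps the
#' smallest number of principal directions whose cumulative variance
#' contribution reaches `var_cutoff`, and rescales so the retained scores
#' have identity covariance. The cutoff sets the ICA *working* dimension `d`
#' (a coarse rank estimate); the adaptive retained count `N` used after
#' component scoring is chosen separately from the estimated SNR.
#'
#' @param rec an [mcg_recording()] (or plain channels-by-samples matrix).
#' @param var_cutoff cumulative variance-contribution cutoff in (0, 1]
#'   (default 0.999).
#' @return An object of class `pca_whitening`: list with `pca` (class
#'   `pca_model`: `mean`, `basis` `[d x n_channels]`, `variances` (the `d`
#'   retained eigenvalues, descending), `cum_contribution`, `all_variances`)
#'   and `whitened` (`d x n_samples` scores with unit covariance), plus the
#'   recording's `fs`, `units`, `channel_names`.
#' @export
pca_whiten <- function(rec, var_cutoff = 0.999) {
  if (inherits(rec, "mcg_recording")) {
    X <- rec$data; fs <- rec$fs; units <- rec$units; chn <- rec$channel_names
  } else {
    X <- as.matrix(rec); fs <- NA_real_; units <- "pT"
    chn <- sprintf("ch%02d", seq_len(nrow(X)))
  }
  T <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / T
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  if (sum(lam) <= 0) stop("zero-variance input: nothing to whiten")
  rank_ok <- lam > max(lam) * 1e-12
  d_rank <- sum(rank_ok)
  d <- min(retained_component_count(lam, var_cutoff), d_rank, T)
  basis <- t(eg$vectors[, seq_len(d), drop = FALSE])      # d x Nc
  vars <- lam[seq_len(d)]
  Z <- (basis %*% Xc) / sqrt(vars)
  pca <- structure(list(mean = mu, basis = basis, variances = vars,
                        cum_contribution = cumsum(vars) / sum(lam),
                        all_variances = lam),
                   class = "pca_model")
  structure(list(pca = pca, whitened = Z, fs = fs, units = units,
                 channel_names = chn),
            class = "pca_whitening")
}

#' @export
print.pca_whitening <- function(x, ...) {
  cat(sprintf("<pca_whitening> d=%d of %d channels; cum. contribution %.5f\n",
              nrow(x$whitened), length(x$pca$mean),
              x$pca$cum_contribution[length(x$pca$cum_contribution)]))
  invisible(x)
}

# Symmetric fixed-point ICA iteration (negentropy maximization, tanh
# contrast, symmetric decorrelation). Z must be whitened d x T.
fastica_symm <- function(Z, seed = 0, tol = 1e-5, max_iter = 500L) {
  d <- nrow(Z); T <- ncol(Z)
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  W <- matrix(stats::rnorm(d * d), d, d)
  W <- sym_decorrelate(W)
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    S <- W %*% Z
    G <- tanh(S)
    gprime_mean <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / T - gprime_mean * W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))   # |diag(W1 W^T)| -> 1
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  list(W = W, converged = converged, iterations = it)
}

# W (W W^T)^{-1/2} via eigendecomposition.
sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  K <- e$vectors %*% (t(e$vectors) / sqrt(vals))
  K %*% W
}

#' Independent component decomposition of whitened data
#'
#' Fixed-point negentropy-maximizing ICA (tanh contrast, symmetric
#' decorrelation) on PCA-whitened data. Deterministic for a fixed seed. The
#' returned sources follow two conventions that downstream scoring relies on:
#' each source's largest-magnitude deflection is positive (sign
#' normalization), and sources are ordered by decreasing energy contribution
#' to the reconstructed data.
#'
#' @param whitened a `pca_whitening` object from [pca_whiten()].
#' @param seed integer seed for the random orthonormal initialization
#'   (default 0).
#' @param tol convergence tolerance on the unmixing update (default 1e-5).
#' @param max_iter iteration cap (default 500); on non-convergence the best
#'   iterate is returned with a warning and `converged = FALSE`.
#' @return An object of class `ica_decomposition`: `unmixing` (`d x d`),
#'   `mixing` (its inverse), `sources` (`d x n_samples`), `pca`, `converged`,
#'   `iterations`, plus recording metadata for reconstruction.
#' @export
ica_decompose <- function(whitened, seed = 0, tol = 1e-5, max_iter = 500L) {
  if (!inherits(whitened, "pca_whitening"))
    stop("expected a `pca_whitening` object from pca_whiten()")
  Z <- whitened$whitened
  fit <- fastica_symm(Z, seed = seed, tol = tol, max_iter = max_iter)
  if (!fit$converged)
    warning(sprintf("ICA did not reach tol=%g in %d iterations; returning best iterate",
                    tol, max_iter))
  W <- fit$W
  S <- W %*% Z

  # sign convention: largest-magnitude deflection positive
  flip <- apply(S, 1L, function(s) abs(min(s)) > abs(max(s)))
  W[flip, ] <- -W[flip, , drop = FALSE]
  S[flip, ] <- -S[flip, , drop = FALSE]

  # order by energy contributed to the data space
  pca <- whitened$pca
  back <- t(pca$basis) * rep(sqrt(pca$variances), each = ncol(pca$basis))
  # back is Nc x d; data-space pattern of component m is back %*% t(W)[, m]
  patterns <- back %*% t(W)
  energy <- colSums(patterns^2)              # sources have ~unit variance
  ord <- order(energy, decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  S <- S[ord, , drop = FALSE]

  structure(list(unmixing = W, mixing = solve(W), sources = S, pca = pca,
                 converged = fit$converged, iterations = fit$iterations,
                 seed = seed, fs = whitened$fs, units = whitened$units,
                 channel_names = whitened$channel_names),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components x %d samples (%s after %d iterations, seed %s)\n",
              nrow(x$sources), ncol(x$sources),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, format(x$seed)))
  invisible(x)
}

#' Reconstruct a multichannel recording from a retained-component mask
#'
#' Back-projects the retained independent components through the mixing
#' matrix and the PCA model, adding the channel means back:
#' `X_hat = B' diag(sqrt(lambda)) A diag(mask) S + mean`. With an all-true
#' mask this reproduces the rank-`d` PCA approximation of the input exactly.
#'
#' @param ica an `ica_decomposition` from [ica_decompose()].
#' @param keep_mask logical vector of length `d`; `TRUE` components are kept.
#' @return An [mcg_recording()] with the same shape/metadata as the input
#'   recording.
#' @export
reconstruct <- function(ica, keep_mask) {
  if (!inherits(ica, "ica_decomposition")) stop("expected `ica_decomposition`")
  d <- nrow(ica$sources)
  keep_mask <- as.logical(keep_mask)
  if (length(keep_mask) != d)
    stop(sprintf("`keep_mask` must have length d=%d", d))
  if (!any(keep_mask))
    warning("all components masked out: returning channel means only")
  pca <- ica$pca
  back <- t(pca$basis) * rep(sqrt(pca$variances), each = ncol(pca$basis))
  Sm <- ica$sources * keep_mask
  X <- back %*% (ica$mixing %*% Sm) + pca$mean
  fs <- if (is.finite(ica$fs)) ica$fs else 1
  mcg_recording(X, fs = fs, channel_names = ica$channel_names,
                units = ica$units)
}
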