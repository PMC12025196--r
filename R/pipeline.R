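#' Adaptive ICA pipeline configuration
#'
#' All tunable parameters of [run_adaptive_ica()], with their defaults:
#' 0.5-100 Hz zero-phase bandpass; 50 Hz spectral interpolation with 2
#' harmonics and 1 Hz half-width; Daubechies-4 depth-7 decomposition with
#' detail levels 5-7 for R-wave enhancement; 0.25 s detector refractory
#' period; 0.05 s SNR window half-width; 0.15 s guard defining the IPR
#' reference interval; 0.999 PCA variance cutoff for the ICA working
#' dimension; ICA tolerance 1e-5, at most 500 iterations, seed 0.
#'
#' @param band length-2 bandpass edges in Hz.
#' @param pli_f0,pli_harmonics,pli_half_width mains-removal parameters.
#' @param wavelet_levels,wavelet_depth wavelet-band reconstruction levels.
#' @param refractory_s R-detector refractory period (s).
#' @param win_s SNR window half-width (s).
#' @param guard_s guard for the IPR reference interval (s).
#' @param var_cutoff PCA variance cutoff for the ICA working dimension.
#' @param tau_delay_s CFE search half-width override in seconds; `NULL`
#'   (default) uses half the mean RR interval.
#' @param ica_tol,ica_max_iter ICA convergence controls.
#' @param seed integer seed for the ICA initialization.
#' @return Named list of class `adaptive_ica_config`.
#' @export
adaptive_ica_config <- function(band = c(0.5, 100), pli_f0 = 50,
                                pli_harmonics = 2L, pli_half_width = 1,
                                wavelet_levels = 5:7, wavelet_depth = 7L,
                                refractory_s = 0.25, win_s = 0.05,
                                guard_s = 0.15, var_cutoff = 0.999,
                                tau_delay_s = NULL, ica_tol = 1e-5,
                                ica_max_iter = 500L, seed = 0L) {
  structure(as.list(environment()), class = "adaptive_ica_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("adaptive ICA failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the adaptive ICA denoising pipeline
#'
#' Executes the full workflow on a multichannel recording: zero-phase
#' bandpass, mains removal by spectral interpolation, wavelet-band R-wave
#' enhancement and R-peak detection, beat-based SNR estimation, mapping of
#' the SNR to a PCA variance threshold and the retained-component count `N`,
#' PCA whitening to the working dimension `d`, fixed-point ICA, IPR template
#' selection, CFE ranking, and reconstruction from the top-`N` components.
#' Every adaptive quantity (estimated SNR, threshold, `d`, `N`, template
#' index and IPR, excluded components) is recorded in the run log.
#'
#' @param rec an [mcg_recording()] in physical units (pT).
#' @param config an [adaptive_ica_config()].
#' @return Object of class `adaptive_ica_result`: `denoised`
#'   ([mcg_recording()]), `scores` (`component_scores`), `snr`
#'   (`snr_estimate`), `threshold`, `n_retained`, `working_dim`,
#'   `annotations`, `intervals`, `ica`, `preprocessed`, `log` (character),
#'   `config`.
#' @export
run_adaptive_ica <- function(rec, config = adaptive_ica_config()) {
  stopifnot_recording(rec)
  if (!inherits(config, "adaptive_ica_config"))
    stop("expected an `adaptive_ica_config`")
  cf <- config
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  note("input: %d channels x %d samples @ %g Hz", n_channels(rec),
       n_samples(rec), rec$fs)
  bp <- with_stage("bandpass",
                   bandpass_filter(rec, cf$band[1L], cf$band[2L]))
  pp <- with_stage("powerline removal",
                   remove_powerline(bp, cf$pli_f0, cf$pli_harmonics,
                                    cf$pli_half_width))
  wb <- with_stage("wavelet band reconstruction",
                   wavelet_band_reconstruct(pp, cf$wavelet_levels,
                                            cf$wavelet_depth))
  ann <- with_stage("R-peak detection",
                    detect_r_peaks(wb, cf$refractory_s))
  note("R-peaks: %d on reference channel %d", length(ann$r_peaks),
       ann$reference_channel)
  iv <- with_stage("interval derivation",
                   derive_intervals(ann, rec$fs, cf$guard_s))
  if (!is.null(cf$tau_delay_s)) iv$tau_delay <- cf$tau_delay_s
  note("intervals: tau1=%.3f tau2=%.3f t_avg=%.3f tau_delay=%.3f s",
       iv$tau1, iv$tau2, iv$t_avg, iv$tau_delay)
  snr <- with_stage("SNR estimation", estimate_snr(pp, ann, cf$win_s))
  thr <- snr_to_variance_threshold(snr$ratio)
  note("estimated SNR %.3g (%.2f dB) -> variance threshold %.5f",
       snr$ratio, snr$db, thr)
  wh <- with_stage("PCA whitening", pca_whiten(pp, cf$var_cutoff))
  d <- nrow(wh$whitened)
  N <- min(retained_component_count(wh$pca$all_variances, thr), d)
  note("working dimension d=%d (cutoff %.4g); adaptive retained count N=%d",
       d, cf$var_cutoff, N)
  ica <- with_stage("ICA decomposition",
                    ica_decompose(wh, seed = cf$seed, tol = cf$ica_tol,
                                  max_iter = cf$ica_max_iter))
  note("ICA %s after %d iterations (seed %s)",
       if (ica$converged) "converged" else "did NOT converge",
       ica$iterations, format(cf$seed))
  scores <- with_stage("component scoring",
                       score_components(ica, iv, rec$fs, n_keep = N,
                                        guard_s = cf$guard_s))
  note("template component %d (IPR %.4g); retained {%s}; excluded {%s}",
       scores$template_index, scores$table$ipr[scores$template_index],
       paste(which(scores$keep_mask), collapse = ","),
       paste(which(!scores$keep_mask), collapse = ","))
  den <- with_stage("reconstruction", reconstruct(ica, scores$keep_mask))
  structure(list(denoised = den, scores = scores, snr = snr, threshold = thr,
                 n_retained = N, working_dim = d, annotations = ann,
                 intervals = iv, ica = ica, preprocessed = pp, log = log,
                 config = cf),
            class = "adaptive_ica_result")
}

#' @export
print.adaptive_ica_result <- function(x, ...) {
  cat("<adaptive_ica_result>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Phantom study: run the pipeline over interference types, SNRs and seeds
#'
#' Generates a phantom scene for every combination of interference type,
#' designed input SNR and seed, runs [run_adaptive_ica()], and evaluates the
#' result against the scene's ground truth. One row per run.
#'
#' @param interference character vector within `c("pli", "bwn")`.
#' @param snr_db numeric vector of designed input SNRs (dB).
#' @param seeds integer vector of scene seeds.
#' @param config an [adaptive_ica_config()].
#' @param ... overrides passed to [phantom_config()] (e.g. `duration_s`,
#'   `n_channels`).
#' @return `data.frame` with columns `interference`, `snr_db`, `seed`,
#'   `snr_est_db`, `working_dim`, `n_retained`, `template_ipr`,
#'   `snr_out_db`, `snr_imp_db`, `corr_mean`, `corr_max`,
#'   `template_is_heartbeat` (template IC is the heartbeat source's
#'   best-matching IC), `template_is_cardiac` (template correlates with the
#'   heartbeat source better than with the interference source),
#'   `heartbeat_retained` (best-matching IC kept), `interference_excluded`.
#' @export
phantom_study <- function(interference = c("pli", "bwn"),
                          snr_db = c(0, 3, 5, 7), seeds = 1:10,
                          config = adaptive_ica_config(), ...) {
  grid <- expand.grid(seed = seeds, snr_db = snr_db,
                      interference = interference,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    sc <- phantom_experiment(phantom_config(
      interference = grid$interference[g], snr_db = grid$snr_db[g],
      seed = grid$seed[g], ...))
    res <- run_adaptive_ica(sc$mixed, config)
    ev <- evaluation_report(res$denoised, sc$clean_channels, res$annotations,
                            snr_in_db = grid$snr_db[g],
                            win_s = config$win_s)
    idc <- identify_scene_components(res$ica, sc)
    rows[[g]] <- data.frame(
      interference = grid$interference[g], snr_db = grid$snr_db[g],
      seed = grid$seed[g], snr_est_db = res$snr$db,
      working_dim = res$working_dim, n_retained = res$n_retained,
      template_ipr = res$scores$table$ipr[res$scores$template_index],
      snr_out_db = ev$snr_out_db, snr_imp_db = ev$snr_imp_db,
      corr_mean = ev$corr_mean, corr_max = ev$corr_max,
      template_is_heartbeat = idc$heartbeat_ic == res$scores$template_index,
      template_is_cardiac = {
        tmpl <- res$ica$sources[res$scores$template_index, ]
        abs(stats::cor(tmpl, sc$sources[1L, ])) >
          abs(stats::cor(tmpl, sc$sources[nrow(sc$sources), ]))
      },
      heartbeat_retained = res$scores$keep_mask[idc$heartbeat_ic],
      interference_excluded = !res$scores$keep_mask[idc$interference_ic])
    rm(sc, res, ev); gc(FALSE)
  }
  do.call(rbind, rows)
}

#' Match ground-truth sources to independent components
#'
#' Finds, for a phantom scene, which IC best matches the heartbeat source
#' and which best matches the interference source (largest absolute Pearson
#' correlation between the IC and the source series).
#'
#' @param ica an `ica_decomposition`.
#' @param scene a `synthetic_scene` whose first source row is the heartbeat.
#' @return List with `heartbeat_ic`, `interference_ic`, `heartbeat_r`,
#'   `interference_r` (the absolute correlations).
#' @export
identify_scene_components <- function(ica, scene) {
  S <- ica$sources
  hb <- scene$sources[1L, ]
  int <- scene$sources[nrow(scene$sources), ]
  r_hb <- abs(apply(S, 1L, stats::cor, y = hb))
  r_int <- abs(apply(S, 1L, stats::cor, y = int))
  list(heartbeat_ic = which.max(r_hb), interference_ic = which.max(r_int),
       heartbeat_r = max(r_hb), interference_r = max(r_int))
}

#' Save / load a pipeline configuration
#'
#' Structured-text (YAML) round trip for [adaptive_ica_config()]; unknown
#' keys are rejected so a stale file cannot silently change behaviour.
#'
#' @param config an [adaptive_ica_config()].
#' @param path file path.
#' @return `read_pipeline_config()` returns an `adaptive_ica_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  if (!inherits(config, "adaptive_ica_config"))
    stop("expected an `adaptive_ica_config`")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  defaults <- adaptive_ica_config()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(unclass(defaults), vals, keep.null = TRUE)
  # yaml may drop NULLs entirely; restore missing keys as defaults
  for (k in setdiff(names(defaults), names(cfg))) cfg[k] <- list(defaults[[k]])
  cfg <- cfg[names(defaults)]
  class(cfg) <- "adaptive_ica_config"
  cfg
}
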