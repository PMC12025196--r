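#' Multichannel biomagnetic recording
#'
#' Container for an OPM-MCG (or other multichannel biomagnetic) recording:
#' a channels-by-samples numeric matrix plus sampling rate, channel names and
#' physical units. Channels are rows and time runs along columns; time is
#' sample-indexed (0-based externally, seconds obtained only via `fs`).
#'
#' @param data numeric matrix, `n_channels x n_samples`. All values must be
#'   finite.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names optional character vector, one name per channel.
#'   Defaults to `ch01, ch02, ...`.
#' @param units physical units of the samples: `"pT"` (picotesla) or `"V"`
#'   (sensor volts, to be converted with [convert_units()]).
#'
#' @return An object of class `mcg_recording`: a list with elements `data`,
#'   `fs`, `channel_names`, `units`.
#' @examples
#' rec <- mcg_recording(matrix(rnorm(200), 2), fs = 100)
#' n_channels(rec)
#' @export
mcg_recording <- function(data, fs, channel_names = NULL,
                          units = c("pT", "V")) {
  units <- match.arg(units)
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (nrow(data) < 1L || ncol(data) < 2L)
    stop("recording needs at least 1 channel and 2 samples")
  if (!all(is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value in recording at channel %d, sample %d",
                 bad[1L], bad[2L]))
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data))
    stop("`channel_names` length must equal the number of channels")
  dimnames(data) <- NULL
  structure(list(data = data, fs = as.numeric(fs),
                 channel_names = channel_names, units = units),
            class = "mcg_recording")
}

#' @export
print.mcg_recording <- function(x, ...) {
  cat(sprintf("<mcg_recording> %d channels x %d samples @ %g Hz (%.3g s), units %s\n",
              n_channels(x), n_samples(x), x$fs, n_samples(x) / x$fs, x$units))
  invisible(x)
}

#' @rdname mcg_recording
#' @param x an `mcg_recording`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname mcg_recording
#' @export
n_samples <- function(x) ncol(x$data)

stopifnot_recording <- function(x) {
  if (!inherits(x, "mcg_recording")) stop("expected an `mcg_recording` object")
  invisible(x)
}

# ---- sidecar metadata ------------------------------------------------------

sidecar_path <- function(path) paste0(path, ".meta.yaml")

write_sidecar <- function(rec, path, format, volts_per_nT = NULL) {
  meta <- list(fs_hz = rec$fs, units = rec$units,
               n_channels = n_channels(rec), n_samples = n_samples(rec),
               format = format, channel_names = rec$channel_names)
  if (!is.null(volts_per_nT)) meta$volts_per_nT <- volts_per_nT
  yaml::write_yaml(meta, sidecar_path(path))
}

read_sidecar <- function(metadata) {
  if (!file.exists(metadata))
    stop(sprintf("metadata file not found: %s", metadata))
  yaml::read_yaml(metadata)
}

# ---- read / write ----------------------------------------------------------

#' Read a multichannel recording from disk
#'
#' Reads a delimited-text or raw-binary matrix written one channel per row,
#' together with a small structured-text sidecar file carrying the sampling
#' rate, units and declared shape. The raw binary format is little-endian
#' 64-bit floats in row-major (channel-major) order.
#'
#' @param path file with the numeric payload.
#' @param format `"csv"`, `"tsv"` or `"raw"`.
#' @param metadata path to the sidecar metadata file; defaults to
#'   `<path>.meta.yaml` as written by [write_recording()].
#' @return An [mcg_recording()].
#' @export
read_recording <- function(path, format = c("csv", "tsv", "raw"),
                           metadata = sidecar_path(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("recording file not found: %s", path))
  meta <- read_sidecar(metadata)
  for (key in c("fs_hz", "units", "n_channels"))
    if (is.null(meta[[key]]))
      stop(sprintf("sidecar metadata is missing required key '%s'", key))

  if (format == "raw") {
    if (is.null(meta$n_samples))
      stop("raw binary input needs 'n_samples' in the sidecar metadata")
    nc <- meta$n_channels; ns <- meta$n_samples
    vals <- readBin(path, what = "double", n = nc * ns + 1L, size = 8L,
                    endian = "little")
    if (length(vals) != nc * ns)
      stop(sprintf("raw payload has %d values, metadata declares %d x %d",
                   length(vals), nc, ns))
    data <- matrix(vals, nrow = nc, ncol = ns, byrow = TRUE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- utils::read.table(path, sep = sep, header = FALSE,
                             colClasses = "character",
                             stringsAsFactors = FALSE)
    # optional leading column of channel names
    first <- suppressWarnings(as.numeric(tab[[1L]]))
    has_names <- anyNA(first)
    num <- if (has_names) tab[, -1L, drop = FALSE] else tab
    data <- matrix(NA_real_, nrow(num), ncol(num))
    for (j in seq_len(ncol(num))) {
      col <- suppressWarnings(as.numeric(num[[j]]))
      data[, j] <- col
    }
    bad <- which(!is.finite(data), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("non-numeric or non-finite cell '%s' at row %d, column %d of %s",
                   num[[bad[1L, 2L]]][bad[1L, 1L]], bad[1L, 1L],
                   bad[1L, 2L] + as.integer(has_names), path))
    if (has_names && is.null(meta$channel_names))
      meta$channel_names <- tab[[1L]]
    if (nrow(data) != meta$n_channels)
      stop(sprintf("shape mismatch: file has %d channels, metadata declares %d",
                   nrow(data), meta$n_channels))
  }
  mcg_recording(data, fs = meta$fs_hz, channel_names = meta$channel_names,
                units = meta$units)
}

#' Write a multichannel recording (payload + sidecar metadata)
#'
#' Inverse of [read_recording()]: writes the numeric payload in the requested
#' format and a `<path>.meta.yaml` sidecar so that a round trip reproduces the
#' data matrix bit-for-bit (raw) or to full printed precision (csv/tsv).
#'
#' @inheritParams read_recording
#' @param rec an [mcg_recording()].
#' @param volts_per_nT optional conversion factor recorded in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path, format = c("csv", "tsv", "raw"),
                            volts_per_nT = NULL) {
  format <- match.arg(format)
  stopifnot_recording(rec)
  if (n_channels(rec) < 1L) stop("refusing to write a recording with no channels")
  ok <- tryCatch({
    if (format == "raw") {
      writeBin(as.vector(t(rec$data)), path, size = 8L, endian = "little")
    } else {
      sep <- if (format == "csv") "," else "\t"
      lines <- vapply(seq_len(n_channels(rec)), function(i)
        paste(c(rec$channel_names[i],
                formatC(rec$data[i, ], format = "g", digits = 17)),
              collapse = sep), character(1L))
      writeLines(lines, path)
    }
    TRUE
  }, error = function(e)
    stop(sprintf("failed to write recording to %s: %s", path,
                 conditionMessage(e))))
  write_sidecar(rec, path, format, volts_per_nT)
  invisible(path)
}

#' Convert a recording from sensor volts to picotesla
#'
#' Applies the linear sensor calibration `value_pT = value_V / volts_per_nT *
#' 1000` (a factor of 2.7 V/nT is typical of closed-loop OPM electronics).
#' Refuses to convert a recording already in pT, so the conversion can never
#' silently be applied twice.
#'
#' @param rec an [mcg_recording()] with `units == "V"`.
#' @param volts_per_nT positive calibration factor in V/nT.
#' @return The recording in pT.
#' @examples
#' rec <- mcg_recording(matrix(2.7, 1, 4), fs = 10, units = "V")
#' convert_units(rec, 2.7)$data[1, 1]  # 1000 pT
#' @export
convert_units <- function(rec, volts_per_nT) {
  stopifnot_recording(rec)
  if (rec$units != "V")
    stop("recording is already in pT; refusing a second conversion")
  if (!is.numeric(volts_per_nT) || length(volts_per_nT) != 1L ||
      !is.finite(volts_per_nT) || volts_per_nT <= 0)
    stop("`volts_per_nT` must be a positive scalar")
  mcg_recording(rec$data / volts_per_nT * 1000, fs = rec$fs,
                channel_names = rec$channel_names, units = "pT")
}
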