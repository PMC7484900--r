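#' Construct an EEG recording object
#'
#' Container for a multi-channel recording: a channels-by-samples matrix in
#' microvolts plus the metadata the rest of the pipeline needs (sampling rate,
#' channel labels, recording condition).
#'
#' @param subject_id Opaque subject label (coerced to character).
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Character vector of channel labels, one per row of
#'   `data`. Defaults to `CH1..CHn`.
#' @param condition One of `"eyes_open"`, `"eyes_closed"`, `"synthetic"`.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, data, fs,
                          channel_names = NULL,
                          condition = c("synthetic", "eyes_open", "eyes_closed")) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L || ncol(data) < 1L) {
    stop("`data` must be a numeric matrix with >= 1 channel and >= 1 sample")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz")
  }
  if (is.null(channel_names)) channel_names <- paste0("CH", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data)) {
    stop("`channel_names` must have one label per channel")
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      data = data,
      fs = as.numeric(fs),
      channel_names = as.character(channel_names),
      condition = condition
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s: %d channels x %d samples @ %g Hz (%s)\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$fs, x$condition
  ))
  invisible(x)
}

# fixed-width ASCII field helper for the EDF header
edf_field <- function(value, width) {
  s <- formatC(as.character(value), width = -width)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  s
}

#' Write a recording to an EDF file
#'
#' Minimal EDF (European Data Format) writer used for fixtures and for
#' exporting synthetic cohorts. Samples are stored as 16-bit integers with
#' per-channel linear scaling between the physical minimum/maximum, so a
#' round trip is exact only up to that quantization. When the sample count is
#' a whole number of seconds the file uses 1-second data records; otherwise a
#' single record holds the whole signal.
#'
#' @param rec An [eeg_recording].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  data <- rec$data
  n_ch <- nrow(data)
  n_samp <- ncol(data)
  fs <- rec$fs
  if (fs == round(fs) && n_samp %% fs == 0) {
    n_rec <- n_samp %/% fs
    spr <- as.integer(fs)
    rec_dur <- 1
  } else {
    n_rec <- 1L
    spr <- n_samp
    rec_dur <- n_samp / fs
  }

  pmin <- apply(data, 1, min)
  pmax <- apply(data, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L
  dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * n_ch
  writeChar(paste0(
    edf_field("0", 8),
    edf_field(rec$subject_id, 80),
    edf_field(paste("restid", rec$condition), 80),
    edf_field("01.01.01", 8),
    edf_field("00.00.00", 8),
    edf_field(hdr_bytes, 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field(format(rec_dur, digits = 7), 8),
    edf_field(n_ch, 4)
  ), con, eos = NULL)
  per_sig <- function(values, width) {
    writeChar(paste(vapply(values, edf_field, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  per_sig(rec$channel_names, 16)
  per_sig(rep("", n_ch), 80)
  per_sig(rep("uV", n_ch), 8)
  per_sig(formatC(pmin, digits = 5, format = "g"), 8)
  per_sig(formatC(pmax, digits = 5, format = "g"), 8)
  per_sig(rep(dmin, n_ch), 8)
  per_sig(rep(dmax, n_ch), 8)
  per_sig(rep("", n_ch), 80)
  per_sig(rep(spr, n_ch), 8)
  per_sig(rep("", n_ch), 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(n_ch)) {
      dig <- round((data[ch, cols] - pmin[ch]) * scale[ch]) + dmin
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads a multi-channel EDF file into an [eeg_recording]: channel-major data,
#' sampling rate and channel labels taken from the header, no resampling or
#' filtering. All signals must share one sampling rate (true of the resting
#' EEG files this package targets).
#'
#' @param path Path to an EDF file.
#' @param condition Recording condition tag to attach (`"eyes_open"`,
#'   `"eyes_closed"`, or `"synthetic"`).
#' @param subject_id Optional subject label; defaults to the header's patient
#'   identification field.
#'
#' @return An [eeg_recording].
#' @export
read_edf_recording <- function(path,
                               condition = c("eyes_open", "eyes_closed", "synthetic"),
                               subject_id = NULL) {
  condition <- match.arg(condition)
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                       # version
  patient <- rd(80)
  rd(80); rd(8); rd(8)        # recording id, date, time
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  if (is.na(n_ch) || n_ch < 1L) stop("EDF format error: zero signals in ", path)
  if (is.na(n_rec) || n_rec < 1L) stop("EDF format error: no data records in ", path)

  sig <- function(width, as = identity) {
    vapply(seq_len(n_ch), function(i) as(trimws(readChar(con, width, useBytes = TRUE))), as(""))
  }
  labels <- sig(16)
  sig(80)                                   # transducer
  sig(8)                                    # physical dimension
  pmin <- as.numeric(sig(8))
  pmax <- as.numeric(sig(8))
  dmin <- as.numeric(sig(8))
  dmax <- as.numeric(sig(8))
  sig(80)                                   # prefiltering
  spr <- as.integer(sig(8))
  sig(32)

  if (length(unique(spr)) != 1L) {
    stop("EDF format error: signals with differing samples-per-record in ", path)
  }
  spr1 <- spr[[1L]]
  fs <- spr1 / rec_dur

  raw <- readBin(con, integer(), n = n_rec * n_ch * spr1, size = 2L,
                 endian = "little", signed = TRUE)
  if (length(raw) < n_rec * n_ch * spr1) stop("EDF file truncated: ", path)
  # records x (signal-major within record) -> channels x samples
  data <- matrix(0, nrow = n_ch, ncol = n_rec * spr1)
  arr <- array(raw, dim = c(spr1, n_ch, n_rec))
  for (ch in seq_len(n_ch)) {
    dig <- as.vector(arr[, ch, ])
    data[ch, ] <- (dig - dmin[ch]) * (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch]) + pmin[ch]
  }
  if (is.null(subject_id)) subject_id <- if (nzchar(patient)) patient else "unknown"
  eeg_recording(subject_id, data, fs, channel_names = labels, condition = condition)
}

#' Segment a recording into fixed-length instances
#'
#' Cuts non-overlapping consecutive windows starting at sample 1; a trailing
#' remainder shorter than one window is discarded. A 60-second resting run at
#' 160 Hz therefore yields 60 one-second instances.
#'
#' @param rec An [eeg_recording].
#' @param window_seconds Window length in seconds (default 1).
#'
#' @return A tibble with one row per instance and columns `subject_id`,
#'   `instance` (1-based ordinal), and `data` (list-column of
#'   channels-by-window matrices).
#' @export
segment_instances <- function(rec, window_seconds = 1.0) {
  stopifnot(inherits(rec, "eeg_recording"))
  w <- round(rec$fs * window_seconds)
  if (w < 2) stop("window must span at least 2 samples")
  n <- ncol(rec$data) %/% w
  if (n < 1L) stop("recording shorter than one window: no instances")
  data <- lapply(seq_len(n), function(k) {
    m <- rec$data[, ((k - 1L) * w + 1L):(k * w), drop = FALSE]
    rownames(m) <- rec$channel_names
    m
  })
  tibble::tibble(
    subject_id = rec$subject_id,
    instance = seq_len(n),
    data = data
  )
}

#' Common average reference
#'
#' Re-references each channel by subtracting, sample by sample, the mean over
#' all channels: `V_i' = V_i - mean_j(V_j)`. This removes signal components
#' common to every electrode; the re-referenced channels sum to zero at every
#' sample. Applied per instance so each window is self-contained.
#'
#' @param x A channels-by-samples matrix, an [eeg_recording], or an instance
#'   tibble from [segment_instances()].
#' @return Same shape as the input, re-referenced.
#' @export
common_average_reference <- function(x) UseMethod("common_average_reference")

#' @export
common_average_reference.matrix <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

#' @export
common_average_reference.eeg_recording <- function(x) {
  x$data <- common_average_reference(x$data)
  x
}

#' @export
common_average_reference.data.frame <- function(x) {
  stopifnot("data" %in% names(x))
  x$data <- lapply(x$data, common_average_reference.matrix)
  x
}
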