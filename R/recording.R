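#' Multichannel recording container
#'
#' Bundles one subject's multichannel signal with its class label, channel
#' names and sampling rate. The data matrix is channels x samples; row
#' \code{i} is the channel named \code{channel_names[i]}.
#'
#' @param subject_id character scalar identifying the subject.
#' @param label binary class label: 1 = patient, 0 = control.
#' @param channel_names character vector of unique channel names, one per
#'   row of \code{data}.
#' @param fs sampling rate in Hz (> 0).
#' @param data numeric matrix, channels x samples, no missing values.
#' @return an object of class \code{eeg_recording}.
#' @export
recording <- function(subject_id, label, channel_names, fs, data) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.character(channel_names) || length(channel_names) == 0)
    stop_validation("channel_names must be a non-empty character vector")
  if (nrow(data) != length(channel_names))
    stop_validation("data has %d rows but %d channel names were given",
                    nrow(data), length(channel_names))
  if (anyDuplicated(channel_names))
    stop_validation("channel names must be unique")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop_validation("fs must be a positive scalar (Hz)")
  if (anyNA(data))
    stop_validation("data contains missing values")
  if (!label %in% c(0, 1))
    stop_validation("label must be 0 (control) or 1 (patient)")
  rownames(data) <- channel_names
  structure(list(subject_id = as.character(subject_id),
                 label = as.integer(label),
                 channel_names = as.character(channel_names),
                 fs = as.numeric(fs),
                 data = data),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s (label %d): %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$label, nrow(x$data), ncol(x$data), x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a multichannel recording from disk
#'
#' Supports two formats: \code{"csv"}, a plain-text matrix with one row per
#' channel (first column \code{channel} holding the channel name, remaining
#' columns samples; an optional leading \code{"# fs=<Hz>"} comment line
#' records the sampling rate), or the transposed layout (header row of
#' channel names, one column per channel, rows = samples) selected with
#' \code{transposed = TRUE}; and \code{"edf"}, European Data Format.
#' EDF channel labels are normalized by stripping a leading \code{"EEG "}
#' token and anything from the first \code{"-"} onwards (reference
#' suffixes); every rename is reported via \code{message()}.
#'
#' @param path file to read.
#' @param label binary class label attached to the recording.
#' @param format \code{"csv"} or \code{"edf"}.
#' @param fs sampling rate in Hz; required for CSV files that carry no
#'   \code{# fs=} comment line. Ignored for EDF (taken from the header).
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @param transposed for CSV only: samples as rows, channels as columns.
#' @return an \code{\link{recording}} object.
#' @export
read_recording <- function(path, label, format = c("csv", "edf"), fs = NULL,
                           subject_id = NULL, transposed = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("cannot read recording: file not found: %s", path),
         call. = FALSE)
  subject_id <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "edf") {
    edf <- read_edf(path)
    rec <- recording(subject_id, label, edf$channel_names, edf$fs, edf$data)
  } else {
    first <- readLines(path, n = 1L)
    if (grepl("^#\\s*fs\\s*=", first)) {
      fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", first))
    }
    if (is.null(fs) || is.na(fs))
      stop_validation("sampling rate unknown: pass fs= or include a '# fs=' line in %s", path)
    df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (transposed) {
      mat <- t(as.matrix(df))
      ch <- colnames(df)
    } else {
      if (!identical(tolower(names(df)[1]), "channel"))
        stop_validation("row-per-channel CSV must have a first column named 'channel' (%s)", path)
      ch <- as.character(df[[1]])
      mat <- as.matrix(df[, -1, drop = FALSE])
      dimnames(mat) <- NULL
    }
    rec <- recording(subject_id, label, ch, fs, mat)
  }
  if (nrow(rec$data) < 2)
    stop_validation("recording %s has %d channel(s); connectivity needs at least 2",
                    path, nrow(rec$data))
  rec
}

#' Write a recording as a row-per-channel CSV
#'
#' Emits a \code{"# fs=<Hz>"} comment line followed by a CSV whose first
#' column is the channel name. \code{read_recording} reads this dialect
#' back bit-identically.
#'
#' @param rec an \code{eeg_recording}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  writeLines(paste(c("channel", sprintf("s%d", seq_len(ncol(rec$data)))),
                   collapse = ","), con)
  # %.17g keeps doubles exact through the text round-trip
  for (i in seq_len(nrow(rec$data)))
    writeLines(paste(c(rec$channel_names[i],
                       sprintf("%.17g", rec$data[i, ])), collapse = ","),
               con)
  invisible(path)
}

#' Load a cohort from a manifest file
#'
#' The manifest is a CSV with columns \code{subject_id}, \code{path} and
#' \code{label}; relative paths are resolved against the manifest's
#' directory. File format is inferred from the extension (\code{.edf} vs
#' anything else = CSV).
#'
#' @param manifest_path manifest CSV.
#' @param fs fallback sampling rate passed through to
#'   \code{\link{read_recording}} for CSV files.
#' @return a list of \code{eeg_recording} objects.
#' @export
read_cohort <- function(manifest_path, fs = NULL) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(man)))
    stop_validation("manifest must have columns subject_id, path, label")
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    fmt <- if (grepl("\\.edf$", p, ignore.case = TRUE)) "edf" else "csv"
    read_recording(p, label = man$label[i], format = fmt, fs = fs,
                   subject_id = man$subject_id[i])
  })
}

#' Band-limit a recording with zero-phase Butterworth filters
#'
#' Applies a high-pass filter at \code{low_cut} and a low-pass filter at
#' \code{high_cut}, each a Butterworth design of the given order run
#' forward-backward (\code{signal::filtfilt}) so the causal structure of
#' the signal is not distorted by filter phase.
#'
#' @param rec an \code{eeg_recording}.
#' @param low_cut high-pass cutoff in Hz (default 0.5).
#' @param high_cut low-pass cutoff in Hz (default 50).
#' @param order Butterworth order for each filter (default 4).
#' @return a new, filtered \code{eeg_recording} of identical shape.
#' @export
bandlimit <- function(rec, low_cut = 0.5, high_cut = 50, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < fs / 2))
    stop_validation("cutoffs must satisfy 0 < low_cut < high_cut < fs/2 (got %g, %g at fs=%g)",
                    low_cut, high_cut, fs)
  hp <- signal::butter(order, low_cut / (fs / 2), type = "high")
  lp <- signal::butter(order, high_cut / (fs / 2), type = "low")
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    x <- signal::filtfilt(hp, out[i, ])
    out[i, ] <- signal::filtfilt(lp, x)
  }
  recording(rec$subject_id, rec$label, rec$channel_names, fs, out)
}

#' Split a recording into fixed-length segments
#'
#' Windows advance by \code{window_seconds * (1 - overlap_fraction)}; a
#' trailing partial window is discarded. Each segment inherits the
#' recording's subject id and label and is indexed from 0 in time order.
#'
#' @param rec an \code{eeg_recording}.
#' @param window_seconds window length in seconds (default 60).
#' @param overlap_fraction fraction of overlap between consecutive
#'   windows, in [0, 1) (default 0).
#' @return a list of \code{eeg_segment} objects (possibly empty, with a
#'   warning, when the recording is shorter than one window).
#' @export
segment_recording <- function(rec, window_seconds = 60, overlap_fraction = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop_validation("overlap_fraction must be in [0, 1)")
  win <- as.integer(round(window_seconds * rec$fs))
  if (win < 1) stop_validation("window_seconds too small for fs=%g", rec$fs)
  n <- ncol(rec$data)
  if (n < win) {
    warning(sprintf("recording %s (%d samples) is shorter than one %g s window; no segments",
                    rec$subject_id, n, window_seconds))
    return(list())
  }
  step <- max(1L, as.integer(round(win * (1 - overlap_fraction))))
  starts <- seq.int(1L, n - win + 1L, by = step)
  lapply(seq_along(starts), function(k) {
    structure(list(subject_id = rec$subject_id,
                   label = rec$label,
                   segment_index = k - 1L,
                   channel_names = rec$channel_names,
                   fs = rec$fs,
                   data = rec$data[, starts[k]:(starts[k] + win - 1L), drop = FALSE]),
              class = "eeg_segment")
  })
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> subject %s, segment %d: %d x %d @ %g Hz\n",
              x$subject_id, x$segment_index, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

# coerce a segment-or-matrix argument to a plain channels x samples matrix
as_signal_matrix <- function(x) {
  if (inherits(x, "eeg_segment") || inherits(x, "eeg_recording")) x$data
  else as.matrix(x)
}
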