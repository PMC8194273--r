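# Minimal reader for European Data Format (EDF) files.
#
# EDF is a fixed-layout ASCII-header format: a 256-byte global header, a
# 256-byte-per-signal block of signal headers, then data records of
# little-endian 16-bit integers, one block per signal per record. Digital
# values are mapped to physical units with the per-signal linear scaling
# declared in the header. Only what the feature pipeline needs is
# implemented: equal sampling rate across retained signals, annotation
# channels dropped.

read_ascii <- function(con, nchars) {
  trimws(rawToChar(readBin(con, "raw", n = nchars)))
}

# strip "EEG " prefix and reference suffix ("-REF", "-A1", ...) from an
# EDF channel label; renames are reported so montage audits are possible
normalize_edf_label <- function(label) {
  out <- sub("^EEG[ _]+", "", label, ignore.case = TRUE)
  out <- sub("-.*$", "", out)
  trimws(out)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))

  version <- read_ascii(con, 8)
  if (!identical(version, "0"))
    stop(sprintf("not an EDF file (version field '%s'): %s", version, path),
         call. = FALSE)
  invisible(read_ascii(con, 80))  # patient id
  invisible(read_ascii(con, 80))  # recording id
  invisible(read_ascii(con, 8))   # start date
  invisible(read_ascii(con, 8))   # start time
  invisible(read_ascii(con, 8))   # header byte count
  invisible(read_ascii(con, 44))  # reserved
  n_records <- as.integer(read_ascii(con, 8))
  record_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1)
    stop(sprintf("EDF header of %s declares no signals", path), call. = FALSE)

  field <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- field(16)
  invisible(field(80))                       # transducer
  invisible(field(8))                        # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  invisible(field(80))                       # prefiltering
  spr <- as.integer(field(8))                # samples per record
  invisible(field(32))                       # reserved

  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)

  data <- matrix(0, nrow = sum(keep), ncol = n_records * max(spr[keep]))
  for (r in seq_len(n_records)) {
    row <- 0L
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, endian = "little",
                     signed = TRUE)
      if (length(dig) < spr[s])
        stop(sprintf("truncated EDF data record %d in %s", r, path),
             call. = FALSE)
      if (!keep[s]) next
      row <- row + 1L
      phys <- (dig - dig_min[s]) * gain[s] + phys_min[s]
      data[row, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
    }
  }

  fs <- unique(spr[keep] / record_dur)
  if (length(fs) != 1)
    stop(sprintf("EDF %s mixes sampling rates across signals (%s); not supported",
                 path, paste(fs, collapse = ", ")), call. = FALSE)

  raw_labels <- labels[keep]
  norm <- vapply(raw_labels, normalize_edf_label, "", USE.NAMES = FALSE)
  renamed <- norm != raw_labels
  if (any(renamed))
    message(sprintf("normalized EDF labels: %s",
                    paste(sprintf("'%s' -> '%s'", raw_labels[renamed],
                                  norm[renamed]), collapse = ", ")))
  list(channel_names = norm, fs = fs, data = data)
}
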