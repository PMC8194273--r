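# Write a minimal valid EDF file from a channels x samples matrix, used
# to exercise the reader without shipping binary fixtures. Signals are
# quantized to the int16 digital range declared in the header.

pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")

write_edf_minimal <- function(path, data, fs, labels,
                              record_seconds = 1) {
  m <- nrow(data)
  spr <- as.integer(fs * record_seconds)
  n_records <- ncol(data) %/% spr
  stopifnot(n_records >= 1)
  phys_min <- -200; phys_max <- 200
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 * (1 + m), 8); wr("", 44); wr(n_records, 8)
  wr(format(record_seconds), 8); wr(m, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(m)) wr("", 80)          # transducer
  for (i in seq_len(m)) wr("uV", 8)
  for (i in seq_len(m)) wr(phys_min, 8)
  for (i in seq_len(m)) wr(phys_max, 8)
  for (i in seq_len(m)) wr(dig_min, 8)
  for (i in seq_len(m)) wr(dig_max, 8)
  for (i in seq_len(m)) wr("", 80)          # prefilter
  for (i in seq_len(m)) wr(spr, 8)
  for (i in seq_len(m)) wr("", 32)

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (s in seq_len(m)) {
      phys <- data[s, ((r - 1) * spr + 1):(r * spr)]
      dig <- as.integer(round((phys - phys_min) / gain + dig_min))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

# the quantization the writer applies, for round-trip comparisons
edf_quantize <- function(data) {
  gain <- 400 / 65535
  dig <- round((data + 200) / gain - 32768)
  (dig + 32768) * gain - 200
}
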