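# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores an ASCII fixed-width header, per-signal ASCII subheaders, and
# data records of little-endian int16 samples scaled linearly between
# digital and physical ranges. This covers continuous EDF as produced by
# clinical EEG systems; EDF+ annotations channels are passed through as
# ordinary signals and dropped at montage matching.

read_edf_field <- function(con, n) {
  trimws(rawToChar(readBin(con, "raw", n)))
}

#' Read an EDF file
#'
#' @param path Path to an EDF file.
#' @return A list with `data` (signals x samples matrix, physical units),
#'   `labels`, `rates` (per-signal samples/s), and `record_duration` (s).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_edf_field(con, 8)
  if (!identical(version, "0")) {
    stop("not an EDF file (bad version field): ", path, call. = FALSE)
  }
  invisible(read_edf_field(con, 80))  # patient id
  invisible(read_edf_field(con, 80))  # recording id
  invisible(read_edf_field(con, 8))   # start date
  invisible(read_edf_field(con, 8))   # start time
  header_bytes <- as.integer(read_edf_field(con, 8))
  invisible(read_edf_field(con, 44))  # reserved
  n_records <- as.integer(read_edf_field(con, 8))
  rec_dur <- as.numeric(read_edf_field(con, 8))
  ns <- as.integer(read_edf_field(con, 4))
  if (is.na(ns) || ns < 1L || is.na(n_records) || n_records < 1L ||
      is.na(rec_dur) || rec_dur <= 0) {
    stop("unreadable EDF header: ", path, call. = FALSE)
  }
  fld <- function(w) vapply(seq_len(ns), function(i) read_edf_field(con, w),
                            character(1))
  labels <- fld(16)
  invisible(fld(80))                  # transducer
  invisible(fld(8))                   # physical dimension
  phys_min <- as.numeric(fld(8))
  phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8))
  dig_max <- as.numeric(fld(8))
  invisible(fld(80))                  # prefiltering
  spr <- as.integer(fld(8))           # samples per record
  invisible(fld(32))                  # reserved
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr))) {
    stop("unreadable EDF signal header: ", path, call. = FALSE)
  }
  seek(con, header_bytes)
  raw16 <- readBin(con, "integer", n = n_records * sum(spr), size = 2,
                   signed = TRUE, endian = "little")
  if (length(raw16) < n_records * sum(spr)) {
    stop("EDF data truncated: ", path, call. = FALSE)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, nrow = ns, ncol = n_records * max(spr))
  offsets <- c(0L, cumsum(spr))
  per_rec <- sum(spr)
  for (s in seq_len(ns)) {
    idx <- outer(offsets[s] + seq_len(spr[s]), (seq_len(n_records) - 1L) * per_rec, "+")
    dig <- raw16[as.vector(idx)]
    data[s, seq_len(n_records * spr[s])] <-
      phys_min[s] + gain[s] * (dig - dig_min[s])
  }
  list(data = data, labels = labels, rates = spr / rec_dur,
       record_duration = rec_dur, n_records = n_records,
       samples_per_record = spr)
}

#' Write a recording (or plain matrix) as EDF
#'
#' Samples are scaled to the int16 digital range per channel. Used by the
#' synthetic-cohort writer and for constructing test inputs.
#'
#' @param data Channels x samples numeric matrix.
#' @param path Output path.
#' @param rate Sampling rate (samples/s); must make whole 1-s records.
#' @param labels Channel labels (length `nrow(data)`).
#' @param phys_dim Physical dimension string (default "uV").
#' @export
write_edf <- function(data, path, rate, labels = rownames(data),
                      phys_dim = "uV") {
  data <- as.matrix(data)
  ns <- nrow(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  rec_dur <- 1
  spr <- as.integer(round(rate * rec_dur))
  if (abs(spr - rate * rec_dur) > 1e-9) {
    stop("rate must yield an integer number of samples per 1-s record",
         call. = FALSE)
  }
  n_records <- ncol(data) %/% spr
  if (n_records < 1L) stop("recording shorter than one data record", call. = FALSE)
  data <- data[, seq_len(n_records * spr), drop = FALSE]
  phys_min <- apply(data, 1, min)
  phys_max <- apply(data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  header_bytes <- 256L + 256L * ns

  pad <- function(x, w) {
    x <- substr(as.character(x), 1, w)
    formatC(x, width = w, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(pad(x, w)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8); wr("", 44); wr(n_records, 8)
  wr(format(rec_dur), 8); wr(ns, 4)
  for (s in seq_len(ns)) wr(labels[s], 16)
  for (s in seq_len(ns)) wr("", 80)
  for (s in seq_len(ns)) wr(phys_dim, 8)
  for (s in seq_len(ns)) wr(formatC(phys_min[s], digits = 6, format = "g"), 8)
  for (s in seq_len(ns)) wr(formatC(phys_max[s], digits = 6, format = "g"), 8)
  for (s in seq_len(ns)) wr(dig_min, 8)
  for (s in seq_len(ns)) wr(dig_max, 8)
  for (s in seq_len(ns)) wr("", 80)
  for (s in seq_len(ns)) wr(spr, 8)
  for (s in seq_len(ns)) wr("", 32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((data[s, cols] - phys_min[s]) / gain[s] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}
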