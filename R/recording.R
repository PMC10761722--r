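#' Construct an EEG recording object
#'
#' The basic container for a multichannel recording: a channels-by-samples
#' numeric matrix (microvolts) in montage order, the sampling rate, and
#' subject metadata.
#'
#' @param data Numeric matrix, channels x samples, rows in montage order.
#' @param rate Sampling rate in samples/second.
#' @param mont An `if_montage`; defaults to [default_montage()].
#' @param subject_id Subject identifier.
#' @param group One of `"HC"`, `"AD"`, `"unknown"`.
#' @param mmse MMSE score (0-30) or `NA`.
#' @return An object of class `if_recording`.
#' @export
recording <- function(data, rate, mont = default_montage(),
                      subject_id = "subject", group = "unknown",
                      mmse = NA_integer_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) != length(mont$labels)) {
    stop("data has ", nrow(data), " channels but montage has ",
         length(mont$labels), call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a positive scalar", call. = FALSE)
  }
  if (ncol(data) < 2 * rate) {
    stop("recording must span at least 2 seconds", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  group <- normalize_group(group, allow_unknown = TRUE)
  rownames(data) <- mont$labels
  structure(list(data = data, rate = rate, montage = mont,
                 subject_id = as.character(subject_id), group = group,
                 mmse = mmse),
            class = "if_recording")
}

normalize_group <- function(group, allow_unknown = FALSE) {
  g <- toupper(trimws(as.character(group)))
  ok <- c("HC", "AD", if (allow_unknown) "UNKNOWN")
  if (!g %in% ok) {
    stop("unknown group token '", group, "' (expected HC or AD)",
         call. = FALSE)
  }
  if (g == "UNKNOWN") "unknown" else g
}

#' Duration of a recording in seconds
#' @param rec An `if_recording`.
#' @return Numeric scalar, seconds.
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "if_recording"))
  ncol(rec$data) / rec$rate
}

#' @export
print.if_recording <- function(x, ...) {
  cat("<if_recording> ", x$subject_id, " [", x$group, "]: ",
      nrow(x$data), " ch x ", ncol(x$data), " samples @ ", x$rate,
      " Hz (", format(duration(x), digits = 4), " s)\n", sep = "")
  invisible(x)
}
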