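#' Read an EEG recording from EDF, delimited text, or npy
#'
#' Channels are matched against the montage (case-insensitively, with common
#' EDF "EEG "/reference-suffix decorations stripped) and reordered into
#' canonical montage order; extra channels (EOG, ECG, ...) are dropped.
#'
#' @param path Path to the file.
#' @param format `"edf"`, `"csv"` (or tsv), or `"npy"`; default guesses from
#'   the file extension.
#' @param mont Montage to resolve channels against.
#' @param rate Sampling rate in samples/s. Required for csv/npy; for EDF the
#'   header rate is used and `rate`, if given, must agree.
#' @param subject_id,group,mmse Subject metadata attached to the result.
#' @return An `if_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv", "npy"),
                           mont = default_montage(), rate = NULL,
                           subject_id = NULL, group = "unknown",
                           mmse = NA_integer_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      edf = "edf", npy = "npy",
      csv = "csv", tsv = "csv", txt = "csv",
      stop("cannot guess format from extension '.", ext,
           "'; pass format=", call. = FALSE))
  }
  if (is.null(subject_id)) {
    subject_id <- tools::file_path_sans_ext(basename(path))
  }
  if (format == "edf") {
    edf <- read_edf(path)
    idx <- match_montage_channels(edf$labels, mont)
    rates <- edf$rates[idx]
    if (length(unique(rates)) != 1L) {
      stop("montage channels have differing EDF sampling rates",
           call. = FALSE)
    }
    if (!is.null(rate) && !isTRUE(all.equal(rate, rates[1]))) {
      stop("supplied rate ", rate, " contradicts EDF header rate ",
           rates[1], call. = FALSE)
    }
    dat <- edf$data[idx, , drop = FALSE]
    rate <- rates[1]
  } else {
    if (is.null(rate)) {
      stop("rate must be supplied for ", format, " input", call. = FALSE)
    }
    dat <- if (format == "npy") read_npy(path) else {
      as.matrix(utils::read.table(path, header = FALSE, sep = guess_sep(path)))
    }
    dat <- unname(as.matrix(dat))
    if (nrow(dat) != length(mont$labels)) {
      stop("recording is missing montage channel(s): expected ",
           length(mont$labels), " rows, found ", nrow(dat), call. = FALSE)
    }
  }
  if (!all(is.finite(dat))) {
    stop("recording contains non-finite samples: ", path, call. = FALSE)
  }
  recording(dat, rate = rate, mont = mont, subject_id = subject_id,
            group = group, mmse = mmse)
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

#' Write a recording's sample matrix as delimited text
#'
#' @param rec An `if_recording`.
#' @param path Output file.
#' @param sep Field separator (default comma).
#' @export
write_recording_csv <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "if_recording"))
  utils::write.table(rec$data, path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is delimited text with columns `subject_id`, `path`, `group`,
#' `mmse`; `mmse` may be empty (typically for HC subjects). Group tokens are
#' case-folded to HC/AD. Relative paths are resolved against the manifest's
#' own directory.
#'
#' @param path Manifest file (csv or tsv, with header).
#' @return A data.frame of class `if_cohort` with columns subject_id, path,
#'   group, mmse.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("subject_id", "path", "group", "mmse")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[, need]
  if (anyDuplicated(tab$subject_id)) {
    stop("manifest has duplicate subject_id: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]),
               collapse = ", "), call. = FALSE)
  }
  tab$group <- vapply(tab$group, normalize_group, character(1))
  tab$mmse <- suppressWarnings(as.integer(tab$mmse))
  rel <- !grepl("^(/|[A-Za-z]:)", tab$path)
  tab$path[rel] <- file.path(dirname(path), tab$path[rel])
  class(tab) <- c("if_cohort", "data.frame")
  tab
}

#' Write a result table to tsv or json
#'
#' Accepts a data.frame (written as flat records) or a named numeric
#' matrix such as a transition matrix (flattened to long
#' source/destination/value records). Round-tripping a tsv with
#' [utils::read.table()] reproduces values to full double precision.
#'
#' @param metrics Data.frame or matrix.
#' @param path Output file.
#' @param format `"tsv"` or `"json"`; default guesses from the extension.
#' @export
write_results <- function(metrics, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  if (is.matrix(metrics)) {
    metrics <- matrix_to_long(metrics)
  }
  if (!is.data.frame(metrics)) {
    stop("metrics must be a data.frame or matrix", call. = FALSE)
  }
  ok <- tryCatch({
    if (format == "tsv") {
      df <- metrics
      num <- vapply(df, is.double, logical(1))
      df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      jsonlite::write_json(metrics, path, dataframe = "rows", digits = NA,
                           na = "null", pretty = TRUE)
    }
    TRUE
  }, error = function(e) {
    stop("could not write results to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

matrix_to_long <- function(m) {
  rn <- rownames(m) %||% paste0("row", seq_len(nrow(m)))
  cn <- colnames(m) %||% paste0("col", seq_len(ncol(m)))
  data.frame(source = rep(rn, times = ncol(m)),
             destination = rep(cn, each = nrow(m)),
             value = as.vector(m), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
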