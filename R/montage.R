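#' Electrode montage with scalp-region membership
#'
#' A montage is an ordered set of electrode labels plus a region map that
#' assigns each electrode to anterior/posterior and lateral scalp regions.
#' Region sets are used to give fitted microstates canonical names
#' (frontal / occipital / left / right leading).
#'
#' @param labels Character vector of electrode names, in canonical order.
#' @param region_map Named list of character vectors; names are region
#'   identifiers, values are subsets of `labels`. An electrode may appear in
#'   one anterior/posterior set and one lateral set.
#' @return An object of class `if_montage`.
#' @export
montage <- function(labels, region_map) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("montage labels must be unique", call. = FALSE)
  }
  if (length(labels) < 2L) stop("montage needs at least 2 electrodes", call. = FALSE)
  if (!is.list(region_map) || is.null(names(region_map)) ||
      any(!nzchar(names(region_map)))) {
    stop("region_map must be a named list of electrode sets", call. = FALSE)
  }
  for (rn in names(region_map)) {
    rs <- region_map[[rn]]
    if (length(rs) == 0L) stop("region '", rn, "' is empty", call. = FALSE)
    bad <- setdiff(rs, labels)
    if (length(bad)) {
      stop("region '", rn, "' names unknown electrodes: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(labels = labels, region_map = region_map),
            class = "if_montage")
}

#' Default 16-channel 10-20 montage
#'
#' The canonical channel order is Fp1, Fp2, F3, F4, C3, C4, P3, P4, O1, O2,
#' F7, F8, Fz, Pz, T5, T6; every matrix in the package uses it. The region
#' map follows standard 10-20 anteriority/laterality: frontal and occipital
#' (posterior) sets partition the scalp front-to-back, left and right sets
#' side-to-side; midline-adjacent electrodes belong to one set of each pair.
#'
#' @return An `if_montage` with 16 labels and four region sets.
#' @export
default_montage <- function() {
  montage(
    labels = c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
               "O1", "O2", "F7", "F8", "Fz", "Pz", "T5", "T6"),
    region_map = list(
      frontal   = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz"),
      occipital = c("O1", "O2", "P3", "P4", "Pz", "T5", "T6"),
      left      = c("Fp1", "F3", "F7", "C3", "P3", "O1", "T5"),
      right     = c("Fp2", "F4", "F8", "C4", "P4", "O2", "T6")
    )
  )
}

#' @export
print.if_montage <- function(x, ...) {
  cat("<if_montage> ", length(x$labels), " electrodes: ",
      paste(x$labels, collapse = " "), "\n", sep = "")
  for (rn in names(x$region_map)) {
    cat("  ", rn, ": ", paste(x$region_map[[rn]], collapse = " "), "\n",
        sep = "")
  }
  invisible(x)
}

# Indices (rows) of a region's electrodes in montage order.
region_indices <- function(mont, region) {
  idx <- match(mont$region_map[[region]], mont$labels)
  if (anyNA(idx)) stop("region map out of sync with labels", call. = FALSE)
  idx
}

# Normalise an EDF-style label ("EEG Fp1-A1A2", "FP1-REF") to a bare
# montage label; matching is case-insensitive.
normalize_channel_label <- function(x) {
  x <- trimws(x)
  x <- sub("^EEG[ _]*", "", x, ignore.case = TRUE)
  x <- sub("[-_ ](A1A2|A1|A2|REF|LE|AVG|M1|M2|CZ)$", "", x,
           ignore.case = TRUE)
  trimws(x)
}

# Match raw channel labels against a montage; returns the index of each
# montage label inside `raw_labels` (errors name the missing electrode).
match_montage_channels <- function(raw_labels, mont) {
  norm <- tolower(normalize_channel_label(raw_labels))
  want <- tolower(mont$labels)
  idx <- match(want, norm)
  if (anyNA(idx)) {
    stop("recording is missing montage channel(s): ",
         paste(mont$labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}
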