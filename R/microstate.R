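# Microstate segmentation on the IF deviation field: states are defined by
# the dIF topography at GF-IF maxima; transitions occur at GF-IF minima.

too_short_dynamics <- function(msg) {
  stop(structure(class = c("ifstate_too_short_dynamics", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Detect local extrema of a GF-IF series
#'
#' Strict local maxima and minima by neighbour comparison; flat runs
#' (plateaus) collapse to their midpoint sample. Alternation is enforced:
#' between two consecutive minima exactly one maximum is kept (the
#' largest), and symmetrically for minima between maxima, so maxima and
#' minima strictly interleave.
#'
#' @param g A `gfif_series`.
#' @return The series with `maxima` and `minima` filled (sample indices).
#' @export
detect_extrema <- function(g) {
  stopifnot(inherits(g, "gfif_series"))
  x <- g$gfif
  if (length(x) < 3L) too_short_dynamics("series shorter than 3 samples")
  r <- rle(x)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- (starts + ends) %/% 2L
  kind <- integer(k)  # +1 max, -1 min, 0 neither
  if (k >= 3L) {
    v <- r$values
    interior <- 2:(k - 1L)
    kind[interior] <- ifelse(v[interior] > v[interior - 1L] &
                               v[interior] > v[interior + 1L], 1L,
                      ifelse(v[interior] < v[interior - 1L] &
                               v[interior] < v[interior + 1L], -1L, 0L))
  }
  idx <- mids[kind != 0L]
  typ <- kind[kind != 0L]
  if (length(idx) == 0L) too_short_dynamics("no local extrema in GF-IF")
  # collapse runs of same-type extrema: keep the most extreme one
  keep <- logical(length(idx))
  i <- 1L
  while (i <= length(idx)) {
    j <- i
    while (j < length(idx) && typ[j + 1L] == typ[i]) j <- j + 1L
    block <- i:j
    pick <- if (typ[i] > 0L) block[which.max(x[idx[block]])] else
      block[which.min(x[idx[block]])]
    keep[pick] <- TRUE
    i <- j + 1L
  }
  g$maxima <- idx[keep & typ > 0L]
  g$minima <- idx[keep & typ < 0L]
  if (length(g$minima) < 2L || length(g$maxima) < 1L) {
    too_short_dynamics("GF-IF dynamics too short: need >= 2 minima and 1 maximum")
  }
  g
}

#' Pool dIF peak topographies across a cohort
#'
#' Stacks the dIF column vector at every GF-IF maximum over all recordings
#' into one matrix, the input to the pooled k-means fit. Row provenance
#' (subject and peak sample) is retained.
#'
#' @param results List of lists, each with elements `iff` (an `if_field`
#'   with `dif`) and `gfif` (a `gfif_series` with extrema), and optionally
#'   `subject_id`.
#' @return Matrix n_peaks x n_channels with attributes `subject` and
#'   `peak_sample`.
#' @export
collect_peak_vectors <- function(results) {
  if (length(results) == 0L) stop("empty cohort", call. = FALSE)
  blocks <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    stopifnot(inherits(r$iff, "if_field"), inherits(r$gfif, "gfif_series"))
    if (length(r$gfif$maxima) == 0L) {
      return(list(m = matrix(0, 0, nrow(r$iff$dif)), s = character(0),
                  p = integer(0)))
    }
    list(m = t(r$iff$dif[, r$gfif$maxima, drop = FALSE]),
         s = rep(r$subject_id %||% paste0("rec", i), length(r$gfif$maxima)),
         p = r$gfif$maxima)
  })
  peaks <- do.call(rbind, lapply(blocks, `[[`, "m"))
  if (nrow(peaks) == 0L) stop("no GF-IF maxima in cohort", call. = FALSE)
  attr(peaks, "subject") <- unlist(lapply(blocks, `[[`, "s"))
  attr(peaks, "peak_sample") <- unlist(lapply(blocks, `[[`, "p"))
  peaks
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centres with
# probability proportional to squared distance to the nearest chosen one.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i1 <- sample.int(n, 1L)
  centers[1L, ] <- x[i1, ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 <= 0)) {
      centers[j, ] <- x[sample.int(n, 1L), ]
      next
    }
    pick <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' Fit the pooled k-means state model
#'
#' Clusters peak dIF topographies with Euclidean k-means (k-means++
#' seeding, `restarts` independent starts, best within-cluster sum of
#' squares kept). Vectors are clustered as-is — no polarity invariance,
#' because the dIF sign distinguishes leading from delaying regions.
#'
#' @param peaks Matrix n_peaks x n_channels from [collect_peak_vectors()].
#' @param k Number of states (default 4).
#' @param seed Integer RNG seed; the fit is deterministic given it.
#' @param restarts Number of k-means++ restarts (default 50).
#' @param mont Montage used later for labelling; stored on the model.
#' @return An object of class `if_state_model` with `centroids`
#'   (k x n_channels, Hz), `labels`, `k`, `seed`, `inertia`.
#' @export
fit_state_model <- function(peaks, k = 4, seed = 1L, restarts = 50,
                            mont = default_montage()) {
  peaks <- as.matrix(peaks)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > nrow(peaks)) {
    stop("k = ", k, " exceeds the number of peak vectors (", nrow(peaks),
         ")", call. = FALSE)
  }
  n_distinct <- nrow(unique(peaks))
  best <- NULL
  withr::with_seed(as.integer(seed), {
    if (n_distinct < k) {
      # degenerate input: fewer distinct topographies than clusters
      u <- unique(peaks)
      centroids <- u[rep(seq_len(nrow(u)), length.out = k), , drop = FALSE]
      assign_idx <- apply_nearest(peaks, centroids)
      best <- list(centers = centroids, cluster = assign_idx,
                   tot.withinss = 0)
    } else {
      for (r in seq_len(restarts)) {
        fit <- tryCatch(
          suppressWarnings(  # Lloyd non-convergence is still a usable fit
            stats::kmeans(peaks, centers = kmeanspp_centers(peaks, k),
                          iter.max = 100L, algorithm = "Lloyd")),
          error = function(e) NULL)
        if (is.null(fit)) next  # empty cluster: refit from next restart
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) {
          best <- fit
        }
      }
    }
  })
  if (is.null(best)) stop("k-means failed on every restart", call. = FALSE)
  centroids <- unname(as.matrix(best$centers))
  colnames(centroids) <- mont$labels[seq_len(ncol(centroids))]
  model <- structure(list(centroids = centroids,
                          labels = paste0("state_", seq_len(k)),
                          k = as.integer(k), seed = as.integer(seed),
                          inertia = best$tot.withinss, montage = mont),
                     class = "if_state_model")
  label_states(model, mont)
}

apply_nearest <- function(x, centers) {
  d2 <- sapply(seq_len(nrow(centers)), function(j) {
    rowSums(sweep(x, 2, centers[j, ])^2)
  })
  d2 <- matrix(d2, nrow = nrow(x))
  apply(d2, 1, which.min)  # ties: lowest index (documented tie-break)
}

#' Name states by their leading scalp region
#'
#' Each centroid is labelled by the region set with the highest mean
#' centroid dIF. When two centroids claim the same region, assignment is
#' greedy by margin (difference between best and second-best region mean):
#' the clearer centroid takes the region, the other falls to its best
#' still-free region. Centroids with no positive region dominance, or left
#' without a free region, keep a generic `state_j` name.
#'
#' @param model An `if_state_model`.
#' @param mont Montage providing the region map.
#' @return The model with `labels` filled.
#' @export
label_states <- function(model, mont = model$montage) {
  stopifnot(inherits(model, "if_state_model"))
  regions <- names(mont$region_map)
  score <- sapply(regions, function(rn) {
    rowMeans(model$centroids[, region_indices(mont, rn), drop = FALSE])
  })
  score <- matrix(score, nrow = model$k, dimnames = list(NULL, regions))
  labels <- paste0("state_", seq_len(model$k))
  margin <- apply(score, 1, function(s) {
    o <- sort(s, decreasing = TRUE)
    if (length(o) > 1L) o[1] - o[2] else o[1]
  })
  dominant <- apply(score, 1, max) > 0
  taken <- character(0)
  for (i in order(margin, decreasing = TRUE)) {
    if (!dominant[i]) next
    prefs <- regions[order(score[i, ], decreasing = TRUE)]
    free <- prefs[!prefs %in% taken & score[i, prefs] > 0]
    if (length(free)) {
      labels[i] <- free[1L]
      taken <- c(taken, free[1L])
    }
  }
  model$labels <- labels
  model
}

#' @export
print.if_state_model <- function(x, ...) {
  cat("<if_state_model> k = ", x$k, ", seed = ", x$seed,
      ", inertia = ", format(x$inertia, digits = 6), "\n", sep = "")
  cat("  states: ", paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Segment a recording into microstates
#'
#' The evaluated span runs from the first to the last GF-IF minimum; each
#' inter-minima segment is assigned the state whose centroid is nearest
#' (Euclidean) to the dIF topography at the segment's GF-IF maximum.
#'
#' @param iff An `if_field` with `dif` filled.
#' @param g A `gfif_series` with extrema detected.
#' @param model A fitted `if_state_model`.
#' @return An object of class `if_state_sequence`: data.frame `segments`
#'   (state, start, end, peak — sample indices), `eval_start`, `eval_end`,
#'   `rate`, `k`.
#' @export
assign_segments <- function(iff, g, model) {
  stopifnot(inherits(iff, "if_field"), inherits(g, "gfif_series"),
            inherits(model, "if_state_model"))
  if (length(g$minima) < 2L) {
    too_short_dynamics("need at least two GF-IF minima to segment")
  }
  mins <- g$minima
  maxs <- g$maxima[g$maxima > mins[1L] & g$maxima < mins[length(mins)]]
  n_seg <- length(mins) - 1L
  stopifnot(length(maxs) == n_seg)  # guaranteed by alternation enforcement
  peak_vecs <- t(iff$dif[, maxs, drop = FALSE])
  states <- apply_nearest(peak_vecs, model$centroids)
  segments <- data.frame(state = states,
                         start = mins[-length(mins)],
                         end = mins[-1L],
                         peak = maxs)
  structure(list(segments = segments, eval_start = mins[1L],
                 eval_end = mins[length(mins)], rate = g$rate,
                 k = model$k, labels = model$labels),
            class = "if_state_sequence")
}

eval_duration_s <- function(seq) {
  (seq$eval_end - seq$eval_start) / seq$rate
}

#' Emergence frequency of microstates
#'
#' Number of GF-IF maxima (segments) per second of evaluated recording,
#' overall and per state.
#'
#' @param seq An `if_state_sequence`.
#' @return List with `emergence_all` (events/s) and `emergence` (length-k
#'   vector, events/s).
#' @export
emergence_frequency <- function(seq) {
  stopifnot(inherits(seq, "if_state_sequence"))
  dur <- eval_duration_s(seq)
  counts <- tabulate(seq$segments$state, nbins = seq$k)
  list(emergence_all = nrow(seq$segments) / dur, emergence = counts / dur)
}

#' Occurrence-duration rate of microstates
#'
#' Fraction of the evaluated span occupied by each state's inter-minima
#' segments. The segments tile the span, so the rates sum to exactly 1.
#'
#' @param seq An `if_state_sequence`.
#' @return Length-k numeric vector summing to 1.
#' @export
occurrence_rate <- function(seq) {
  stopifnot(inherits(seq, "if_state_sequence"))
  durs <- seq$segments$end - seq$segments$start
  out <- vapply(seq_len(seq$k), function(s) sum(durs[seq$segments$state == s]),
                numeric(1))
  out / sum(out)
}

#' Microstate transition probability matrix
#'
#' `P[s, s']` is the probability that a segment in state `s` is followed by
#' one in state `s'` (peak-to-peak transitions; self-transitions count).
#' Rows with no outgoing event are all-zero and flagged in the
#' `no_outgoing` attribute.
#'
#' @param seq An `if_state_sequence`.
#' @param k Number of states (defaults to the sequence's).
#' @return k x k matrix; rows with outgoing events sum to 1.
#' @export
transition_matrix <- function(seq, k = seq$k) {
  stopifnot(inherits(seq, "if_state_sequence"))
  s <- seq$segments$state
  if (length(s) < 2L) stop("need at least 2 segments", call. = FALSE)
  tm <- matrix(0, k, k)
  for (i in seq_len(length(s) - 1L)) {
    tm[s[i], s[i + 1L]] <- tm[s[i], s[i + 1L]] + 1
  }
  outgoing <- rowSums(tm)
  ok <- outgoing > 0
  tm[ok, ] <- tm[ok, , drop = FALSE] / outgoing[ok]
  dimnames(tm) <- list(seq$labels[seq_len(k)], seq$labels[seq_len(k)])
  attr(tm, "no_outgoing") <- which(!ok)
  tm
}

#' All per-recording microstate statistics in one call
#'
#' @param seq An `if_state_sequence`.
#' @return An object of class `if_microstate_metrics` with elements
#'   `emergence_all`, `emergence`, `occurrence_rate`, `transition`,
#'   `n_segments`, `labels`, and the per-segment duration vector
#'   `segment_durations_s`.
#' @export
microstate_metrics <- function(seq) {
  em <- emergence_frequency(seq)
  structure(list(emergence_all = em$emergence_all, emergence = em$emergence,
                 occurrence_rate = occurrence_rate(seq),
                 transition = transition_matrix(seq),
                 n_segments = nrow(seq$segments),
                 labels = seq$labels,
                 segment_durations_s =
                   (seq$segments$end - seq$segments$start) / seq$rate),
            class = "if_microstate_metrics")
}

#' @export
print.if_microstate_metrics <- function(x, ...) {
  cat("<if_microstate_metrics> ", x$n_segments, " segments, ",
      format(x$emergence_all, digits = 4), " /s overall\n", sep = "")
  df <- data.frame(state = x$labels,
                   emergence = round(x$emergence, 4),
                   occurrence = round(x$occurrence_rate, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
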