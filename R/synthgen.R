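# Seeded synthetic cohorts: narrowband multichannel oscillations with a
# hidden switching process that makes one scalp region phase-lead (run at a
# higher instantaneous frequency) at a time. Provides ground truth for
# every downstream stage.

#' Parameters for the synthetic-recording generator
#'
#' Defaults emulate eyes-closed resting EEG in the theta/alpha band: 16
#' channels at 200 Hz for 60 s, a base rhythm near the HC group-mean IF
#' (8.6 Hz), a 1-Hz lead boost for the active region, gamma-distributed
#' region dwell times with 0.4-s mean, and pink background noise at 0.3 of
#' the oscillation amplitude. The AD-like condition is modelled as a lower
#' base frequency (7.8 Hz, the slowing-wave effect) and reduced occipital
#' leading occupancy.
#'
#' @param n_channels Number of electrodes (16, montage order).
#' @param rate Sampling rate, samples/s (200).
#' @param duration_s Epoch length, s (60).
#' @param base_freq Base oscillation frequency, Hz (8.6).
#' @param delta_f IF boost of the leading region, Hz (1.0).
#' @param state_priors Named probabilities over the leading regions
#'   (frontal, occipital, left, right); must sum to 1.
#' @param dwell_mean Mean region dwell time, s (0.4).
#' @param dwell_shape Gamma shape of the dwell distribution (2).
#' @param amplitude Oscillation amplitude, uV (20).
#' @param noise_sd Noise SD as a fraction of `amplitude` (0.3).
#' @param noise_color `"pink"` (default) or `"white"`.
#' @param lead_mode `"if"` (phase-velocity boost, default) or `"ia"`
#'   (amplitude boost, for the amplitude-field variant).
#' @param seed Integer RNG seed.
#' @return A list of class `if_synth_params`.
#' @export
synth_params <- function(n_channels = 16, rate = 200, duration_s = 60,
                         base_freq = 8.6, delta_f = 1.0,
                         state_priors = c(frontal = 0.25, occipital = 0.25,
                                          left = 0.25, right = 0.25),
                         dwell_mean = 0.4, dwell_shape = 2,
                         amplitude = 20, noise_sd = 0.3,
                         noise_color = c("pink", "white"),
                         lead_mode = c("if", "ia"), seed = 1L) {
  noise_color <- match.arg(noise_color)
  lead_mode <- match.arg(lead_mode)
  if (abs(sum(state_priors) - 1) > 1e-8 || any(state_priors < 0)) {
    stop("state_priors must be nonnegative and sum to 1", call. = FALSE)
  }
  if (is.null(names(state_priors))) {
    names(state_priors) <- c("frontal", "occipital", "left", "right")
  }
  if (dwell_mean <= 2 / rate) stop("dwell_mean too short", call. = FALSE)
  if (base_freq - delta_f <= 0 || base_freq + delta_f >= rate / 2) {
    stop("base_freq +/- delta_f outside the representable band", call. = FALSE)
  }
  structure(list(n_channels = n_channels, rate = rate,
                 duration_s = duration_s, base_freq = base_freq,
                 delta_f = delta_f, state_priors = state_priors,
                 dwell_mean = dwell_mean, dwell_shape = dwell_shape,
                 amplitude = amplitude, noise_sd = noise_sd,
                 noise_color = noise_color, lead_mode = lead_mode,
                 seed = as.integer(seed)),
            class = "if_synth_params")
}

# 1/f-amplitude noise via FFT shaping, unit variance.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # mirrored frequency index
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Generate one synthetic recording with ground truth
#'
#' A hidden semi-Markov process draws leading regions i.i.d. from
#' `state_priors` with Gamma dwell times. Every channel is
#' `A * cos(phi_c(t))` with `dphi_c/dt = 2 pi (f0 + delta_f)` while the
#' channel belongs to the active region and `2 pi f0` otherwise; phase
#' accumulates continuously across switches, so no broadband transients
#' are introduced. Additive pink (or white) noise completes the signal.
#' The recording is raw (pre-filter), so the full pipeline is exercised.
#'
#' @param params An `if_synth_params`.
#' @param mont Montage supplying the region sets.
#' @param subject_id,group,mmse Metadata for the resulting recording.
#' @return List with `recording` (an `if_recording`) and `truth` (state
#'   schedule data.frame with state/start_s/end_s, per-sample state index,
#'   per-channel true IF matrix, and the parameters).
#' @export
generate_recording <- function(params, mont = default_montage(),
                               subject_id = "synth", group = "unknown",
                               mmse = NA_integer_) {
  stopifnot(inherits(params, "if_synth_params"))
  n <- round(params$duration_s * params$rate)
  regions <- names(params$state_priors)
  withr::with_seed(params$seed, {
    # hidden state schedule
    starts <- numeric(0); states <- integer(0); t0 <- 0
    while (t0 < params$duration_s) {
      starts <- c(starts, t0)
      states <- c(states, sample.int(length(regions), 1L,
                                     prob = params$state_priors))
      t0 <- t0 + stats::rgamma(1, shape = params$dwell_shape,
                               scale = params$dwell_mean / params$dwell_shape)
    }
    ends <- c(starts[-1L], params$duration_s)
    state_of_sample <- states[findInterval((seq_len(n) - 0.5) / params$rate,
                                           starts)]
    lead <- matrix(FALSE, params$n_channels, n)
    for (s in seq_along(regions)) {
      ch <- region_indices(mont, regions[s])
      lead[ch, state_of_sample == s] <- TRUE
    }
    if (params$lead_mode == "if") {
      true_if <- params$base_freq + params$delta_f * lead
      amp <- matrix(params$amplitude, params$n_channels, n)
    } else {
      true_if <- matrix(params$base_freq, params$n_channels, n)
      amp <- params$amplitude * (1 + (params$delta_f / params$base_freq) * lead)
    }
    phase0 <- stats::runif(params$n_channels, 0, 2 * pi)
    phi <- t(apply(true_if, 1, function(f) cumsum(2 * pi * f / params$rate)))
    dat <- amp * cos(phi + phase0)
    noise <- t(vapply(seq_len(params$n_channels), function(i) {
      if (params$noise_color == "pink") pink_noise(n) else stats::rnorm(n)
    }, numeric(n)))
    dat <- dat + params$amplitude * params$noise_sd * noise
  })
  rec <- recording(dat, rate = params$rate, mont = mont,
                   subject_id = subject_id, group = group, mmse = mmse)
  truth <- list(schedule = data.frame(state = regions[states],
                                      start_s = starts, end_s = ends),
                state_of_sample = state_of_sample,
                state_names = regions,
                true_if = true_if, params = params)
  list(recording = rec, truth = truth)
}

#' Default AD-like parameter variant
#'
#' Lower base frequency (7.8 Hz) and occipital leading prior reduced from
#' 0.25 to 0.10 (others renormalized), mimicking the slowing and reduced
#' occipital leading occupancy of the AD-like condition.
#'
#' @param hc_params The HC-condition `if_synth_params` to modify.
#' @param base_freq AD-like base frequency (default 7.8 Hz).
#' @param occipital_prior AD-like occipital prior (default 0.10).
#' @return An `if_synth_params`.
#' @export
ad_variant <- function(hc_params = synth_params(), base_freq = 7.8,
                       occipital_prior = 0.10) {
  p <- unclass(hc_params)
  pri <- p$state_priors
  rest <- setdiff(names(pri), "occipital")
  pri[rest] <- pri[rest] * (1 - occipital_prior) / sum(pri[rest])
  pri["occipital"] <- occipital_prior
  p$base_freq <- base_freq
  p$state_priors <- pri / sum(pri)
  do.call(synth_params, p)
}

#' Generate a synthetic cohort
#'
#' Per-subject seeds are derived deterministically from `seed`. AD-like
#' subjects use `ad_params` and receive integer MMSE scores drawn
#' uniformly from 10-26.
#'
#' @param n_hc,n_ad Group sizes (defaults 18 and 16).
#' @param hc_params,ad_params Generator parameters per condition.
#' @param seed Master seed.
#' @param mont Montage.
#' @return List with `cohort` (data.frame: subject_id, group, mmse, seed),
#'   `recordings` (list of `if_recording`), `truths` (list).
#' @export
generate_cohort <- function(n_hc = 18, n_ad = 16,
                            hc_params = synth_params(),
                            ad_params = ad_variant(hc_params),
                            seed = 1L, mont = default_montage()) {
  if (n_hc < 1L || n_ad < 1L) stop("need at least one subject per group",
                                   call. = FALSE)
  n <- n_hc + n_ad
  subj_seeds <- as.integer((as.numeric(seed) * 7919 + 104729 * seq_len(n)) %%
                             .Machine$integer.max)
  mmse_ad <- withr::with_seed(as.integer(seed),
                              sample(10:26, n_ad, replace = TRUE))
  ids <- c(sprintf("HC%02d", seq_len(n_hc)), sprintf("AD%02d", seq_len(n_ad)))
  groups <- c(rep("HC", n_hc), rep("AD", n_ad))
  mmse <- c(rep(NA_integer_, n_hc), mmse_ad)
  recs <- vector("list", n); truths <- vector("list", n)
  for (i in seq_len(n)) {
    base <- if (groups[i] == "HC") hc_params else ad_params
    p <- unclass(base); p$seed <- subj_seeds[i]
    pars <- do.call(synth_params, p)
    g <- generate_recording(pars, mont = mont, subject_id = ids[i],
                            group = groups[i], mmse = mmse[i])
    recs[[i]] <- g$recording
    truths[[i]] <- g$truth
  }
  cohort <- data.frame(subject_id = ids, group = groups, mmse = mmse,
                       seed = subj_seeds, stringsAsFactors = FALSE)
  list(cohort = cohort, recordings = recs, truths = truths)
}

#' Write a synthetic cohort to disk (csv recordings + manifest + truth)
#'
#' @param cohort_data Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"edf"` recordings.
#' @return Path of the written manifest.
#' @export
write_cohort <- function(cohort_data, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cohort_data$cohort
  files <- paste0(tab$subject_id, ".", format)
  for (i in seq_len(nrow(tab))) {
    rec <- cohort_data$recordings[[i]]
    if (format == "csv") {
      write_recording_csv(rec, file.path(dir, files[i]))
    } else {
      write_edf(rec$data, file.path(dir, files[i]), rate = rec$rate,
                labels = rownames(rec$data))
    }
  }
  manifest <- data.frame(subject_id = tab$subject_id, path = files,
                         group = tab$group, mmse = tab$mmse)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.table(manifest, mpath, sep = ",", row.names = FALSE,
                     quote = FALSE)
  truths <- lapply(cohort_data$truths, function(tr) {
    list(schedule = tr$schedule, params = unclass(tr$params))
  })
  names(truths) <- tab$subject_id
  jsonlite::write_json(truths, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(mpath)
}
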