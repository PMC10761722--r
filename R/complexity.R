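# GF-IF dynamics characterisation: Welch power spectra, multiscale sample
# entropy, and IAAFT surrogate comparison.

#' Welch power spectral density on a fine low-frequency grid
#'
#' Welch's method with Hann windows (default 5 s), 50% overlap, and segment
#' FFTs zero-padded so the evaluated grid is exactly `fmin..fmax` in steps
#' of `df` (default 0.001 to 1 Hz in 0.001-Hz bins, i.e. 1000 bins). Power
#' is one-sided and reported in dB/Hz.
#'
#' @param x Numeric series (e.g. a GF-IF trace).
#' @param rate Sampling rate, samples/s.
#' @param window_s Window length in seconds (default 5).
#' @param overlap Fractional overlap between windows (default 0.5).
#' @param fmin,fmax,df Frequency grid in Hz.
#' @return Object of class `if_psd`: `freqs` (Hz), `power` (dB/Hz).
#' @export
welch_psd <- function(x, rate, window_s = 5, overlap = 0.5,
                      fmin = 0.001, fmax = 1, df = 0.001) {
  nwin <- round(window_s * rate)
  if (length(x) < nwin) {
    stop("series (", length(x), " samples) shorter than one ", window_s,
         "-s window", call. = FALSE)
  }
  nfft <- round(rate / df)
  bins <- round(seq(fmin, fmax, by = df) / df)
  if (max(bins) > nfft / 2) stop("fmax exceeds Nyquist", call. = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))  # Hann
  hop <- max(1L, floor(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  scale <- 1 / (rate * sum(w^2))
  acc <- numeric(length(bins))
  for (s0 in starts) {
    seg <- x[s0:(s0 + nwin - 1L)] * w
    X <- stats::fft(c(seg, numeric(nfft - nwin)))
    acc <- acc + Mod(X[bins + 1L])^2
  }
  pxx <- 2 * scale * acc / length(starts)  # one-sided, interior bins
  structure(list(freqs = bins * df, power = 10 * log10(pxx)),
            class = "if_psd")
}

#' Coarse-grain a series at temporal scale tau
#'
#' Non-overlapping block means of length `tau`; the trailing remainder is
#' dropped, so the output has `floor(N / tau)` samples.
#'
#' @param y Numeric series.
#' @param tau Integer scale >= 1.
#' @return Numeric vector of block means.
#' @export
coarse_grain <- function(y, tau) {
  tau <- as.integer(tau)
  if (tau < 1L) stop("tau must be >= 1", call. = FALSE)
  if (tau > length(y)) stop("tau exceeds series length", call. = FALSE)
  if (tau == 1L) return(y)
  nb <- length(y) %/% tau
  colMeans(matrix(y[seq_len(nb * tau)], nrow = tau))
}

#' Sample entropy
#'
#' `SampEn(m, r) = -log(C_{m+1}(r) / C_m(r))`, where `C_m(r)` is the
#' fraction of template pairs (i != j) whose m-length vectors lie within
#' `r` under the Chebyshev (max-coordinate) norm; self-matches are
#' excluded. With `normalize = TRUE` (default) the series is z-scored
#' first, so `r` is a fraction of its SD. Returns `NA` (flagged, not
#' silently zero) when no (m+1)-template pair matches.
#'
#' @param x Numeric series.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance (default 0.2; a fraction of SD when normalizing).
#' @param normalize Z-score `x` before matching (default TRUE).
#' @return Nonnegative scalar, or `NA_real_` if undefined.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2, normalize = TRUE) {
  if (length(x) <= m + 1L) stop("series too short for m = ", m, call. = FALSE)
  if (r <= 0) stop("r must be positive", call. = FALSE)
  if (normalize) {
    s <- stats::sd(x)
    if (s < 1e-300) return(0)  # constant series: perfectly regular
    x <- (x - mean(x)) / s
  }
  cnt <- .sampen_counts(as.numeric(x), as.integer(m), r)
  if (cnt[1] == 0) return(NA_real_)  # no m-matches: C_m = 0
  if (cnt[2] == 0) return(NA_real_)  # no (m+1)-matches
  -log(cnt[2] / cnt[1])
}

#' Multiscale entropy profile
#'
#' Sample entropy of the coarse-grained series at scales 1..`max_scale`.
#' The series is z-scored once at scale 1 and the tolerance `r` is held
#' fixed across scales (the Costa convention), so entropy changes across
#' scales reflect the dynamics, not a moving tolerance.
#'
#' @param x Numeric series.
#' @param max_scale Largest temporal scale (default 20).
#' @param m,r Sample-entropy parameters (defaults 2, 0.2).
#' @return Object of class `if_mse`: `scales`, `sampen` (NA where
#'   undefined), `m`, `r`, `n`.
#' @export
mse_profile <- function(x, max_scale = 20, m = 2, r = 0.2) {
  n <- length(x)
  if (n %/% max_scale <= m + 1L) {
    stop("series too short for max_scale = ", max_scale, call. = FALSE)
  }
  s <- stats::sd(x)
  if (s < 1e-300) stop("constant series has no MSE profile", call. = FALSE)
  z <- (x - mean(x)) / s
  sampen <- vapply(seq_len(max_scale), function(tau) {
    sample_entropy(coarse_grain(z, tau), m = m, r = r, normalize = FALSE)
  }, numeric(1))
  structure(list(scales = seq_len(max_scale), sampen = sampen, m = m, r = r,
                 n = n), class = "if_mse")
}

#' IAAFT surrogate series
#'
#' Iterative amplitude-adjusted Fourier transform surrogate: alternately
#' (a) impose the original Fourier amplitude spectrum on the current
#' series while keeping its phases, and (b) rank-remap the values onto the
#' sorted original. A fixed number of iterations is run, ending on the
#' rank step, so the surrogate's value multiset equals the original's
#' exactly while its power spectrum matches approximately. Surrogates are
#' the null model for linear-stochastic dynamics with the same amplitude
#' distribution.
#'
#' @param x Numeric series (length >= 16).
#' @param iterations Number of IAAFT iterations (default 100).
#' @param seed Integer seed for the initial random shuffle.
#' @return Numeric series, same length as `x`.
#' @export
iaaft_surrogate <- function(x, iterations = 100, seed = 1L) {
  n <- length(x)
  if (n < 16L) stop("series too short for a surrogate", call. = FALSE)
  amp <- Mod(fft_any(x))
  xs <- sort(x)
  s <- withr::with_seed(as.integer(seed), sample(x))
  for (it in seq_len(iterations)) {
    S <- fft_any(s)
    s2 <- Re(fft_any(amp * exp(1i * Arg(S)), inverse = TRUE)) / n
    s <- xs[rank(s2, ties.method = "first")]
  }
  s
}

#' Original-vs-surrogate multiscale entropy comparison
#'
#' Computes the MSE profile of `x` and of `n_surr` IAAFT surrogates
#' (seeds `base_seed .. base_seed + n_surr - 1`). The per-scale surrogate
#' profiles feed a paired test downstream: surrogate entropy exceeding the
#' original at small scales is the signature of deterministic structure
#' that surrogates (which keep only linear correlations) cannot reproduce.
#'
#' @param x Numeric series.
#' @param n_surr Number of surrogates (default 10).
#' @param iterations IAAFT iterations per surrogate (default 100).
#' @param max_scale,m,r MSE parameters.
#' @param base_seed First surrogate seed.
#' @return Object of class `if_surrogate_result`: `original_mse`,
#'   `surrogate_mse` (n_surr x max_scale matrix), `surrogate_mse_mean`,
#'   `n_surr`, `iterations`, `seeds`.
#' @export
surrogate_comparison <- function(x, n_surr = 10, iterations = 100,
                                 max_scale = 20, m = 2, r = 0.2,
                                 base_seed = 1L) {
  if (n_surr < 2L) stop("need at least 2 surrogates", call. = FALSE)
  orig <- mse_profile(x, max_scale = max_scale, m = m, r = r)
  seeds <- as.integer(base_seed) + seq_len(n_surr) - 1L
  sm <- t(vapply(seeds, function(sd_i) {
    mse_profile(iaaft_surrogate(x, iterations = iterations, seed = sd_i),
                max_scale = max_scale, m = m, r = r)$sampen
  }, numeric(max_scale)))
  structure(list(original_mse = orig, surrogate_mse = sm,
                 surrogate_mse_mean = colMeans(sm), n_surr = n_surr,
                 iterations = iterations, seeds = seeds),
            class = "if_surrogate_result")
}
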