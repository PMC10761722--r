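# Shared fixtures and independent oracles used across test files.

# Brute-force sample-entropy oracle: direct double loop over template
# pairs, independent of the package's compiled kernel. Returns the pair
# counts (B = m-matches, A = (m+1)-matches) and the entropy.
sampen_oracle <- function(x, m = 2, r = 0.2, normalize = TRUE) {
  if (normalize) x <- (x - mean(x)) / stats::sd(x)
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) < r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) < r) A <- A + 1L
      }
    }
  }
  list(B = B, A = A,
       sampen = if (B == 0L || A == 0L) NA_real_ else -log(A / B))
}

# Planted dIF topographies for the four default regions (unit lead boost,
# channel-mean removed), in montage order.
planted_topographies <- function(delta_f = 1, mont = default_montage()) {
  regions <- c("frontal", "occipital", "left", "right")
  out <- t(vapply(regions, function(rn) {
    v <- delta_f * (mont$labels %in% mont$region_map[[rn]])
    v - mean(v)
  }, numeric(length(mont$labels))))
  rownames(out) <- regions
  out
}

# Best one-to-one matching of centroids to planted rows by enumerating all
# permutations (k <= 5); returns the permutation (planted i -> centroid
# perm[i]) maximising the mean Pearson correlation, plus the matched
# correlations.
match_centroids <- function(planted, centroids) {
  k <- nrow(planted)
  cors <- outer(seq_len(k), seq_len(k), Vectorize(function(a, b) {
    stats::cor(planted[a, ], centroids[b, ])
  }))
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == k), ,
                 drop = FALSE]
  scores <- apply(perms, 1, function(p) mean(cors[cbind(seq_len(k), p)]))
  best <- perms[which.max(scores), ]
  list(perm = best, cors = cors[cbind(seq_len(k), best)])
}

# A tone recording: every channel the same sinusoid (plus optional noise).
tone_recording <- function(freq = 10, rate = 200, duration_s = 20,
                           amplitude = 1, noise_sd = 0, seed = 1,
                           mont = default_montage()) {
  n <- round(duration_s * rate)
  t_s <- (seq_len(n) - 1) / rate
  base <- amplitude * cos(2 * pi * freq * t_s)
  dat <- withr::with_seed(seed, {
    t(vapply(seq_along(mont$labels), function(i) {
      base + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    }, numeric(n)))
  })
  recording(dat, rate = rate, mont = mont, subject_id = "tone")
}

# Offset from an index in the IF/GF-IF series back to the raw recording
# sample grid: trim_edges drops trim_s * rate samples, the IF central
# difference drops one more.
raw_sample_offset <- function(rate, trim_s = 5) round(trim_s * rate) + 1L
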