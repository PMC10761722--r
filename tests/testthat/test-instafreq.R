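test_that("analytic phase of a cosine advances at the tone frequency", {
  rate <- 200; freq <- 10
  rec <- tone_recording(freq, rate, duration_s = 10, amplitude = 2)
  ph <- instantaneous_phase(rec)
  expect_true(all(abs(ph$theta) <= pi + 1e-12))
  d <- diff(ph$theta[1, 200:1800])
  d <- d - 2 * pi * round(d / (2 * pi))
  expect_equal(d, rep(2 * pi * freq / rate, length(d)), tolerance = 1e-3)
  # envelope recovers the amplitude away from edges
  expect_equal(ph$amplitude[1, 400:1600], rep(2, 1201), tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("constant channels are rejected as degenerate", {
  dat <- matrix(stats::rnorm(16 * 600), 16)
  dat[5, ] <- 0
  expect_error(instantaneous_phase(recording(dat, 100)), "degenerate")
})

test_that("IF of a pure 10 Hz tone is 10 Hz within 0.05 Hz in the interior", {
  rate <- 200
  rec <- tone_recording(10, rate, duration_s = 20)
  iff <- instantaneous_frequency(instantaneous_phase(rec))
  n <- ncol(iff$iff)
  inner <- iff$iff[1, round(0.5 * rate):(n - round(0.5 * rate))]
  expect_lt(max(abs(inner - 10)), 0.05)
})

test_that("IF tracks a linear 4-13 Hz chirp with interior RMSE < 0.1 Hz", {
  rate <- 200; dur <- 50
  n <- dur * rate
  t_s <- (seq_len(n) - 1) / rate
  f0 <- 4; f1 <- 13; k <- (f1 - f0) / dur
  phase <- 2 * pi * (f0 * t_s + k * t_s^2 / 2)
  dat <- matrix(rep(cos(phase), each = 16), nrow = 16)
  # tiny jitter so channels are not bit-identical constants after ops
  rec <- recording(dat, rate)
  iff <- instantaneous_frequency(instantaneous_phase(rec))
  f_true <- (f0 + k * t_s)[2:(n - 1)]  # central-difference grid
  m <- ncol(iff$iff)
  keep <- round(2 * rate):(m - round(2 * rate))
  rmse <- sqrt(mean((iff$iff[1, keep] - f_true[keep])^2))
  expect_lt(rmse, 0.1)
})

test_that("median filtering suppresses phase-slip excursions of a two-tone signal", {
  rate <- 200; dur <- 20
  t_s <- (seq_len(dur * rate) - 1) / rate
  x <- cos(2 * pi * 6 * t_s) + 0.95 * cos(2 * pi * 12 * t_s)
  dat <- matrix(rep(x, each = 16), nrow = 16)
  ph <- instantaneous_phase(recording(dat, rate))
  # unfiltered central-difference IF has slip excursions ...
  u <- diff(ph$theta[1, ])
  u <- u - 2 * pi * round(u / (2 * pi))
  expect_true(any(u < 0))  # non-monotone phase: slips exist
  # ... the filtered IF does not leave the representable band
  iff <- instantaneous_frequency(ph)
  inner <- iff$iff[1, 100:(ncol(iff$iff) - 100)]
  expect_true(all(inner > 0 & inner < rate / 2))
  expect_lt(stats::sd(inner), stats::sd(((rate / (2 * pi)) *
    (u[-1] + u[-length(u)]) / 2)[100:(length(u) - 100)]))
})

test_that("deviation field removes the spatial mean and keeps the spread", {
  rate <- 200
  rec <- tone_recording(10, rate, duration_s = 10)
  iff <- deviation_field(instantaneous_frequency(instantaneous_phase(rec)))
  expect_lt(max(abs(iff$dif)), 1e-9)  # identical channels
  expect_lt(max(abs(colSums(iff$dif))), 1e-9)

  # O1, O2 at 11 Hz, the rest at 9 Hz: closed-form deviations
  mont <- default_montage()
  n <- 10 * rate
  t_s <- (seq_len(n) - 1) / rate
  dat <- t(vapply(seq_along(mont$labels), function(i) {
    f <- if (mont$labels[i] %in% c("O1", "O2")) 11 else 9
    cos(2 * pi * f * t_s)
  }, numeric(n)))
  iff2 <- deviation_field(instantaneous_frequency(instantaneous_phase(
    recording(dat, rate))))
  mid <- 400:1200
  o_idx <- match(c("O1", "O2"), mont$labels)
  expect_equal(rowMeans(iff2$dif[o_idx, mid]), rep(2 * 14 / 16, 2),
               tolerance = 0.01, ignore_attr = TRUE)
  expect_equal(rowMeans(iff2$dif[-o_idx, mid]), rep(-2 * 2 / 16, 14),
               tolerance = 0.01, ignore_attr = TRUE)
  expect_lt(max(abs(colSums(iff2$dif))), 1e-9)

  # GF-IF equals the closed-form population SD of the two-level pattern
  g <- gfif_series(iff2, detect = FALSE)
  sd_true <- sqrt((2 * (2 * 14 / 16)^2 + 14 * (2 * 2 / 16)^2) / 16)
  expect_equal(stats::median(g$gfif[mid]), sd_true, tolerance = 0.01)
})

test_that("SD of dIF equals SD of IF at every sample", {
  g <- generate_recording(synth_params(duration_s = 20, seed = 3))
  p <- process_recording(g$recording)
  sd_if <- apply(p$iff$iff, 2, function(v) sqrt(mean((v - mean(v))^2)))
  sd_dif <- apply(p$iff$dif, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(sd_if, sd_dif, tolerance = 1e-12)
})

test_that("time-shifted input shifts IF and GF-IF in the interior", {
  rate <- 200; s <- 40
  g <- generate_recording(synth_params(duration_s = 14, seed = 9,
                                       noise_sd = 0))
  dat <- g$recording$data
  rec1 <- recording(dat[, 1:(rate * 12)], rate)
  rec2 <- recording(dat[, (s + 1):(rate * 12 + s)], rate)
  cfg <- pipeline_config(); cfg$trim_s <- 2
  p1 <- process_recording(rec1, cfg); p2 <- process_recording(rec2, cfg)
  # the finite-window Hilbert transform is only approximately
  # shift-equivariant: boundary leakage decays away from the edges, so the
  # comparison uses a 3-s interior margin and a tolerance far below the
  # signal scale (IF ~ 8.6 +/- 0.56 Hz)
  n <- length(p1$gfif$gfif)
  keep <- 600:(n - 600 - s)
  expect_lt(max(abs(p1$gfif$gfif[keep + s] - p2$gfif$gfif[keep])), 0.01)
  expect_lt(max(abs(p1$iff$iff[, keep + s] - p2$iff$iff[, keep])), 0.05)
})

test_that("amplitude-field variant reuses the pipeline unchanged", {
  g <- generate_recording(synth_params(duration_s = 12, seed = 5,
                                       lead_mode = "ia"))
  cfg <- pipeline_config(); cfg$field <- "ia"
  p <- process_recording(g$recording, cfg)
  expect_equal(nrow(p$iff$dif), 16)
  expect_lt(max(abs(colSums(p$iff$dif))), 1e-6)
  expect_true(length(p$gfif$maxima) > 0)
})
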