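test_that("generator parameters are validated", {
  expect_error(synth_params(state_priors = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(synth_params(dwell_mean = 0.001), "dwell")
  expect_error(synth_params(base_freq = 120), "band")
  expect_error(generate_cohort(n_hc = 0, n_ad = 2), "at least one")
})

test_that("same seed gives a bit-identical recording", {
  p <- synth_params(duration_s = 6, seed = 42)
  g1 <- generate_recording(p)
  g2 <- generate_recording(p)
  expect_identical(g1$recording$data, g2$recording$data)
  expect_identical(g1$truth$schedule, g2$truth$schedule)
  g3 <- generate_recording(synth_params(duration_s = 6, seed = 43))
  expect_false(identical(g1$recording$data, g3$recording$data))
})

test_that("no structure (delta_f = 0, no noise) yields a flat GF-IF", {
  g <- generate_recording(synth_params(duration_s = 12, delta_f = 0,
                                       noise_sd = 0, seed = 1))
  p <- process_recording(g$recording)
  # finite-window Hilbert edge effects leave small deviations at the very
  # ends; the interior GF-IF is flat
  n <- length(p$gfif$gfif)
  expect_lt(max(p$gfif$gfif[200:(n - 200)]), 0.05)
})

test_that("pipeline IF on lead channels matches the planted trajectory", {
  pars <- synth_params(duration_s = 30, seed = 14, noise_sd = 0.1)
  g <- generate_recording(pars)
  p <- process_recording(g$recording)
  offset <- raw_sample_offset(pars$rate)
  mont <- default_montage()
  sched <- g$truth$schedule
  # intervals >= 0.5 s whose interior lies inside the evaluated span
  long <- sched[sched$end_s - sched$start_s >= 0.5 &
                  sched$start_s > 5.2 & sched$end_s < 25, ]
  expect_gt(nrow(long), 3)
  errs <- vapply(seq_len(nrow(long)), function(i) {
    ch <- match(mont$region_map[[long$state[i]]], mont$labels)
    s0 <- round((long$start_s[i] + 0.1) * pars$rate) - offset
    s1 <- round((long$end_s[i] - 0.1) * pars$rate) - offset
    mean(p$iff$iff[ch, s0:s1]) - (pars$base_freq + pars$delta_f)
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.1)
})

test_that("state occupancy converges to the priors over long durations", {
  pars <- synth_params(duration_s = 600,
                       state_priors = c(frontal = 0.4, occipital = 0.3,
                                        left = 0.2, right = 0.1), seed = 4)
  g <- generate_recording(pars)
  sched <- g$truth$schedule
  dur <- sched$end_s - sched$start_s
  occ <- tapply(dur, sched$state, sum)[names(pars$state_priors)] / sum(dur)
  expect_true(all(abs(occ - pars$state_priors) < 0.03))
})

test_that("generated phase is continuous across state switches", {
  g <- generate_recording(synth_params(duration_s = 10, noise_sd = 0,
                                       seed = 6))
  ph <- instantaneous_phase(bandpass_filter(recording(g$recording$data, 200)))
  d <- diff(ph$theta[1, 100:1900])
  d <- d - 2 * pi * round(d / (2 * pi))
  expect_lt(max(abs(d)), 2 * pi * 13 / 200 + 0.05)
})

test_that("cohorts have the right sizes, labels, MMSE ranges, and determinism", {
  ch <- generate_cohort(n_hc = 3, n_ad = 2, seed = 5,
                        hc_params = synth_params(duration_s = 6))
  expect_equal(nrow(ch$cohort), 5)
  expect_identical(ch$cohort$group, c(rep("HC", 3), rep("AD", 2)))
  expect_true(all(is.na(ch$cohort$mmse[1:3])))
  expect_true(all(ch$cohort$mmse[4:5] >= 10 & ch$cohort$mmse[4:5] <= 26))
  ch2 <- generate_cohort(n_hc = 3, n_ad = 2, seed = 5,
                         hc_params = synth_params(duration_s = 6))
  expect_identical(ch$recordings[[4]]$data, ch2$recordings[[4]]$data)
})

test_that("the AD-like variant slows the rhythm and starves the occipital prior", {
  hc <- synth_params()
  ad <- ad_variant(hc)
  expect_equal(ad$base_freq, 7.8)
  expect_equal(unname(ad$state_priors["occipital"]), 0.10)
  expect_equal(sum(ad$state_priors), 1)
  expect_equal(unname(ad$state_priors["frontal"]),
               unname(ad$state_priors["left"]))
})

test_that("written cohorts round-trip through the manifest reader", {
  dir <- withr::local_tempdir()
  ch <- generate_cohort(n_hc = 2, n_ad = 1, seed = 3,
                        hc_params = synth_params(duration_s = 5))
  man <- write_cohort(ch, dir)
  tab <- read_cohort(man)
  expect_equal(nrow(tab), 3)
  rec <- read_recording(tab$path[1], rate = 200,
                        subject_id = tab$subject_id[1], group = tab$group[1])
  expect_equal(rec$data, ch$recordings[[1]]$data, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})
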