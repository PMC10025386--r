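test_that("the PSTH is exact count arithmetic", {
  grid <- time_grid(-200, 800)
  trials <- dplyr::bind_rows(lapply(1:100, function(k)
    tibble::tibble(trial = k, spike_times = list(10))))
  x <- list(trials = trials, grid = grid)
  psth <- compute_psth(x, bin_ms = 20)
  hit <- psth$t_ms == 0
  expect_equal(psth$rate_hz[hit], 50)  # one spike per 20 ms bin
  expect_equal(sum(psth$rate_hz[!hit]), 0)

  silent <- make_fixture_raster("silent")
  expect_equal(sum(compute_psth(silent)$rate_hz), 0)

  # conservation: sum(rate * bin) = mean spike count per trial
  tonic <- make_fixture_raster("tonic", n_trials = 30, seed = 2)
  psth_t <- compute_psth(tonic)
  expect_equal(sum(psth_t$rate_hz) * 0.02,
               mean(vapply(tonic$trials$spike_times, length, numeric(1))),
               tolerance = 1e-9)
})

test_that("CR detection uses a strict 25% criterion", {
  expect_true(detect_cr(0.2 * 80, 80))
  expect_false(detect_cr(0.25 * 80, 80))  # boundary: not a CR
  expect_false(detect_cr(80, 80))
  # monotone: lowering the rate never un-detects
  expect_true(all(detect_cr(seq(0, 19.9, 0.1), 80)))
})

test_that("acquisition is censored without an inhibition mechanism", {
  sess <- run_session(session_config(delay_protocol(200), n_trials = 25,
                                     seed = 1, params = pot_params(g_i = 1e-9)))
  expect_true(is.na(acquisition_trial(sess)))

  sess90 <- run_session(session_config(delay_protocol(90), n_trials = 25,
                                       seed = 1))
  expect_true(is.na(acquisition_trial(sess90)))
})

test_that("acquisition ignores trials after the detected index", {
  sess <- tiny_session(n_trials = 40, seed = 6)
  ct <- cr_trials(sess)
  acq <- acquisition_trial(sess)
  if (!is.na(acq)) {
    # recomputing on the truncated session gives the same index
    trunc <- sess
    trunc$trials <- sess$trials[1:acq, ]
    expect_equal(acquisition_trial(trunc), acq, ignore_attr = TRUE)
  }
  expect_equal(attr(ct, "baseline_hz"), mean(ct$rate_hz[1:5]))
})

test_that("pause features recover a rectangular trough", {
  x <- make_fixture_raster("single-pause", n_trials = 200, rate_hz = 80,
                           seed = 1)
  psth <- compute_psth(x)
  f <- pause_features(psth)
  expect_equal(f$onset_ms, 100)
  expect_equal(f$offset_ms, 300)
  expect_gt(f$maximum_ms, 100)
  expect_lt(f$maximum_ms, 300)

  flat <- compute_psth(make_fixture_raster("tonic", n_trials = 200, seed = 2))
  expect_true(is.na(pause_features(flat)$onset_ms))
})

test_that("bimodal detection counts disjoint sub-50% runs", {
  x2 <- make_fixture_raster("double-pause", n_trials = 200, seed = 3)
  b2 <- detect_bimodal_pause(compute_psth(x2))
  expect_equal(nrow(b2), 2)
  expect_equal(b2$onset_ms, c(100, 400))

  x1 <- make_fixture_raster("single-pause", n_trials = 200, seed = 3)
  expect_equal(nrow(detect_bimodal_pause(compute_psth(x1))), 1)
})

test_that("the acquisition-law fit recovers exact synthetic slopes", {
  pts <- tibble::tibble(isi = c(200, 400, 600, 800), iti = 15000)
  pts$trials_to_acquisition <- 8000 * pts$isi / pts$iti
  fit <- fit_acquisition_law(pts)
  expect_equal(fit$slope, 8000, tolerance = 1e-9)
  expect_equal(fit$n, 4)

  pts$trials_to_acquisition <- NA_real_
  expect_error(fit_acquisition_law(pts), "non-censored")
})
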