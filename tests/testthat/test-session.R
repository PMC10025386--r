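test_that("a reference paired trial writes, reads, and stores one batch", {
  p <- pot_params()
  proto <- delay_protocol(200)
  grid <- potcell:::default_grid(list(proto))
  st <- new_state(p, reserve_level = 0.5)
  set.seed(1)
  out <- run_trial(st, proto, grid, p)
  r <- out$result

  # both switches detect the CS within tens of ms of onset
  expect_equal(r$write_on_ms, 20)
  expect_equal(r$read_on_ms, 20)
  expect_true(r$batch_stored)
  expect_gt(r$batch_mass, 0)
  # the batch encodes the interval: all stored mass lies below ~US + spread
  enc <- seq(0, p$t_max)
  mass <- out$state$archive$mass
  expect_gt(sum(mass[enc <= 320]) / sum(mass), 0.95)
})

test_that("probe trials read but store nothing; short intervals are discarded", {
  p <- pot_params()
  proto <- delay_protocol(200)
  grid <- potcell:::default_grid(list(proto))
  st <- new_state(p, reserve_level = 0.5)
  st$archive$mass[151] <- 0.01
  set.seed(1)
  out <- run_trial(st, proto, grid, p, probe = TRUE)
  expect_false(out$result$batch_stored)
  expect_gt(out$result$read_mass, 0)          # the learned pause is still read
  expect_gt(max(out$inhibition), 0)
  expect_gt(out$state$abandoned, 0)           # probe writes are abandoned

  # ISI 90 < 100 ms: ejection happens but the batch is discarded
  proto90 <- delay_protocol(90)
  grid90 <- potcell:::default_grid(list(proto90))
  st2 <- new_state(p, reserve_level = 0.5)
  set.seed(1)
  out2 <- run_trial(st2, proto90, grid90, p)
  expect_false(out2$result$batch_stored)
  expect_equal(sum(out2$state$archive$mass), 0)
  expect_gt(out2$state$discarded, 0)
})

test_that("the intertrial interval replenishes, diffuses, and preserves memory", {
  p <- pot_params()
  st <- new_state(p)
  st$archive$mass[201] <- 0.02

  st15 <- advance_iti(st, 15000, p)
  expect_equal(st15$reserve$level, 1.875e-3, tolerance = 1e-12)
  st30 <- advance_iti(st, 30000, p)
  expect_equal(st30$reserve$level, 3.75e-3, tolerance = 1e-12)

  # archive mass persists across the interval (diffusion conserves it)
  expect_equal(sum(st15$archive$mass), 0.02, tolerance = 1e-12)
})

test_that("paired training grows the archive; sessions are bit-reproducible", {
  sess <- tiny_session(n_trials = 30, seed = 4)
  expect_equal(nrow(sess$trials), 30)
  expect_gt(dplyr::last(sess$trials$archive_total),
            sess$trials$archive_total[1])
  # reserve grows through the session (replenishment-limited regime)
  expect_gt(dplyr::last(sess$trials$reserve_level),
            sess$trials$reserve_level[5])

  again <- tiny_session(n_trials = 30, seed = 4)
  expect_identical(sess$trials, again$trials)
  expect_identical(sess$state$archive$mass, again$state$archive$mass)
})

test_that("the full mass ledger balances to 1e-9", {
  sess <- run_session(session_config(delay_protocol(200), n_trials = 60,
                                     probe_every = 10, probe_start = 20,
                                     seed = 2))
  expect_lt(mass_ledger_error(sess$state), 1e-9)

  # and with discarded batches in the mix
  sess90 <- run_session(session_config(delay_protocol(90), n_trials = 40,
                                       seed = 2))
  expect_lt(mass_ledger_error(sess90$state), 1e-9)
  expect_gt(sess90$state$discarded, 0)
})

test_that("CS-only trials deplete the archive geometrically", {
  trained <- tiny_session(n_trials = 50, seed = 3)
  pre <- sum(trained$state$archive$mass)
  ext_cfg <- session_config(
    trial_protocol(cs = stimulus_spec(0, 300, 100, "cs"), label = "cs_only"),
    n_trials = 25, seed = 5)
  ext <- run_session(ext_cfg, state = trained$state)
  post <- sum(ext$state$archive$mass)
  expect_equal(post, pre * (1 - 0.03)^25, tolerance = 1e-9)
})

test_that("two CS trains in one trial trigger the write switch only once", {
  proto <- trial_protocol(
    cs = list(stimulus_spec(0, 100, 100, "cs"),
              stimulus_spec(300, 100, 100, "cs")),
    us = stimulus_spec(500, 20, 500, "us"), label = "two_cs")
  sess <- run_session(session_config(proto, n_trials = 10, seed = 1))
  # one write activation per trial: the refractory period hides the second CS
  expect_equal(sess$state$n_writes, 10L)
  expect_equal(unique(sess$trials$write_on_ms), 20)
  # the batch therefore encodes the long interval: mass concentrated between
  # the second CS and the US
  enc <- seq(0, pot_params()$t_max)
  mass <- sess$state$archive$mass
  expect_gt(sum(mass[enc >= 200 & enc <= 600]) / sum(mass), 0.8)
})

test_that("interleaving alternates protocols and probes follow the schedule", {
  cfg <- session_config(list(delay_protocol(200), delay_protocol(500)),
                        n_trials = 8, iti = 30000, seed = 1)
  sess <- run_session(cfg)
  expect_equal(sess$trials$protocol,
               rep(c("delay_isi200", "delay_isi500"), 4))

  cfg2 <- session_config(delay_protocol(200), n_trials = 50,
                         probe_every = 10, probe_start = 20, seed = 1)
  sess2 <- run_session(cfg2)
  expect_equal(which(sess2$trials$is_probe), c(30, 40, 50))
})

test_that("jittered replicates vary the sampled parameters and keep metrics sane", {
  cfg <- session_config(delay_protocol(200), n_trials = 12, seed = 7)
  reps <- run_replicates(cfg, n_reps = 3,
                         jitter = c(tau_write = 0.1, r_i = 0.1))
  expect_length(reps$sessions, 3)
  draws <- reps$draws[reps$draws$parameter == "tau_write", ]
  expect_equal(nrow(draws), 3)
  expect_gt(stats::sd(draws$value), 0)
  expect_true(all(abs(draws$value / 70 - 1) <= 0.1))

  # zero jitter: dynamics identical up to the pacemaker seed
  reps0 <- run_replicates(cfg, n_reps = 2, jitter = c(tau_write = 0))
  expect_equal(reps0$sessions[[1]]$trials$archive_total,
               reps0$sessions[[2]]$trials$archive_total, tolerance = 1e-12)
})
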