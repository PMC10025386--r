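test_that("activation energy decays, accumulates, and crosses on a spike step", {
  sp <- switch_params(tau = 70, ae_thresh = 2)
  st <- switch_state(sp)

  # 100 Hz drive: spikes every 10 ms. Closed form says the energy after the
  # second spike is exp(-10/70) + 1 = 1.867 < 2, so activation happens on
  # the THIRD spike, 20 ms after the first.
  t_act <- NA
  for (step in 0:30) {
    st <- step_switch(st, sp, cs_spike = as.integer(step %% 10 == 0), dt = 1)
    if (st$activated && is.na(t_act)) t_act <- step
  }
  expect_equal(t_act, 20)

  # matches the independent closed-form accumulation
  ae2 <- exp(-10 / 70) + 1
  expect_lt(ae2, 2)
  expect_gte(ae2 * exp(-10 / 70) + 1, 2)

  # event-driven path agrees
  expect_equal(potcell:::switch_activation_time(seq(0, 290, 10), sp), 20)
  rp <- switch_params(tau = 200, ae_thresh = 2)
  expect_equal(potcell:::switch_activation_time(seq(0, 290, 10), rp), 20)
})

test_that("energy relaxes to baseline and refractory blocks activation", {
  sp <- switch_params(tau = 70, ae_thresh = 2, refractory = 1000)
  st <- switch_state(sp)
  st$ae <- 1
  for (i in 1:350) st <- step_switch(st, sp, 0, 1)  # 5 tau
  expect_lt(abs(st$ae - sp$ae0), 0.01)

  # a train arriving entirely inside the refractory period never activates
  st <- switch_state(sp)
  st$refractory_remaining <- 1000
  acts <- 0
  for (i in 1:100) {
    st <- step_switch(st, sp, as.integer(i %% 5 == 0), 1)
    acts <- acts + st$activated
  }
  expect_equal(acts, 0)
})

test_that("successive activations are separated by the refractory period", {
  sp <- switch_params(tau = 70, ae_thresh = 2, refractory = 150)
  st <- switch_state(sp)
  act_times <- c()
  for (step in 0:1200) {
    st <- step_switch(st, sp, as.integer(step %% 10 == 0), 1)
    if (st$activated) act_times <- c(act_times, step)
  }
  expect_gt(length(act_times), 1)
  expect_true(all(diff(act_times) >= 150))
})

test_that("fast_forward_switch matches explicit zero-input stepping", {
  sp <- switch_params(tau = 70, ae_thresh = 2)
  st <- switch_state(sp)
  st$ae <- 1.7
  st$refractory_remaining <- 420

  ff <- fast_forward_switch(st, sp, 1000)
  stepped <- st
  for (i in 1:1000) stepped <- step_switch(stepped, sp, 0, 1)
  expect_equal(ff$ae, stepped$ae, tolerance = 1e-9)
  expect_equal(ff$refractory_remaining, stepped$refractory_remaining)

  # a 15 s intertrial interval fully relaxes the switch
  ff2 <- fast_forward_switch(st, sp, 15000)
  expect_equal(ff2$ae, sp$ae0, tolerance = 1e-6)
  expect_equal(ff2$refractory_remaining, 0)

  # zero elapsed time changes nothing but the on flag
  ff0 <- fast_forward_switch(st, sp, 0)
  expect_equal(ff0$ae, st$ae)
  expect_equal(ff0$refractory_remaining, st$refractory_remaining)
  expect_false(ff0$on)
})

test_that("low-rate stimulation delays or loses activation", {
  # at 25 Hz the write switch needs four spikes (120 ms) and the read switch
  # three (80 ms); a 50 ms 25 Hz train (two spikes) never activates the read
  # switch — the basis of the weak low-frequency probe responses
  wp <- switch_params(tau = 70, ae_thresh = 2)
  rp <- switch_params(tau = 200, ae_thresh = 2)
  t25 <- seq(0, 520, by = 40)
  expect_equal(potcell:::switch_activation_time(t25, wp), 120)
  expect_equal(potcell:::switch_activation_time(t25, rp), 80)
  expect_true(is.na(potcell:::switch_activation_time(c(0, 40), rp)))
})
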