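#' Probe a trained cell with an altered CS
#'
#' Assays the learned response of a trained state with a probe CS of chosen
#' duration and rate. The archive is sampled once (the read switch, if it
#' activates, fixes the inhibition schedule) and `n_probes` probe trials are
#' simulated from that frozen state, so the battery measures response timing
#' without the extinction confound of consuming the archive config after
#' config. Pause features are scored against a drive-matched reference —
#' the same probe simulated with the inhibition switched off — so that
#' differences in CS excitatory drive between probe durations do not read
#' as timing shifts. Returns the probe PSTH and pause features.
#'
#' @param session a trained `pot_session` (its final state is probed).
#' @param duration,rate probe CS duration (ms) and rate (Hz).
#' @param n_probes number of probe trials averaged into the PSTH.
#' @param seed RNG seed for the pacemaker during probing.
#' @param t_end probe trial window end in ms.
#' @return A list: `$psth`, `$features` (one-row tibble; all-`NA` when the
#'   probe fails to activate the read switch), `$read_on_ms`.
#' @export
probe_response <- function(session, duration, rate, n_probes = 50,
                           seed = 1, t_end = 1000) {
  params <- session$config$params
  grid <- time_grid(-200, t_end, params$dt)
  spec <- stimulus_spec(0, duration, rate, "cs")
  cs_times <- spec_spike_times(spec)
  cs_values <- integer(grid$n)
  cs_values[grid_index(cs_times, grid)] <- 1L
  rp <- switch_params(params$tau_read, params$ae0, params$ae_thresh,
                      params$refractory_read)
  t_read <- switch_activation_time(cs_times, rp)
  a_values <- numeric(grid$n)
  if (!is.na(t_read)) {
    smp <- params$c_read * session$state$archive$mass
    a_values <- inhibition_schedule(smp, t_read, grid, params)
  }
  set.seed(seed)
  zero_a <- numeric(grid$n)
  sim_batch <- function(a) {
    rows <- vector("list", n_probes)
    for (k in seq_len(n_probes)) {
      p_values <- as.integer(stats::runif(grid$n) < params$lambda * grid$dt)
      idx <- simulate_membrane(cs_values, a, p_values, params)
      rows[[k]] <- tibble::tibble(trial = k,
                                  spike_times = list(grid$times[idx]))
    }
    compute_psth(list(trials = dplyr::bind_rows(rows), grid = grid),
                 bin_ms = params$psth_bin_ms)
  }
  psth <- sim_batch(a_values)
  reference <- sim_batch(zero_a)
  ref_hz <- pmax(reference$rate_hz, 1)
  list(psth = psth, reference = reference,
       features = pause_features(psth, baseline_hz = ref_hz,
                                 fraction = params$pause_fraction,
                                 min_bins = params$pause_min_bins),
       read_on_ms = t_read)
}

#' Synthetic spike rasters for testing the measurement layer
#'
#' Deterministic (seeded) rasters with known structure, used as fixtures for
#' the PSTH/CR/pause analysis functions.
#'
#' @param kind `"tonic"` (homogeneous Poisson), `"single-pause"` (tonic with
#'   a silent 100-300 ms window), `"double-pause"` (silent 100-200 and
#'   400-500 ms), or `"silent"`.
#' @param n_trials number of trials.
#' @param rate_hz tonic rate.
#' @param seed RNG seed.
#' @return A list with `$trials` (tibble of spike-time lists) and `$grid`,
#'   accepted by [compute_psth()] and [window_rate()].
#' @export
make_fixture_raster <- function(kind = c("tonic", "single-pause",
                                         "double-pause", "silent"),
                                n_trials = 50, rate_hz = 80, seed = 1) {
  kind <- match.arg(kind)
  grid <- time_grid(-200, 800)
  set.seed(seed)
  gaps <- switch(kind,
    "tonic" = cbind(numeric(0), numeric(0)),
    "silent" = cbind(grid$t_start, grid$t_end),
    "single-pause" = cbind(100, 300),
    "double-pause" = cbind(c(100, 400), c(200, 500))
  )
  rows <- vector("list", n_trials)
  p <- rate_hz / 1000 * grid$dt
  for (k in seq_len(n_trials)) {
    spk <- grid$times[stats::runif(grid$n) < p]
    if (nrow(gaps)) {
      for (g in seq_len(nrow(gaps))) {
        spk <- spk[spk < gaps[g, 1] | spk >= gaps[g, 2]]
      }
    }
    rows[[k]] <- tibble::tibble(trial = k, spike_times = list(spk))
  }
  list(trials = dplyr::bind_rows(rows), grid = grid)
}

#' The published conditioning experiments
#'
#' Builds the configuration of each of the six shipped simulations:
#' * `sim1` — basic acquisition: 200 ms ISI (CS 300 ms/100 Hz, US 20 ms/
#'   500 Hz at 200 ms), 400 trials, 15 s ITI, US omitted on every 20th trial
#'   after trial 300; plus an ISI battery 150-500 ms in 50 ms steps.
#' * `sim2` — probe invariance: train with a 200 ms/100 Hz CS and 200 ms
#'   ISI, then probe with CS durations {50, 100, 550} ms crossed with rates
#'   {25, 50, 100} Hz.
#' * `sim3` — extinction: 400 paired trials, then 400 CS-only trials.
#' * `sim4` — interleaved two-ISI training: alternating 200 and 500 ms ISI
#'   trials, 30 s ITI.
#' * `sim5` — compound-stimulus predictions: `two_cs` (CS 0-100 and
#'   300-400 ms, US at 500 ms, 800 trials) and `two_us` (CS 0-420 ms, US at
#'   200 and 400 ms, 400 trials).
#' * `sim6` — the acquisition law: a fixed-ITI sweep (15 s) and a fixed-
#'   ratio sweep (ITI/ISI = 80). `fast = TRUE` (default) uses the reduced
#'   desk-scale grids — fixed ITI: ISI {200, 400, 600, 800}; fixed ratio:
#'   ISI {300, 500, 800} (at ISI 200 the ratio design gives a 16 s ITI,
#'   indistinguishable from the fixed-ITI arm, so the fast grid samples the
#'   conditions where the two arms diverge); `fast = FALSE` uses the
#'   100-1000 ms / 10 ms grid.
#'
#' @param name one of `"sim1"` ... `"sim6"`.
#' @param fast use the reduced sim6 grids (see above).
#' @param seed base RNG seed stored in the configurations.
#' @param params a [pot_params()].
#' @return A `pot_experiment` object (a named list; contents depend on the
#'   experiment — see Details above).
#' @export
build_experiment <- function(name = c("sim1", "sim2", "sim3", "sim4",
                                      "sim5", "sim6"),
                             fast = TRUE, seed = 1, params = pot_params()) {
  name <- match.arg(name)
  ex <- switch(name,
    sim1 = list(
      config = session_config(delay_protocol(200), n_trials = 400,
                              iti = 15000, probe_every = 20,
                              probe_start = 300, seed = seed,
                              params = params),
      battery_isis = seq(150, 500, by = 50)
    ),
    sim2 = list(
      train = session_config(delay_protocol(200, cs_duration = 200),
                             n_trials = 400, iti = 15000, seed = seed,
                             params = params),
      probes = tidyr_expand_grid(duration = c(50, 100, 550),
                                 rate = c(25, 50, 100))
    ),
    sim3 = list(
      train = session_config(delay_protocol(200), n_trials = 400,
                             iti = 15000, seed = seed, params = params),
      extinction = session_config(
        trial_protocol(cs = stimulus_spec(0, 300, 100, "cs"),
                       label = "cs_only"),
        n_trials = 400, iti = 15000, seed = seed + 1, params = params)
    ),
    sim4 = list(
      config = session_config(
        list(delay_protocol(200), delay_protocol(500)),
        n_trials = 600, iti = 30000, seed = seed, params = params),
      isi_windows = list(c(0, 200), c(400, 500))
    ),
    sim5 = list(
      two_cs = session_config(
        trial_protocol(
          cs = list(stimulus_spec(0, 100, 100, "cs"),
                    stimulus_spec(300, 100, 100, "cs")),
          us = stimulus_spec(500, 20, 500, "us"),
          label = "two_cs"),
        n_trials = 800, iti = 15000, seed = seed, params = params),
      two_us = session_config(
        trial_protocol(
          cs = stimulus_spec(0, 420, 100, "cs"),
          us = list(stimulus_spec(200, 20, 500, "us"),
                    stimulus_spec(400, 20, 500, "us")),
          label = "two_us"),
        n_trials = 400, iti = 15000, seed = seed, params = params)
    ),
    sim6 = {
      if (fast) {
        list(fixed_iti = tibble::tibble(isi = c(200, 400, 600, 800),
                                        iti = 15000, n_max = 1000),
             fixed_ratio = tibble::tibble(isi = c(300, 500, 800),
                                          iti = 80 * c(300, 500, 800),
                                          n_max = 700),
             seeds_per_isi = 5)
      } else {
        isis <- seq(100, 1000, by = 10)
        list(fixed_iti = tibble::tibble(isi = isis, iti = 15000,
                                        n_max = 1000),
             fixed_ratio = tibble::tibble(isi = isis, iti = 80 * isis,
                                          n_max = 1000),
             seeds_per_isi = 3)
      }
    }
  )
  structure(c(list(name = name, seed = seed, params = params), ex),
            class = "pot_experiment")
}

# minimal expand.grid -> tibble without depending on tidyr
tidyr_expand_grid <- function(...) {
  tibble::as_tibble(expand.grid(..., KEEP.OUT.ATTRS = FALSE))
}

#' @export
print.pot_experiment <- function(x, ...) {
  cat(sprintf("<pot_experiment> %s\n", x$name))
  invisible(x)
}

#' Run an acquisition session and report trials to acquisition
#'
#' Convenience wrapper used by the sweeps: runs a delay-conditioning session
#' and returns the first-CR trial (NA = censored within `n_trials`).
#'
#' @param isi interstimulus interval in ms.
#' @param iti intertrial interval in ms.
#' @param n_trials trial cap.
#' @param seed RNG seed.
#' @param params a [pot_params()].
#' @return One-row tibble: `isi`, `iti`, `trials_to_acquisition`,
#'   `baseline_hz`.
#' @export
acquisition_run <- function(isi, iti = 15000, n_trials = 400, seed = 1,
                            params = pot_params()) {
  cfg <- session_config(delay_protocol(isi), n_trials = n_trials, iti = iti,
                        seed = seed, params = params)
  sess <- run_session(cfg)
  acq <- acquisition_trial(sess)
  tibble::tibble(isi = isi, iti = iti,
                 trials_to_acquisition = as.integer(acq),
                 baseline_hz = attr(acq, "baseline_hz"))
}

#' Trials-to-acquisition sweep
#'
#' Runs [acquisition_run()] over a grid of (ISI, ITI) conditions, averaging
#' the acquisition trial over `seeds_per_isi` seeds per condition (censored
#' runs enter at the cap), the procedure behind the acquisition-law fit.
#'
#' @param grid tibble with columns `isi`, `iti`, `n_max`.
#' @param seeds_per_isi seeds averaged per condition.
#' @param seed base seed (condition k, replicate r uses
#'   `seed + 1000 * k + r`).
#' @param params a [pot_params()].
#' @return Tibble: `isi`, `iti`, `trials_to_acquisition` (mean), `n_censored`.
#' @export
acquisition_sweep <- function(grid, seeds_per_isi = 3, seed = 1,
                              params = pot_params()) {
  purrr::pmap_dfr(grid, function(isi, iti, n_max) {
    k <- which(grid$isi == isi & grid$iti == iti)[1]
    tt <- vapply(seq_len(seeds_per_isi), function(r) {
      a <- acquisition_run(isi, iti, n_trials = n_max,
                           seed = seed + 1000 * k + r,
                           params = params)$trials_to_acquisition
      ifelse(is.na(a), n_max, a)
    }, numeric(1))
    tibble::tibble(isi = isi, iti = iti,
                   trials_to_acquisition = mean(tt),
                   n_censored = sum(tt == n_max))
  })
}
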