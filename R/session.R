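#' Session configuration
#'
#' Describes a multi-trial conditioning session: the trial protocol (or an
#' interleaved list of protocols cycled trial by trial), the number of
#' trials, the intertrial interval, an optional probe schedule (US omitted
#' on every `probe_every`-th trial after `probe_start`), the RNG seed, and
#' the model parameters.
#'
#' @param protocols a [trial_protocol()] or list of protocols (interleaved
#'   in order, trial by trial).
#' @param n_trials number of trials (>= 1).
#' @param iti intertrial interval in ms. Must exceed the switch refractory
#'   periods and several switch time constants so every trial starts from
#'   relaxed switches (checked).
#' @param probe_every omit the US on every `probe_every`-th trial (0 = never).
#' @param probe_start first trial index eligible for probes.
#' @param seed RNG seed; sessions are bit-for-bit reproducible given the seed.
#' @param params a [pot_params()].
#' @param snapshot_every record an archive snapshot every this many trials
#'   (0 = none; the final archive is always kept).
#' @param keep_inhibition keep the per-trial inhibition trace `A(t)` as a
#'   list-column (memory heavy; default off).
#' @return A `session_config` object.
#' @examples
#' cfg <- session_config(delay_protocol(200), n_trials = 10, seed = 1)
#' sess <- run_session(cfg)
#' glance(sess)
#' @export
session_config <- function(protocols, n_trials, iti = 15000,
                           probe_every = 0, probe_start = 0, seed = 1,
                           params = pot_params(), snapshot_every = 0,
                           keep_inhibition = FALSE) {
  if (inherits(protocols, "trial_protocol")) protocols <- list(protocols)
  stopifnot(length(protocols) >= 1,
            all(vapply(protocols, inherits, TRUE, "trial_protocol")),
            n_trials >= 1, iti > 0,
            probe_every == 0 || probe_every >= 2)
  min_iti <- max(params$refractory_write, params$refractory_read,
                 5 * params$tau_read, 5 * params$tau_write)
  if (iti < min_iti) {
    stop("iti must exceed the switch refractory and relaxation times (",
         min_iti, " ms)", call. = FALSE)
  }
  structure(list(protocols = protocols, n_trials = as.integer(n_trials),
                 iti = iti, probe_every = as.integer(probe_every),
                 probe_start = as.integer(probe_start), seed = seed,
                 params = params, snapshot_every = as.integer(snapshot_every),
                 keep_inhibition = isTRUE(keep_inhibition)),
            class = "session_config")
}

#' Model state between trials
#'
#' Bundles the persistent quantities: reserve level, archive, and the
#' cumulative mass ledger (replenished, stored, discarded, abandoned,
#' read-consumed), plus counters of write/read activations.
#'
#' @param params a [pot_params()].
#' @param reserve_level initial reserve level (default 0, a naive cell).
#' @return A `pot_state` object.
#' @export
new_state <- function(params = pot_params(), reserve_level = 0) {
  structure(list(
    reserve = new_reserve(reserve_level, params),
    archive = new_archive(params),
    initial_reserve = reserve_level,
    replenished = 0, stored = 0, discarded = 0, abandoned = 0,
    read_consumed = 0, n_reads = 0, n_writes = 0
  ), class = "pot_state")
}

# Precompute everything deterministic about a protocol on a grid: combined CS
# spike times and 0/1 vector, write/read activation times, nominal US onset,
# the closed-form stored-batch shape, and ejected fractions for the
# discard/abandon branches.
precompute_protocol <- function(protocol, grid, params) {
  cs_times <- sort(unique(round(unlist(
    lapply(protocol$cs, spec_spike_times)) / grid$dt) * grid$dt))
  cs_values <- integer(grid$n)
  cs_values[grid_index(cs_times, grid)] <- 1L
  wp <- switch_params(params$tau_write, params$ae0, params$ae_thresh,
                      params$refractory_write)
  rp <- switch_params(params$tau_read, params$ae0, params$ae_thresh,
                      params$refractory_read)
  t_write <- switch_activation_time(cs_times, wp)
  t_read <- switch_activation_time(cs_times, rp)
  us_onset <- protocol_us_onset(protocol)
  shape <- NULL
  if (!is.na(t_write) && !is.na(us_onset) && us_onset > t_write &&
      us_onset >= params$discard_before_ms) {
    shape <- stored_batch_shape(t_write, us_onset, params)
  }
  full <- 1 - exp(-round(params$t_eject / params$dt) * params$dt /
                    params$tau_reserve)
  frac_of <- function(span) params$eject_frac *
    (1 - exp(-max(0, span) / params$tau_reserve)) / full
  list(
    protocol = protocol, cs_times = cs_times, cs_values = cs_values,
    t_write = t_write, t_read = t_read, us_onset = us_onset,
    shape = shape,
    # ejected fraction when the batch is discarded (ejection stops at the US)
    eject_frac_discard = if (!is.na(t_write) && !is.na(us_onset))
      frac_of(min(params$t_eject, us_onset - t_write)) else 0,
    # ejected fraction when no US arrives (probe / CS-only): full episode
    eject_frac_abandon = if (!is.na(t_write))
      frac_of(min(params$t_eject, grid$t_end - t_write)) else 0
  )
}

#' Run a single trial
#'
#' Couples all modules for one trial: the write and read switches are driven
#' by the CS train; a read activation samples the archive and fixes the
#' inhibition schedule for the rest of the trial; a write activation opens a
#' batch whose ejection, drift and diffusion are integrated in closed form
#' and which is stored at the first US spike (or discarded when US onset
#' precedes the discard threshold, or abandoned when no US arrives); the
#' membrane is stepped with CS, inhibition and pacemaker input at every step.
#'
#' Chronology inside a trial matters: the read activation (typically ~20 ms
#' after CS onset) samples the archive *before* this trial's batch is stored
#' at the US.
#'
#' @param state a [new_state()].
#' @param protocol a [trial_protocol()].
#' @param grid a [time_grid()] covering the protocol.
#' @param params a [pot_params()].
#' @param probe force this trial to be a probe (US omitted).
#' @param .pre precomputed protocol info (internal; computed if missing).
#' @return `list(state =, result =)`; `result` is a one-row tibble with the
#'   trial's spike times (list-column), activation times, batch bookkeeping
#'   and archive/reserve totals.
#' @export
run_trial <- function(state, protocol, grid, params = pot_params(),
                      probe = protocol$is_probe, .pre = NULL) {
  stopifnot(inherits(state, "pot_state"))
  pre <- .pre %||% precompute_protocol(protocol, grid, params)
  # --- read: sample archive, fix inhibition schedule
  a_values <- numeric(grid$n)
  read_mass <- 0
  if (!is.na(pre$t_read)) {
    state$n_reads <- state$n_reads + 1L
    rs <- read_sample(state$archive, params)
    state$archive <- rs$archive
    read_mass <- sum(rs$sample)
    state$read_consumed <- state$read_consumed + read_mass
    a_values <- inhibition_schedule(rs$sample, pre$t_read, grid, params)
  }
  # --- write: eject, evolve, store/discard/abandon (closed form)
  stored <- FALSE
  batch_mass <- 0
  level <- state$reserve$level
  if (!is.na(pre$t_write)) {
    state$n_writes <- state$n_writes + 1L
    if (!probe && !is.na(pre$us_onset)) {
      if (!is.null(pre$shape)) {
        batch_mass <- level * pre$shape$eject_frac
        state$archive$mass <- state$archive$mass + level * pre$shape$shape
        state$stored <- state$stored + batch_mass
        state$reserve$level <- level * (1 - pre$shape$eject_frac)
        stored <- TRUE
      } else {
        lost <- level * pre$eject_frac_discard
        state$discarded <- state$discarded + lost
        state$reserve$level <- level - lost
        batch_mass <- lost
      }
    } else {
      lost <- level * pre$eject_frac_abandon
      state$abandoned <- state$abandoned + lost
      state$reserve$level <- level - lost
      batch_mass <- lost
    }
  }
  # --- membrane
  p_values <- as.integer(stats::runif(grid$n) < params$lambda * grid$dt)
  spike_idx <- simulate_membrane(pre$cs_values, a_values, p_values, params)
  spike_times <- grid$times[spike_idx]
  result <- tibble::tibble(
    protocol = pre$protocol$label,
    is_probe = probe,
    write_on_ms = pre$t_write,
    read_on_ms = pre$t_read,
    us_onset_ms = if (probe) NA_real_ else pre$us_onset,
    batch_stored = stored,
    batch_mass = batch_mass,
    read_mass = read_mass,
    reserve_level = state$reserve$level,
    archive_total = sum(state$archive$mass),
    n_spikes = length(spike_times),
    spike_times = list(spike_times)
  )
  list(state = state, result = result, inhibition = a_values)
}

#' Advance the model through an intertrial interval
#'
#' Closed-form ITI update: the reserve refills at rate `q` (capped at
#' `r_max`), stored units diffuse (total archive mass is conserved), the
#' switches relax to baseline, and the membrane is reset — the ITI is orders
#' of magnitude longer than every relaxation time in the model.
#'
#' @param state a [new_state()].
#' @param iti intertrial interval in ms.
#' @param params a [pot_params()].
#' @return The updated state.
#' @export
advance_iti <- function(state, iti, params = pot_params()) {
  stopifnot(iti > 0)
  state$reserve <- replenish(state$reserve, iti)
  state$replenished <- state$replenished + attr(state$reserve, "added")
  state$archive <- diffuse_archive(state$archive, iti, params)
  state
}

#' Run a conditioning session
#'
#' Runs `n_trials` trials of the configured protocol(s), interleaving
#' protocols trial by trial, applying the probe schedule, and advancing the
#' model through the ITI after every trial. Deterministic given the seed.
#'
#' @param config a [session_config()].
#' @param state optionally continue from an existing [new_state()] (e.g.
#'   extinction from a trained cell). By default a naive state (empty
#'   reserve, empty archive).
#' @return A `pot_session` object: `$trials` (tibble, one row per trial),
#'   `$grid`, `$config`, `$state` (final, post-ITI), `$snapshots` (archive
#'   snapshots tibble), `$archive` (final archive as tibble).
#' @export
run_session <- function(config, state = NULL) {
  stopifnot(inherits(config, "session_config"))
  params <- config$params
  grid <- default_grid(config$protocols, dt = params$dt)
  pres <- lapply(config$protocols, precompute_protocol, grid = grid,
                 params = params)
  state <- state %||% new_state(params)
  set.seed(config$seed)
  rows <- vector("list", config$n_trials)
  inhib <- if (config$keep_inhibition) vector("list", config$n_trials)
  snaps <- list()
  np <- length(pres)
  for (tr in seq_len(config$n_trials)) {
    pre <- pres[[(tr - 1L) %% np + 1L]]
    probe <- pre$protocol$is_probe ||
      (config$probe_every > 0 && tr > config$probe_start &&
         tr %% config$probe_every == 0)
    out <- run_trial(state, pre$protocol, grid, params, probe = probe,
                     .pre = pre)
    state <- out$state
    rows[[tr]] <- out$result
    if (config$keep_inhibition) inhib[[tr]] <- out$inhibition
    if (config$snapshot_every > 0 && tr %% config$snapshot_every == 0) {
      snaps[[length(snaps) + 1L]] <-
        dplyr::mutate(as_tibble(state$archive), trial = tr, .before = 1)
    }
    state <- advance_iti(state, config$iti, params)
  }
  trials <- dplyr::bind_rows(rows)
  trials <- dplyr::mutate(trials, trial = dplyr::row_number(), .before = 1)
  if (config$keep_inhibition) trials$inhibition <- inhib
  structure(list(
    trials = trials,
    grid = grid,
    config = config,
    state = state,
    snapshots = if (length(snaps)) dplyr::bind_rows(snaps) else
      tibble::tibble(trial = integer(), encoded_time_ms = numeric(),
                     mass = numeric()),
    archive = as_tibble(state$archive)
  ), class = "pot_session")
}

#' @export
print.pot_session <- function(x, ...) {
  cat(sprintf("<pot_session> %d trials, %d protocol(s), seed %s\n",
              nrow(x$trials), length(x$config$protocols),
              format(x$config$seed)))
  cat(sprintf("  final archive total %.4g, reserve %.4g\n",
              sum(x$state$archive$mass), x$state$reserve$level))
  invisible(x)
}

#' @rdname run_session
#' @param x a `pot_session`.
#' @param ... unused.
#' @method tidy pot_session
#' @export
tidy.pot_session <- function(x, ...) x$trials

#' @rdname run_session
#' @method glance pot_session
#' @export
glance.pot_session <- function(x, ...) {
  acq <- acquisition_trial(x)
  tibble::tibble(
    n_trials = nrow(x$trials),
    n_probes = sum(x$trials$is_probe),
    baseline_hz = attr(acq, "baseline_hz"),
    acquisition_trial = as.integer(acq),
    archive_total = sum(x$state$archive$mass),
    reserve_level = x$state$reserve$level,
    mass_ledger_error = mass_ledger_error(x$state)
  )
}

#' Relative mass-ledger imbalance of a state
#'
#' Every recorder unit is accounted for: initial reserve + replenished mass
#' must equal current reserve + archive + discarded + abandoned +
#' read-consumed. Returns the relative imbalance (should be ~1e-12).
#'
#' @param state a [new_state()] (or `pot_session$state`).
#' @export
mass_ledger_error <- function(state) {
  inflow <- state$initial_reserve + state$replenished
  holdings <- state$reserve$level + sum(state$archive$mass) +
    state$discarded + state$abandoned + state$read_consumed
  abs(inflow - holdings) / max(inflow, .Machine$double.eps)
}

#' Run jittered replicate sessions
#'
#' Repeats a session `n_reps` times with the named parameters independently
#' jittered (multiplied by `runif(1, 1 - w, 1 + w)`) and distinct seeds, the
#' procedure used to put standard errors on pause features and
#' trials-to-acquisition curves.
#'
#' @param config a [session_config()].
#' @param n_reps number of replicates.
#' @param jitter named numeric vector of relative half-widths, e.g.
#'   `c(tau_write = 0.1, tau_read = 0.1, r_i = 0.1, c_read = 0.1)`.
#' @return A list with `$sessions` (list of `pot_session`) and `$draws`
#'   (tibble of the jittered parameter values per replicate).
#' @export
run_replicates <- function(config, n_reps,
                           jitter = c(tau_write = 0.1, tau_read = 0.1,
                                      r_i = 0.1, c_read = 0.1)) {
  stopifnot(n_reps >= 1, length(jitter) >= 1, !is.null(names(jitter)))
  bad <- setdiff(names(jitter), names(config$params))
  if (length(bad)) stop("unknown jitter parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  draws <- vector("list", n_reps)
  sessions <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    mult <- stats::runif(length(jitter), 1 - jitter, 1 + jitter)
    p <- config$params
    for (j in seq_along(jitter)) {
      p[[names(jitter)[j]]] <- p[[names(jitter)[j]]] * mult[j]
    }
    cfg <- config
    cfg$params <- do.call(pot_params, unclass(p))
    cfg$seed <- rep_seeds[r]
    sessions[[r]] <- run_session(cfg)
    draws[[r]] <- tibble::tibble(rep = r, seed = rep_seeds[r],
                                 parameter = names(jitter),
                                 value = unlist(cfg$params[names(jitter)]))
  }
  list(sessions = sessions, draws = dplyr::bind_rows(draws))
}
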