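#' Model parameters for the passage-of-time Purkinje cell
#'
#' Builds the full parameter set of the model: leaky integrate-and-fire
#' membrane, activation-energy switches on the write and read modules, the
#' recorder-unit reserve, evolution (drift + noise) of released units, archive
#' storage, and read-out gain. Defaults are the published operating point of
#' the model; any value can be overridden by name.
#'
#' @details
#' Membrane (all voltages mV, resistances Ohm, times ms):
#' * `tau_m` membrane time constant (5), `v_rest` (-70), `v_threshold` (-54),
#'   `v_hyperpolarization` reset potential (-85), `v_spike` cosmetic spike
#'   height (10, not used by the dynamics),
#' * `r_e` CS (parallel-fiber) input resistance (50), `r_i` archive inhibition
#'   resistance (2.25e6), `r_p` pacemaker resistance (50), `lambda` pacemaker
#'   Poisson rate (0.3 events/ms).
#'
#' Switches: `tau_write` (70 ms) and `tau_read` (200 ms) are the passive-decay
#' time constants of the write/read activation energies; each CS spike
#' increments the energy by 1, and crossing `ae_thresh` (2) from baseline
#' `ae0` (0) turns the module ON and starts a refractory timer
#' (`refractory_write`, `refractory_read`, both 1000 ms).
#'
#' Memory: the reserve holds at most `r_max` (1) recorder units and refills
#' at `q` (1.25e-7 units/ms). A write activation opens a releasable subpool
#' — fraction `eject_frac` (3e-3) of the current reserve — which drains
#' exponentially with time constant `tau_reserve` (250 ms) for at most
#' `t_eject` (300 ms), or until the US freezes the batch. Released units
#' drift at 1 ms of encoded time per ms and spread by two noise sources: Brownian diffusion with kernel
#' scale `sigma` (40 ms) per `t_blur` (100 ms) of evolution, and drift-rate
#' dispersion `nu` (0.15, standard deviation of the relative drift rate).
#' Stored units keep diffusing between trials: the archive is re-blurred with
#' standard deviation `sigma_store` (40 ms) per `t_store_ref` (15000 ms) of
#' elapsed intertrial time. Batches are discarded when US onset falls before
#' `discard_before_ms` (100 ms) after CS onset. The archive spans encoded
#' times `[0, t_max]` (`t_max` = 2000 ms) at resolution `dt` (1 ms).
#'
#' Read-out: a read activation samples fraction `c_read` (0.03) of the
#' archive (removing it) and converts each sampled unit into `g_i` (7.5)
#' current units of inhibition at the moment it encodes.
#'
#' @param ... named overrides of any default listed above.
#' @return An object of class `pot_params` (a named list).
#' @examples
#' p <- pot_params()
#' p$tau_m
#' pot_params(g_i = 10, nu = 0.2)$nu
#' @export
pot_params <- function(...) {
  p <- list(
    dt = 1,
    # membrane
    tau_m = 5, v_rest = -70, v_threshold = -54,
    v_hyperpolarization = -85, v_spike = 10,
    r_e = 50, r_i = 2.25e6, r_p = 50, lambda = 0.3,
    # switches
    tau_write = 70, tau_read = 200, ae0 = 0, ae_thresh = 2,
    refractory_write = 1000, refractory_read = 1000,
    # reserve / write
    r_max = 1, q = 1.25e-7, tau_reserve = 250, eject_frac = 3e-3,
    t_eject = 300,
    # evolution noise
    sigma = 40, t_blur = 100, nu = 0.15,
    # storage diffusion
    sigma_store = 40, t_store_ref = 15000,
    # archive / read-out
    t_max = 2000, c_read = 0.03, g_i = 7.5, discard_before_ms = 100,
    # analysis defaults
    psth_bin_ms = 20, cr_fraction = 0.25, baseline_trials = 5,
    pause_fraction = 0.5, pause_min_bins = 2
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(over)] <- over
  }
  stopifnot(
    p$dt > 0, p$tau_m > 0,
    p$v_hyperpolarization < p$v_rest,
    p$v_rest < p$v_threshold, p$v_threshold < p$v_spike,
    p$tau_write > 0, p$tau_read > 0, p$ae_thresh > p$ae0,
    p$refractory_write > 0, p$refractory_read > 0,
    p$r_max > 0, p$q >= 0, p$tau_reserve > 0, p$t_eject > 0,
    p$eject_frac > 0, p$eject_frac <= 1,
    p$sigma >= 0, p$t_blur > 0, p$nu >= 0,
    p$sigma_store >= 0, p$t_store_ref > 0,
    p$t_max > 0, p$c_read > 0, p$c_read < 1, p$g_i > 0,
    p$lambda >= 0, p$lambda * p$dt <= 1
  )
  structure(p, class = "pot_params")
}

#' @export
print.pot_params <- function(x, ...) {
  cat("<pot_params>\n")
  nm <- names(x)
  for (i in seq_along(x)) {
    cat(sprintf("  %-22s %s\n", nm[i], format(x[[i]])))
  }
  invisible(x)
}

# standard-deviation of a recorder-unit cohort after evolving `t` ms:
# Brownian diffusion (variance sigma^2 * t / t_blur) plus drift-rate
# dispersion (variance (nu * t)^2)
evolution_sd <- function(t, params) {
  sqrt((params$nu * t)^2 + params$sigma^2 * t / params$t_blur)
}
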