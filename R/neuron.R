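#' Draw a Poisson pacemaker train
#'
#' The cell's intrinsic pacemaker is a Poisson impulse train: independent
#' Bernoulli(`lambda * dt`) spikes per grid step. This is the only source of
#' randomness inside a trial; it uses the session RNG stream, so a fixed seed
#' reproduces trains bit for bit.
#'
#' @param grid a [time_grid()].
#' @param params a [pot_params()] (uses `lambda`).
#' @return An `impulse_train` on the pacemaker channel.
#' @export
draw_pacemaker <- function(grid, params = pot_params()) {
  p <- params$lambda * grid$dt
  if (p > 1) stop("lambda * dt must be <= 1", call. = FALSE)
  v <- as.integer(stats::runif(grid$n) < p)
  structure(list(values = v, grid = grid, channel = "pacemaker"),
            class = "impulse_train")
}

#' Advance the membrane by one time step
#'
#' Explicit Euler update of the leaky integrate-and-fire membrane with the
#' leak implemented as relaxation toward rest:
#' `dV = (dt/tau_m) * (-(V - v_rest) + r_e*cs - r_i*a + r_p*p)`.
#' When `V` reaches threshold a spike is emitted and `V` resets to the
#' hyperpolarization potential. There is no absolute refractory period
#' beyond the reset.
#'
#' @param v membrane potential (mV).
#' @param cs 0/1 CS spike this step.
#' @param a inhibitory current this step (from the archive read-out).
#' @param p 0/1 pacemaker spike this step.
#' @param params a [pot_params()].
#' @return `list(v =, spike =)`.
#' @export
step_membrane <- function(v, cs, a, p, params = pot_params()) {
  v <- v + (params$dt / params$tau_m) *
    (-(v - params$v_rest) + params$r_e * cs - params$r_i * a + params$r_p * p)
  spike <- v >= params$v_threshold
  if (spike) v <- params$v_hyperpolarization
  list(v = v, spike = spike)
}

# Simulate the membrane over a whole trial given the per-step drive vectors.
# Returns integer indices of spike steps. The inner loop is deliberately
# plain: the drive is precomputed, so each iteration is one multiply-add and
# a threshold test.
simulate_membrane <- function(cs_values, a_values, p_values, params) {
  n <- length(cs_values)
  k <- params$dt / params$tau_m
  v_rest <- params$v_rest
  v_thr <- params$v_threshold
  v_hyp <- params$v_hyperpolarization
  drive <- params$r_e * cs_values - params$r_i * a_values +
    params$r_p * p_values
  v <- v_rest
  spikes <- integer(0)
  for (i in seq_len(n)) {
    v <- v + k * (-(v - v_rest) + drive[i])
    if (v >= v_thr) {
      spikes[length(spikes) + 1L] <- i
      v <- v_hyp
    }
  }
  spikes
}
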