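# shared helpers for the test suite

# short reference-protocol session (200 ms ISI) for unit tests
tiny_session <- function(n_trials = 20, seed = 1, ...) {
  run_session(session_config(delay_protocol(200), n_trials = n_trials,
                             seed = seed, ...))
}

# particle simulation of recorder-unit evolution: each particle drifts at an
# individual rate (1 + N(0, nu)) and random-walks with per-step Brownian
# increments (variance sigma^2/t_blur per ms), reflecting at 0 — the
# path-level counterpart of evolve_batch. Independent oracle.
particle_positions <- function(n, t, params, seed = 42) {
  set.seed(seed)
  rate <- 1 + stats::rnorm(n, 0, params$nu)
  step_sd <- params$sigma * sqrt(params$dt / params$t_blur)
  pos <- numeric(n)
  for (k in seq_len(round(t / params$dt))) {
    pos <- abs(pos + rate * params$dt + stats::rnorm(n, 0, step_sd))
  }
  pmin(pos, params$t_max)
}

# total-variation distance between a mass histogram and particle positions,
# compared on coarse bins so particle sampling noise stays well below the
# tolerance
tv_distance <- function(mass, pos, t_max, coarse_ms = 10) {
  breaks <- seq(0, t_max + coarse_ms, by = coarse_ms)
  fine_t <- seq(0, t_max, length.out = length(mass))
  p <- tapply(mass, cut(fine_t, breaks, right = FALSE), sum, default = 0)
  q <- tapply(rep(1 / length(pos), length(pos)),
              cut(pos, breaks, right = FALSE), sum, default = 0)
  p[is.na(p)] <- 0; q[is.na(q)] <- 0
  0.5 * sum(abs(p / sum(p) - q))
}
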