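#' Recorder-unit reserve
#'
#' The reserve is the pool of unreleased recorder units (all encoding 0 ms).
#' While the write module is ON it ejects units exponentially with time
#' constant `tau_reserve`; it refills at constant rate `q` up to `r_max`.
#'
#' @param level initial level in `[0, r_max]`. Sessions start from an empty
#'   reserve (a naive cell): the first pairings therefore write very little,
#'   and the per-trial batch grows as the reserve fills.
#' @param params a [pot_params()].
#' @return A `pot_reserve` object.
#' @export
new_reserve <- function(level = 0, params = pot_params()) {
  stopifnot(level >= 0, level <= params$r_max)
  structure(list(level = level, r_max = params$r_max,
                 tau_reserve = params$tau_reserve, q = params$q),
            class = "pot_reserve")
}

#' Eject recorder units from the reserve into an open batch
#'
#' One step of write-ON ejection: mass
#' `level * (1 - exp(-dt / tau_reserve))` moves from the reserve into bin 0
#' of the open batch (freshly released units encode 0 ms).
#'
#' @param reserve a `pot_reserve`.
#' @param batch an open `pot_batch`.
#' @param dt step size in ms.
#' @return `list(reserve =, batch =)` with the mass moved.
#' @export
eject <- function(reserve, batch, dt) {
  stopifnot(inherits(reserve, "pot_reserve"), inherits(batch, "pot_batch"),
            batch$open)
  delta <- reserve$level * (1 - exp(-dt / reserve$tau_reserve))
  reserve$level <- reserve$level - delta
  batch$mass[1] <- batch$mass[1] + delta
  list(reserve = reserve, batch = batch)
}

#' Replenish the reserve at constant rate
#'
#' @param reserve a `pot_reserve`.
#' @param elapsed elapsed time in ms.
#' @return The replenished reserve, capped at `r_max`. The attribute
#'   `"added"` records the mass actually added (less than `q * elapsed` when
#'   the cap binds), which the session mass ledger uses.
#' @export
replenish <- function(reserve, elapsed) {
  stopifnot(elapsed >= 0)
  new_level <- min(reserve$r_max, reserve$level + reserve$q * elapsed)
  added <- new_level - reserve$level
  reserve$level <- new_level
  attr(reserve, "added") <- added
  reserve
}

#' An open batch of evolving recorder units
#'
#' A histogram of recorder-unit mass over encoded-time bins `[0, t_max]` at
#' bin width `dt`. `age` tracks how long the batch has been evolving, which
#' sets the per-step diffusion increment.
#'
#' @param params a [pot_params()].
#' @return A `pot_batch` object (open).
#' @export
new_batch <- function(params = pot_params()) {
  nb <- as.integer(round(params$t_max / params$dt)) + 1L
  structure(list(mass = numeric(nb), open = TRUE, age = 0,
                 dt = params$dt, t_max = params$t_max),
            class = "pot_batch")
}

# Gaussian blur of a histogram with reflecting boundaries (method of
# images): mass diffusing past an edge is folded back, so the blur conserves
# mass exactly and introduces no drift bias for mass near the edges.
blur_histogram <- function(mass, sd, dt = 1) {
  if (sd <= 0) return(mass)
  total <- sum(mass)
  if (total <= 0) return(mass)
  half <- max(1L, as.integer(ceiling(4 * sd / dt)))
  kern <- stats::dnorm((-half:half) * dt, 0, sd)
  kern <- kern / sum(kern)
  n <- length(mass)
  if (half >= n) stop("blur kernel wider than the histogram", call. = FALSE)
  pad <- 2L * half
  padded <- c(numeric(pad), mass, numeric(pad))
  full <- stats::filter(padded, kern, sides = 2)
  out <- as.numeric(full[(pad + 1L):(pad + n)])
  below <- as.numeric(full[(half + 1L):pad])              # positions -half..-1
  above <- as.numeric(full[(pad + n + 1L):(pad + n + half)])  # n..n+half-1
  # reflect about the 0 bin centre and about the t_max bin centre
  out[2:(half + 1L)] <- out[2:(half + 1L)] + below[half:1]
  out[(n - 1L):(n - half)] <- out[(n - 1L):(n - half)] + above
  out * (total / sum(out))
}

#' Evolve an open batch by one time step
#'
#' Drift plus noise: the histogram advances by one bin (1 ms of encoded time
#' per ms of real time) and is then blurred with a Gaussian kernel whose
#' standard deviation is the increment of the evolution-noise law between the
#' batch's previous and new age (Brownian diffusion plus drift-rate
#' dispersion; see [pot_params()]). Total mass is conserved; mass drifting
#' past `t_max` accumulates in the last bin.
#'
#' @param batch an open `pot_batch`.
#' @param params a [pot_params()].
#' @return The evolved batch (age advanced by `dt`).
#' @export
evolve_batch <- function(batch, params = pot_params()) {
  stopifnot(inherits(batch, "pot_batch"), batch$open)
  dt <- batch$dt
  n <- length(batch$mass)
  # drift one bin
  m <- c(0, batch$mass[-n])
  m[n] <- m[n] + batch$mass[n]
  # diffusion increment over [age, age + dt]
  v0 <- evolution_sd(batch$age, params)^2
  v1 <- evolution_sd(batch$age + dt, params)^2
  m <- blur_histogram(m, sqrt(max(0, v1 - v0)), dt)
  batch$mass <- m
  batch$age <- batch$age + dt
  batch
}

# Closed-form stored-batch shape for a protocol: superposition of Gaussian
# cohorts. The write module turns ON at `t_write` and opens a releasable
# subpool (eject_frac of the reserve) that drains exponentially with
# tau_reserve for min(t_eject, t_us - t_write) ms; a cohort ejected at time
# t has evolved (t_us - t) ms when the US freezes it, so it is a Gaussian
# centred there (reflected at 0) with sd from the evolution-noise law.
# Returns NULL when no ejection fits, otherwise list(shape, eject_frac):
# `shape` sums to `eject_frac`, the fraction of the reserve ejected; the
# stored batch for reserve level L is L * shape.
stored_batch_shape <- function(t_write, t_us, params) {
  dt <- params$dt
  t_stop <- min(t_write + params$t_eject, t_us)
  n_cohort <- as.integer(round((t_stop - t_write) / dt))
  if (n_cohort <= 0) return(NULL)
  a <- dt / params$tau_reserve
  full <- 1 - exp(-round(params$t_eject / dt) * a)
  frac <- exp(-(seq_len(n_cohort) - 1) * a) * (1 - exp(-a)) *
    (params$eject_frac / full)
  evolved <- t_us - (t_write + (seq_len(n_cohort) - 1) * dt)
  sds <- pmax(evolution_sd(evolved, params), 1e-9)
  nb <- as.integer(round(params$t_max / dt)) + 1L
  edges_hi <- (0:(nb - 1)) * dt + dt / 2
  edges_lo <- edges_hi - dt
  shape <- numeric(nb)
  for (j in seq_len(n_cohort)) {
    # reflecting boundary at encoded time 0 (method of images)
    p <- stats::pnorm(edges_hi, evolved[j], sds[j]) -
      stats::pnorm(edges_lo, evolved[j], sds[j]) +
      stats::pnorm(edges_hi, -evolved[j], sds[j]) -
      stats::pnorm(edges_lo, -evolved[j], sds[j])
    tot <- sum(p)
    if (tot > 0) shape <- shape + frac[j] * (p / tot)
  }
  list(shape = shape,
       eject_frac = params$eject_frac * (1 - exp(-n_cohort * a)) / full)
}

#' The cumulative archive
#'
#' The archive is the cell's memory of the CS-US interval: a cumulative
#' histogram of stored recorder-unit states over encoded-time bins
#' `[0, t_max]`.
#'
#' @param params a [pot_params()].
#' @return A `pot_archive` object.
#' @export
new_archive <- function(params = pot_params()) {
  nb <- as.integer(round(params$t_max / params$dt)) + 1L
  structure(list(mass = numeric(nb), dt = params$dt, t_max = params$t_max),
            class = "pot_archive")
}

#' @method as_tibble pot_archive
#' @export
as_tibble.pot_archive <- function(x, ...) {
  tibble::tibble(encoded_time_ms = seq(0, x$t_max, by = x$dt), mass = x$mass)
}

#' Store a batch in the archive (or discard it)
#'
#' At the first US spike the batch's evolution stops. If US onset (measured
#' from CS onset) is earlier than `discard_before_ms` the batch is discarded
#' — the mass is lost, the archive unchanged; this is why intervals shorter
#' than 100 ms cannot be learned. Otherwise the batch mass is added to the
#' archive and the batch closes.
#'
#' @param archive a `pot_archive`.
#' @param batch a `pot_batch`.
#' @param us_onset_ms first US spike time, ms from CS onset.
#' @param params a [pot_params()].
#' @return `list(archive =, batch =, stored = TRUE/FALSE, mass =)`.
#' @export
store_batch <- function(archive, batch, us_onset_ms, params = pot_params()) {
  stopifnot(inherits(archive, "pot_archive"), inherits(batch, "pot_batch"))
  m <- sum(batch$mass)
  if (us_onset_ms < params$discard_before_ms) {
    batch$open <- FALSE
    batch$mass[] <- 0
    return(list(archive = archive, batch = batch, stored = FALSE, mass = m))
  }
  archive$mass <- archive$mass + batch$mass
  batch$open <- FALSE
  batch$mass[] <- 0
  list(archive = archive, batch = batch, stored = TRUE, mass = m)
}

#' Diffuse the archive through an intertrial interval
#'
#' Stored recorder units keep drifting apart slowly: between trials the
#' archive histogram is re-blurred with a Gaussian kernel whose variance
#' grows with elapsed real time — standard deviation
#' `sigma_store * sqrt(elapsed / t_store_ref)`. Mass is conserved
#' (truncate-and-renormalize boundaries).
#'
#' @param archive a `pot_archive`.
#' @param elapsed elapsed time in ms (typically the ITI).
#' @param params a [pot_params()].
#' @export
diffuse_archive <- function(archive, elapsed, params = pot_params()) {
  stopifnot(elapsed >= 0)
  sd <- params$sigma_store * sqrt(elapsed / params$t_store_ref)
  archive$mass <- blur_histogram(archive$mass, sd, archive$dt)
  archive
}

#' Sample a fraction of the archive (read-out)
#'
#' A read activation samples a constant fraction `c_read` of every archive
#' bin and removes it — sampling consumes the archive, which is the
#' extinction mechanism: CS-only trials deplete the memory geometrically.
#'
#' @param archive a `pot_archive`.
#' @param params a [pot_params()].
#' @return `list(archive =, sample =)`; `sample` is the sampled histogram
#'   (a bare numeric vector over encoded-time bins).
#' @export
read_sample <- function(archive, params = pot_params()) {
  smp <- params$c_read * archive$mass
  archive$mass <- archive$mass - smp
  list(archive = archive, sample = smp)
}

#' Translate a read sample into an inhibition schedule
#'
#' Each sampled unit contributes `g_i` current units of inhibition at the
#' moment it encodes, counted from the read activation: a unit encoding
#' `s` ms inhibits at `read_on_ms + s`. The archive's histogram shape is
#' thereby translated directly into the time course of the inhibitory
#' current `A(t)`.
#'
#' @param sample sampled histogram from [read_sample()].
#' @param read_on_ms read activation time, ms from CS onset.
#' @param grid a [time_grid()].
#' @param params a [pot_params()].
#' @return Numeric vector `A(t)` over the grid (current units, >= 0).
#' @export
inhibition_schedule <- function(sample, read_on_ms, grid,
                                params = pot_params()) {
  a <- numeric(grid$n)
  if (!length(sample) || sum(sample) <= 0) return(a)
  idx0 <- grid_index(read_on_ms, grid)
  idx <- idx0 + seq_along(sample) - 1L
  keep <- idx >= 1L & idx <= grid$n
  a[idx[keep]] <- sample[keep] * params$g_i
  a
}
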