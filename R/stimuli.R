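#' Simulation time grid
#'
#' A trial is simulated on a regular grid from `t_start` (before CS onset,
#' negative) to `t_end`, step `dt`. Time 0 is CS onset.
#'
#' @param t_start window start in ms (must be < 0; default -200 gives a
#'   pre-CS baseline for the PSTH).
#' @param t_end window end in ms (exclusive).
#' @param dt step size in ms.
#' @return A `time_grid` object with fields `t_start`, `t_end`, `dt`, `times`
#'   (the step times) and `n` (number of steps).
#' @examples
#' g <- time_grid(-200, 800)
#' g$n
#' @export
time_grid <- function(t_start = -200, t_end = 800, dt = 1) {
  stopifnot(dt > 0, t_start < 0, t_end > 0)
  n <- (t_end - t_start) / dt
  if (abs(n - round(n)) > 1e-9) {
    stop("(t_end - t_start) must be an integer number of steps", call. = FALSE)
  }
  n <- as.integer(round(n))
  structure(
    list(t_start = t_start, t_end = t_end, dt = dt,
         times = seq(t_start, by = dt, length.out = n), n = n),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> [%g, %g) ms, dt = %g ms, %d steps\n",
              x$t_start, x$t_end, x$dt, x$n))
  invisible(x)
}

grid_index <- function(t, grid) {
  as.integer(round((t - grid$t_start) / grid$dt)) + 1L
}

#' Stimulus specification
#'
#' One stimulus train: a regular impulse train on either the CS
#' (parallel-fiber) or US (climbing-fiber) channel.
#'
#' @param onset onset time in ms (0 = CS onset convention).
#' @param duration train duration in ms.
#' @param rate impulse rate in Hz.
#' @param channel `"cs"` or `"us"`.
#' @return A `stimulus_spec` object.
#' @examples
#' stimulus_spec(0, 300, 100, "cs")    # tone-like CS
#' stimulus_spec(200, 20, 500, "us")   # periocular-like US
#' @export
stimulus_spec <- function(onset, duration, rate, channel = c("cs", "us")) {
  channel <- match.arg(channel)
  stopifnot(is.finite(onset), duration >= 0, rate >= 0)
  structure(list(onset = onset, duration = duration, rate = rate,
                 channel = channel),
            class = "stimulus_spec")
}

# spike times of a regular train: first spike exactly at onset, then every
# 1000/rate ms; a spike is emitted at every multiple of the interspike
# interval that falls strictly inside the stimulus duration (left-edge
# placement, so the count is floor(duration*rate/1000) or one more when the
# duration is not a whole number of intervals)
spec_spike_times <- function(spec) {
  if (spec$duration <= 0 || spec$rate <= 0) return(numeric(0))
  step <- 1000 / spec$rate
  n <- ceiling(spec$duration / step)
  spec$onset + step * (seq_len(n) - 1)
}

#' Build a 0/1 impulse train on a time grid
#'
#' Places regular spikes at interval `1000/rate` ms starting exactly at the
#' stimulus onset (deterministic, no jitter): one spike at every multiple of
#' the interval strictly inside the duration. The spike count is
#' `floor(duration * rate / 1000)`, plus one when the duration is not a
#' whole number of intervals (left-edge convention).
#'
#' @param spec a [stimulus_spec()].
#' @param grid a [time_grid()].
#' @return An `impulse_train` object: 0/1 `values` on the grid plus the grid.
#' @examples
#' g <- time_grid(-200, 800)
#' tr <- make_impulse_train(stimulus_spec(0, 300, 100, "cs"), g)
#' sum(tr$values)  # 30 spikes at 0, 10, ..., 290 ms
#' @export
make_impulse_train <- function(spec, grid) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(grid, "time_grid"))
  tt <- spec_spike_times(spec)
  if (length(tt)) {
    if (min(tt) < grid$t_start || max(tt) >= grid$t_end) {
      stop(sprintf(
        "stimulus (onset %g, duration %g) extends beyond the grid window [%g, %g)",
        spec$onset, spec$duration, grid$t_start, grid$t_end), call. = FALSE)
    }
  }
  values <- integer(grid$n)
  values[grid_index(tt, grid)] <- 1L
  structure(list(values = values, grid = grid, channel = spec$channel),
            class = "impulse_train")
}

#' Combine impulse trains on a shared grid
#'
#' Elementwise maximum: a step with a spike on any train is a spike. Used for
#' compound stimuli (e.g. two CS trains in one trial).
#'
#' @param trains list of `impulse_train` objects sharing one grid.
#' @return A combined `impulse_train`.
#' @export
combine_trains <- function(trains) {
  stopifnot(length(trains) >= 1)
  g <- trains[[1]]$grid
  for (tr in trains) {
    stopifnot(inherits(tr, "impulse_train"))
    if (!identical(tr$grid$times, g$times)) {
      stop("all trains must share one time grid", call. = FALSE)
    }
  }
  v <- Reduce(pmax, lapply(trains, `[[`, "values"))
  structure(list(values = as.integer(v), grid = g,
                 channel = trains[[1]]$channel),
            class = "impulse_train")
}

#' @method as_tibble impulse_train
#' @export
as_tibble.impulse_train <- function(x, ...) {
  tibble::tibble(time_ms = x$grid$times, value = x$values)
}

#' @export
print.impulse_train <- function(x, ...) {
  cat(sprintf("<impulse_train> %s, %d spikes on [%g, %g) ms\n",
              x$channel, sum(x$values), x$grid$t_start, x$grid$t_end))
  invisible(x)
}

#' Trial protocol
#'
#' The stimulus layout of one conditioning trial: one or more CS trains, zero
#' or more US trains, and a probe flag (probe trials omit the US at run time).
#'
#' @param cs list of [stimulus_spec()] on the CS channel (or a single spec).
#' @param us list of [stimulus_spec()] on the US channel (or a single spec);
#'   may be empty for CS-only protocols.
#' @param is_probe if `TRUE` the US is omitted when the trial runs.
#' @param label optional protocol label.
#' @return A `trial_protocol` object.
#' @examples
#' # the reference delay protocol: 300 ms 100 Hz CS, 20 ms 500 Hz US at 200 ms
#' delay_protocol(isi = 200)
#' @export
trial_protocol <- function(cs, us = list(), is_probe = FALSE, label = NULL) {
  if (inherits(cs, "stimulus_spec")) cs <- list(cs)
  if (inherits(us, "stimulus_spec")) us <- list(us)
  stopifnot(length(cs) >= 1,
            all(vapply(cs, inherits, TRUE, "stimulus_spec")),
            all(vapply(us, inherits, TRUE, "stimulus_spec")))
  structure(list(cs = cs, us = us, is_probe = isTRUE(is_probe),
                 label = label %||% "protocol"),
            class = "trial_protocol")
}

#' @rdname trial_protocol
#' @param isi CS-onset to US-onset interval in ms.
#' @param cs_duration,cs_rate CS train duration (ms) and rate (Hz).
#' @param us_duration,us_rate US train duration (ms) and rate (Hz).
#' @export
delay_protocol <- function(isi, cs_duration = 300, cs_rate = 100,
                           us_duration = 20, us_rate = 500) {
  trial_protocol(
    cs = stimulus_spec(0, cs_duration, cs_rate, "cs"),
    us = stimulus_spec(isi, us_duration, us_rate, "us"),
    label = sprintf("delay_isi%g", isi)
  )
}

#' @export
print.trial_protocol <- function(x, ...) {
  cs <- paste(vapply(x$cs, function(s)
    sprintf("[%g+%gms @%gHz]", s$onset, s$duration, s$rate), ""), collapse = " ")
  us <- if (length(x$us)) paste(vapply(x$us, function(s)
    sprintf("[%g+%gms @%gHz]", s$onset, s$duration, s$rate), ""), collapse = " ")
    else "none"
  cat(sprintf("<trial_protocol> %s%s CS %s | US %s\n", x$label,
              if (x$is_probe) " (probe)" else "", cs, us))
  invisible(x)
}

# last stimulus offset of a protocol (US counted even for probes so probe and
# paired trials share one window)
protocol_end <- function(protocol) {
  offs <- vapply(c(protocol$cs, protocol$us),
                 function(s) s$onset + s$duration, numeric(1))
  max(offs)
}

# first US spike time, or NA for CS-only protocols
protocol_us_onset <- function(protocol) {
  if (!length(protocol$us)) return(NA_real_)
  tt <- unlist(lapply(protocol$us, spec_spike_times))
  if (!length(tt)) return(NA_real_)
  min(tt)
}

# default trial window for a set of protocols: pre-CS baseline to
# last stimulus offset + 500 ms
default_grid <- function(protocols, dt = 1, t_pre = 200, t_post = 500) {
  t_end <- max(vapply(protocols, protocol_end, numeric(1))) + t_post
  time_grid(-t_pre, t_end, dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
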