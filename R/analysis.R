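#' Per-trial firing rate in a time window
#'
#' @param x a `pot_session` (or any list with `$trials` and `$grid`).
#' @param lo,hi window bounds in ms (spikes with `lo <= t < hi`).
#' @return Numeric vector of rates in Hz, one per trial.
#' @export
window_rate <- function(x, lo, hi) {
  stopifnot(hi > lo)
  vapply(x$trials$spike_times,
         function(tt) sum(tt >= lo & tt < hi) / ((hi - lo) / 1000),
         numeric(1))
}

#' Peristimulus time histogram
#'
#' Mean firing rate in fixed bins tiling the trial window, averaged over the
#' selected trials.
#'
#' @param x a `pot_session` (or any list with `$trials` and `$grid`).
#' @param trials integer vector of trial indices to average (default: all).
#' @param bin_ms bin width in ms (must tile the window).
#' @return A `pot_psth` tibble with columns `t_ms` (left bin edge), `t_mid`
#'   and `rate_hz`, and attributes `bin_ms` and `n_trials`.
#' @export
compute_psth <- function(x, trials = NULL, bin_ms = 20) {
  trials <- trials %||% seq_len(nrow(x$trials))
  if (!length(trials)) stop("no trials selected", call. = FALSE)
  grid <- x$grid
  nb <- (grid$t_end - grid$t_start) / bin_ms
  if (abs(nb - round(nb)) > 1e-9) {
    stop("bin_ms must tile the trial window exactly", call. = FALSE)
  }
  nb <- as.integer(round(nb))
  edges <- grid$t_start + bin_ms * (0:nb)
  counts <- numeric(nb)
  for (tt in x$trials$spike_times[trials]) {
    if (length(tt)) {
      b <- floor((tt - grid$t_start) / bin_ms) + 1
      counts <- counts + tabulate(b[b >= 1 & b <= nb], nb)
    }
  }
  out <- tibble::tibble(
    t_ms = edges[-(nb + 1)],
    t_mid = edges[-(nb + 1)] + bin_ms / 2,
    rate_hz = counts / (length(trials) * bin_ms / 1000)
  )
  attr(out, "bin_ms") <- bin_ms
  attr(out, "n_trials") <- length(trials)
  class(out) <- c("pot_psth", class(out))
  out
}

#' Baseline firing rate of a PSTH
#'
#' Mean rate over the pre-CS bins (`t < 0`).
#'
#' @param psth a [compute_psth()] result.
#' @export
psth_baseline <- function(psth) {
  mean(psth$rate_hz[psth$t_ms < 0])
}

#' Conditioned-response test for one trial
#'
#' A CR is scored when the window rate is strictly below
#' `fraction` (default 25%) of the pre-training baseline rate. The boundary
#' is exclusive: a rate exactly at the criterion is not a CR.
#'
#' @param rate_hz firing rate during the detection window (Hz).
#' @param baseline_hz pre-training rate (Hz, > 0).
#' @param fraction criterion fraction of baseline.
#' @return Logical.
#' @export
detect_cr <- function(rate_hz, baseline_hz, fraction = 0.25) {
  stopifnot(baseline_hz > 0)
  rate_hz < fraction * baseline_hz
}

#' Per-trial CR table for a session
#'
#' Computes the detection-window rate for every trial, the pre-training
#' baseline (mean over the first `baseline_trials` trials), and the CR flag.
#'
#' @param x a `pot_session`.
#' @param isi_window detection window `c(lo, hi)` in ms; defaults to
#'   `[0, US onset]` of the first protocol (the interstimulus interval).
#' @param baseline_trials number of initial trials defining the baseline.
#' @param fraction CR criterion fraction.
#' @return Tibble with `trial`, `rate_hz`, `cr`; the baseline is attached as
#'   attribute `baseline_hz`.
#' @export
cr_trials <- function(x, isi_window = NULL, baseline_trials = NULL,
                      fraction = NULL) {
  params <- x$config$params
  baseline_trials <- baseline_trials %||% params$baseline_trials
  fraction <- fraction %||% params$cr_fraction
  if (is.null(isi_window)) {
    us <- protocol_us_onset(x$config$protocols[[1]])
    if (is.na(us)) stop("no US in protocol; supply isi_window", call. = FALSE)
    isi_window <- c(0, us)
  }
  rate <- window_rate(x, isi_window[1], isi_window[2])
  if (nrow(x$trials) < baseline_trials) {
    stop("session shorter than the baseline span", call. = FALSE)
  }
  baseline <- mean(rate[seq_len(baseline_trials)])
  out <- tibble::tibble(trial = x$trials$trial, rate_hz = rate,
                        cr = detect_cr(rate, baseline, fraction))
  attr(out, "baseline_hz") <- baseline
  out
}

#' Trial of first conditioned response
#'
#' The first trial whose detection-window rate drops strictly below the
#' criterion fraction of the pre-training baseline. Returns `NA` (censored)
#' when the criterion is never met.
#'
#' @inheritParams cr_trials
#' @return Integer trial index (or `NA`), with attribute `baseline_hz`.
#' @export
acquisition_trial <- function(x, isi_window = NULL, baseline_trials = NULL,
                              fraction = NULL) {
  ct <- cr_trials(x, isi_window, baseline_trials, fraction)
  idx <- which(ct$cr)
  out <- if (length(idx)) as.integer(idx[1]) else NA_integer_
  attr(out, "baseline_hz") <- attr(ct, "baseline_hz")
  out
}

# contiguous runs of PSTH bins below fraction*baseline lasting >= min_bins;
# an isolated single bin back at baseline inside a pause is treated as noise
# (runs separated by one above-threshold bin are merged)
pause_run_table <- function(psth, baseline_hz, fraction, min_bins) {
  below <- psth$rate_hz < fraction * baseline_hz
  n <- length(below)
  if (n > 2) {
    gap <- which(!below[2:(n - 1)] & below[1:(n - 2)] & below[3:n]) + 1L
    below[gap] <- TRUE
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_bins)
  list(starts = starts[keep], ends = ends[keep])
}

# features of one run: onset = left edge of first bin; maximum = centre of
# the run's minimal-rate plateau (deep pauses bottom out over many tied
# bins; the plateau midpoint is the point of maximal suppression); offset =
# left edge of the first bin back at/above the threshold after the run.
run_features <- function(psth, start, end, bin_ms) {
  idx <- start:end
  rmin <- min(psth$rate_hz[idx])
  tied <- idx[psth$rate_hz[idx] <= rmin + 1e-12]
  # centre of the longest contiguous stretch of minimal bins
  plateau <- tied
  if (length(tied) > 1) {
    # split tied bins into contiguous stretches, take the longest
    brk <- cumsum(c(1, diff(tied) != 1))
    lens <- tabulate(brk)
    plateau <- tied[brk == which.max(lens)]
  }
  maximum <- psth$t_mid[plateau[ceiling(length(plateau) / 2)]]
  tibble::tibble(
    onset_ms = psth$t_ms[start],
    maximum_ms = maximum,
    offset_ms = psth$t_ms[end] + bin_ms,
    min_rate_hz = rmin
  )
}

#' Temporal features of the learned pause
#'
#' Locates the pause in a trained PSTH: bins below `fraction` (default 50%)
#' of the pre-CS baseline, in runs of at least `min_bins` consecutive bins.
#' When several runs exist the deepest one is taken. Returns the pause
#' onset (left edge of the first sub-threshold bin), maximum (centre of the
#' minimal-rate plateau) and offset (left edge of the first recovered bin).
#'
#' @param psth a [compute_psth()] result.
#' @param baseline_hz baseline rate; default [psth_baseline()]. May also be
#'   a vector with one reference rate per PSTH bin (a drive-matched
#'   reference, e.g. the same stimulus simulated without inhibition), in
#'   which case each bin is compared against its own reference.
#' @param fraction sub-baseline fraction defining the pause.
#' @param min_bins minimum run length in bins.
#' @return One-row tibble `onset_ms`, `maximum_ms`, `offset_ms`,
#'   `min_rate_hz`; all `NA` when no pause is found.
#' @export
pause_features <- function(psth, baseline_hz = NULL, fraction = 0.5,
                           min_bins = 2) {
  baseline_hz <- baseline_hz %||% psth_baseline(psth)
  bin_ms <- attr(psth, "bin_ms")
  runs <- pause_run_table(psth, baseline_hz, fraction, min_bins)
  if (!length(runs$starts)) {
    return(tibble::tibble(onset_ms = NA_real_, maximum_ms = NA_real_,
                          offset_ms = NA_real_, min_rate_hz = NA_real_))
  }
  feats <- purrr::map2(runs$starts, runs$ends,
                       ~run_features(psth, .x, .y, bin_ms))
  feats <- dplyr::bind_rows(feats)
  feats[which.min(feats$min_rate_hz)[1], ]
}

#' Count and characterize distinct pauses
#'
#' Number of disjoint sub-`fraction`-baseline runs (each at least
#' `min_bins` bins) separated by at least one recovered bin, with the
#' features of each run — the assay for multi-interval training.
#'
#' @inheritParams pause_features
#' @return Tibble with one row per pause (possibly zero rows), columns as
#'   in [pause_features()] plus `pause`.
#' @export
detect_bimodal_pause <- function(psth, baseline_hz = NULL, fraction = 0.5,
                                 min_bins = 2) {
  baseline_hz <- baseline_hz %||% psth_baseline(psth)
  bin_ms <- attr(psth, "bin_ms")
  runs <- pause_run_table(psth, baseline_hz, fraction, min_bins)
  if (!length(runs$starts)) {
    return(tibble::tibble(pause = integer(), onset_ms = numeric(),
                          maximum_ms = numeric(), offset_ms = numeric(),
                          min_rate_hz = numeric()))
  }
  feats <- purrr::map2(runs$starts, runs$ends,
                       ~run_features(psth, .x, .y, bin_ms))
  dplyr::mutate(dplyr::bind_rows(feats), pause = dplyr::row_number(),
                .before = 1)
}

#' Fit the trials-to-acquisition law
#'
#' Least-squares slope through the origin of trials-to-acquisition against
#' the ISI/ITI ratio. Censored points (`NA` trials) are dropped; at least
#' three non-censored points are required.
#'
#' @param points tibble/data.frame with columns `isi`, `iti` and
#'   `trials_to_acquisition` (NA = censored).
#' @return One-row tibble: `slope`, `std_error`, `r_squared`, `n`, plus the
#'   fitted model in attribute `"fit"`.
#' @export
fit_acquisition_law <- function(points) {
  stopifnot(all(c("isi", "iti", "trials_to_acquisition") %in% names(points)))
  pts <- points[!is.na(points$trials_to_acquisition), , drop = FALSE]
  if (nrow(pts) < 3) stop("need >= 3 non-censored points", call. = FALSE)
  pts$ratio <- pts$isi / pts$iti
  fit <- stats::lm(trials_to_acquisition ~ 0 + ratio, data = pts)
  sm <- suppressWarnings(summary(fit))  # synthetic inputs can fit exactly
  out <- tibble::tibble(
    slope = unname(stats::coef(fit)[1]),
    std_error = sm$coefficients[1, 2],
    r_squared = sm$r.squared,
    n = nrow(pts)
  )
  attr(out, "fit") <- fit
  out
}
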