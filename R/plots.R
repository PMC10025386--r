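#' Plot a PSTH
#'
#' @param object a [compute_psth()] result.
#' @param baseline_hz optional baseline to draw as a reference line.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pot_psth
#' @export
autoplot.pot_psth <- function(object, baseline_hz = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t_mid,
                                            y = .data$rate_hz)) +
    ggplot2::geom_step(direction = "mid") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "darkgreen") +
    ggplot2::labs(x = "time from CS onset (ms)", y = "firing rate (Hz)")
  if (!is.null(baseline_hz)) {
    p <- p + ggplot2::geom_hline(yintercept = baseline_hz,
                                 linetype = 3, colour = "grey40")
  }
  p
}

#' Raster plot of a session
#'
#' One point per spike, trials stacked on the y axis; probe trials drawn in
#' red.
#'
#' @param x a `pot_session` (or any list with `$trials`).
#' @param every plot every `every`-th trial (rasters of long sessions).
#' @return A ggplot.
#' @export
plot_raster <- function(x, every = 1) {
  tr <- x$trials[seq(1, nrow(x$trials), by = every), ]
  probe <- if ("is_probe" %in% names(tr)) tr$is_probe else
    rep(FALSE, nrow(tr))
  df <- purrr::map2_dfr(seq_len(nrow(tr)), tr$spike_times,
                        function(i, tt) tibble::tibble(
                          trial = tr$trial[i], t = tt, probe = probe[i]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$trial,
                                   colour = .data$probe)) +
    ggplot2::geom_point(shape = ".", show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red")) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time from CS onset (ms)", y = "trial")
}

#' Plot an archive snapshot
#'
#' The intracellular interval memory: recorder-unit mass per encoded-time
#' bin.
#'
#' @param x a `pot_session` or `pot_archive` (or its [as_tibble()] form).
#' @param max_ms right edge of the plotted window.
#' @return A ggplot.
#' @export
plot_archive <- function(x, max_ms = 1000) {
  df <- if (inherits(x, "pot_session")) x$archive else
    if (inherits(x, "pot_archive")) as_tibble(x) else tibble::as_tibble(x)
  df <- df[df$encoded_time_ms <= max_ms, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$encoded_time_ms,
                                   y = .data$mass)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "encoded time (ms)", y = "recorder-unit mass")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
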