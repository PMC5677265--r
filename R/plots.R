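#' Plot a gait recording
#'
#' Acceleration channels and (when present) bilateral reference vGRF in
#' stacked facets against time.
#'
#' @param object a [grf_recording()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.grf_recording <- function(object, ...) {
  rate <- sampling_rate(object)
  long <- tidyr::pivot_longer(as_tibble(object), -"k",
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = setdiff(names(object), "k"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k / rate, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Plot predicted against reference vGRF
#'
#' @param object a `proxy_eval` from [evaluate_proxy()].
#' @param ... unused.
#' @return a ggplot with one facet per foot.
#' @export
autoplot.proxy_eval <- function(object, ...) {
  ref <- object$reference
  pred <- object$predictions
  long <- dplyr::bind_rows(
    tibble(k = ref$k, foot = "left", series = "reference", vgrf = ref$grf_left),
    tibble(k = ref$k, foot = "right", series = "reference", vgrf = ref$grf_right),
    tibble(k = pred$k, foot = "left", series = "predicted", vgrf = pred$grf_left),
    tibble(k = pred$k, foot = "right", series = "predicted", vgrf = pred$grf_right))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$vgrf,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$foot)) +
    ggplot2::labs(x = "sample k", y = "vGRF (N)", colour = NULL)
}

#' Plot an OFR selection trace
#'
#' Error reduction ratio per selection step (log scale) with the cumulative
#' explained energy.
#'
#' @param object an `ofr_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ofr_result <- function(object, ...) {
  df <- tibble(step = seq_along(object$err), err = object$err,
               cumulative = cumsum(object$err))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$err)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "red") +
    ggplot2::labs(x = "selection step", y = "ERR (bars), cumulative (line)")
}

#' Plot membership functions
#'
#' @param membership tibble from [exact_membership()] or
#'   [event_membership()].
#' @param ... additional memberships to overlay, named (e.g.
#'   `approx = event_membership(...)`).
#' @return a ggplot of `w_left` and `w_right` against the sample index.
#' @export
plot_membership <- function(membership, ...) {
  extras <- list(...)
  all <- c(list(exact = membership), extras)
  long <- dplyr::bind_rows(lapply(all, function(m) {
    tidyr::pivot_longer(m, c("w_left", "w_right"),
                        names_to = "side", values_to = "w")
  }), .id = "construction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$w,
                                     colour = .data$construction)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$side)) +
    ggplot2::labs(x = "sample k", y = "membership weight", colour = NULL)
}

#' Plot a correlation diagnostic
#'
#' Statistic versus lag with the 95% white-noise significance band, for
#' [max_lag_by_crosscorrelation()] and [nonlinearity_test()] results.
#'
#' @param object a `lag_analysis` or `nonlinearity_test`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lag_analysis <- function(object, ...) {
  df <- dplyr::rename(object$trace, statistic = "correlation")
  plot_lag_trace(df, unique(object$trace$band))
}

#' @rdname autoplot.lag_analysis
#' @export
autoplot.nonlinearity_test <- function(object, ...) {
  plot_lag_trace(object$trace, object$band)
}

plot_lag_trace <- function(df, band) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$statistic)) +
    ggplot2::geom_hline(yintercept = c(-band, band), linetype = "dashed") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "lag (samples)", y = "normalized correlation")
}
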