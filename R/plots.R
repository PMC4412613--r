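#' @importFrom ggplot2 autoplot
NULL

#' Plot methods
#'
#' `autoplot()` methods for the package's result types: current traces,
#' amplitude histograms with their fitted Gaussian mixture, and I/V / J/V
#' curves.
#'
#' @param object The object to plot.
#' @param sweeps Optional subset of sweep indices for trace sets.
#' @param ... Unused.
#' @return A ggplot object.
#' @name vactrace-autoplot
NULL

#' @rdname vactrace-autoplot
#' @export
autoplot.trace_set <- function(object, sweeps = NULL, ...) {
  d <- object
  if (!is.null(sweeps)) d <- d[d$sweep %in% sweeps, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$current_pA)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~sweep, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "current (pA)")
}

#' @rdname vactrace-autoplot
#' @export
autoplot.amplitude_histogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$bin_mid_pA, .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "grey60") +
    ggplot2::labs(x = "current (pA)", y = "samples")
}

#' @rdname vactrace-autoplot
#' @export
autoplot.peak_mixture <- function(object, ...) {
  hist <- attr(object, "histogram")
  grid <- tibble::tibble(x = seq(min(hist$bin_mid_pA), max(hist$bin_mid_pA),
                                 length.out = 400))
  bw <- attr(hist, "bin_width")
  grid$y <- rowSums(vapply(seq_len(nrow(object)), function(k) {
    a <- object$area[k] * bw / (object$sd_pA[k] * sqrt(2 * pi))
    a * exp(-(grid$x - object$centre_pA[k])^2 / (2 * object$sd_pA[k]^2))
  }, numeric(nrow(grid))))
  autoplot(hist) +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$x, .data$y),
                       colour = "red") +
    ggplot2::geom_vline(xintercept = object$centre_pA, linetype = 3)
}

#' @rdname vactrace-autoplot
#' @export
autoplot.iv_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$voltage_mV, .data$current_pA)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$current_pA - .data$sem,
      ymax = .data$current_pA + .data$sem), width = 2, na.rm = TRUE) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "voltage (mV)", y = "current (pA)",
                  title = attr(object, "label"))
}

#' @rdname vactrace-autoplot
#' @export
autoplot.jv_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$voltage_mV, .data$J_A_m2)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$J_A_m2 - .data$sem,
      ymax = .data$J_A_m2 + .data$sem), width = 2, na.rm = TRUE) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "voltage (mV)", y = expression(J~(A~m^{-2})),
                  title = attr(object, "label"))
}
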