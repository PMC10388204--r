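#' Plot methods
#'
#' `autoplot()` methods for the package's result objects, plus a couple of
#' named plot helpers. All return ggplot objects for further styling.
#'
#' @param object Result object.
#' @param ... Unused.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.fret_tdp <- function(object, ...) {
  df <- object$pairs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$e_from, y = .data$e_to)) +
    ggplot2::geom_bin2d(bins = length(object$bin_edges) - 1) +
    ggplot2::coord_fixed(xlim = range(object$bin_edges),
                         ylim = range(object$bin_edges)) +
    ggplot2::labs(x = "initial FRET efficiency", y = "final FRET efficiency",
                  fill = "transitions") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.fret_states <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$state),
                                   y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "state", y = "population fraction") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.itc_fit <- function(object, ...) {
  proto <- object$protocol
  v <- cumsum(proto$injection_volumes_ul) * 1e-6
  V0 <- proto$cell_volume_ul * 1e-6
  ratio <- proto$syringe_conc_M * (v / V0) * (1 - v / (2 * V0)) /
    (proto$cell_conc_M * (1 - v / (2 * V0)))
  df <- tibble(molar_ratio = ratio, observed = object$observed_heats,
               fitted = object$fitted_heats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "firebrick") +
    ggplot2::labs(x = "molar ratio (ligand/protein)",
                  y = "heat (kcal/mol of injectant)") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.pull_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble(time = object$time, force = object$force, x = object$x),
    -"time", names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ns)") +
    ggplot2::theme_minimal()
}

#' FRET efficiency histogram plot
#'
#' @param hist Tibble from [build_fret_histogram()].
#' @return A ggplot.
#' @export
plot_fret_histogram <- function(hist) {
  p <- ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin_mid,
                                          y = .data$density)) +
    ggplot2::geom_col(width = diff(hist$bin_mid[1:2]), fill = "grey40") +
    ggplot2::labs(x = "FRET efficiency", y = "density") +
    ggplot2::theme_minimal()
  if ("state_global" %in% names(hist)) {
    p <- p + ggplot2::facet_wrap(~state_global)
  }
  p
}
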