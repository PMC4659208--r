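#' Plot total flow against stenosis degree for each variant
#'
#' Line chart of the sweep's total cerebral flow over the stenosis grid, one
#' line per anatomical variant.
#'
#' @param sweep A \code{cow_sweep}.
#'
#' @return A ggplot object.
#' @export
plot_total_flow <- function(sweep) {
  stopifnot(inherits(sweep, "cow_sweep"))
  ggplot2::ggplot(
    sweep$results,
    ggplot2::aes(x = .data$degree, y = .data$total_flow_ml_s,
                 colour = .data$variant)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "RICA stenosis degree (%)",
                  y = "Total flow (ml/s)",
                  colour = "Configuration") +
    ggplot2::theme_minimal()
}

#' Plot communicating-artery flows across the sweep
#'
#' Signed cross-flows (positive ACoA flow towards the right hemisphere,
#' positive PCoA flow feeding the anterior circulation), one panel per
#' communicating artery.
#'
#' @param sweep A \code{cow_sweep}.
#'
#' @return A ggplot object.
#' @export
plot_communicating_flows <- function(sweep) {
  stopifnot(inherits(sweep, "cow_sweep"))
  long <- sweep$results |>
    dplyr::select("variant", "degree", "ACoA", "RPCoA", "LPCoA") |>
    tidyr::pivot_longer(c("ACoA", "RPCoA", "LPCoA"),
                        names_to = "segment", values_to = "flow_ml_s")
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$degree, y = .data$flow_ml_s,
                 colour = .data$variant)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$segment), scales = "free_y") +
    ggplot2::labs(x = "RICA stenosis degree (%)",
                  y = "Signed flow (ml/s)",
                  colour = "Configuration") +
    ggplot2::theme_minimal()
}

#' @rdname plot_total_flow
#' @param object A \code{cow_sweep}.
#' @param ... Unused.
#' @export
autoplot.cow_sweep <- function(object, ...) {
  plot_total_flow(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
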