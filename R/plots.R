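# ggplot2 views of trajectories and reports.

#' Plot a trajectory's concentration time courses
#'
#' @param object An `aktpi_trajectory`.
#' @param species Species to draw; defaults to the pathway readouts
#'   (pAKT, pGSK3B, GSK3B, PIP3) intersected with what the trajectory has.
#' @param ... Unused.
#' @return A ggplot object (one line per species).
#' @method autoplot aktpi_trajectory
#' @export
autoplot.aktpi_trajectory <- function(object,
                                      species = c("pAKT", "pGSK3B",
                                                  "GSK3B", "PIP3"),
                                      ...) {
  species <- intersect(species, names(object))
  if (!length(species)) species <- setdiff(names(object), "time_s")
  long <- tidy(object, species = species)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$time_s, y = .data$concentration_nM,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "concentration (nM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a scenario report as grouped bars
#'
#' Percentage rows and exposure rows live on different scales, so the plot
#' facets by quantity with free y scales.
#'
#' @param object An `aktpi_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aktpi_report
#' @export
autoplot.aktpi_report <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scenario, y = .data$value,
                                     fill = .data$scenario)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "exposure (nM·s) / percent") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
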