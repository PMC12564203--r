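# broom-style verbs for the package's result objects.

#' Tidy a trajectory into long form
#'
#' @param x An `aktpi_trajectory`.
#' @param species Optional character vector restricting the species kept.
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `species`, `concentration_nM`.
#' @method tidy aktpi_trajectory
#' @export
tidy.aktpi_trajectory <- function(x, species = NULL, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(x), -"time_s",
                              names_to = "species",
                              values_to = "concentration_nM")
  if (!is.null(species)) {
    long <- dplyr::filter(long, .data$species %in% !!species)
  }
  dplyr::arrange(long, .data$species, .data$time_s)
}

#' One-row summary of a trajectory
#'
#' @param x An `aktpi_trajectory`.
#' @param ... Unused.
#' @return A tibble with the horizon, grid size, species count and the
#'   minimum concentration reached (a negative value beyond tolerance
#'   would indicate integrator trouble).
#' @method glance aktpi_trajectory
#' @export
glance.aktpi_trajectory <- function(x, ...) {
  vals <- as.matrix(tibble::as_tibble(x)[, setdiff(names(x), "time_s")])
  tibble::tibble(
    horizon_s = max(x$time_s),
    n_times = nrow(x),
    n_species = ncol(vals),
    min_concentration_nM = min(vals),
    max_concentration_nM = max(vals)
  )
}

#' Tidy a scenario report into long form
#'
#' @param x An `aktpi_report`.
#' @param ... Unused.
#' @return A tibble with columns `quantity`, `scenario`, `value`.
#' @method tidy aktpi_report
#' @export
tidy.aktpi_report <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"quantity",
                      names_to = "scenario", values_to = "value")
}
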