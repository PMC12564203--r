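# Outcome measures: concentration-time exposure integrals (nM*s) by the
# composite trapezoid rule on the stored output grid (so exposures are
# recomputable from any saved trajectory CSV), phospho-percentages
# (p-form / unphosphorylated form x 100 -- the convention behind the "%"
# rows of the scenario tables), and relative activity of the free target.

#' Concentration-time exposure integral
#'
#' Composite trapezoidal integral of one or more species' concentration
#' series over the full output grid of a trajectory.
#'
#' @param trajectory An `aktpi_trajectory` (or any data frame with a
#'   `time_s` column and per-species columns).
#' @param species Character vector of species names.
#' @return Named numeric vector of exposures in nM*s.
#' @examples
#' traj <- tibble::tibble(time_s = 0:100, A = rep(5, 101))
#' exposure(traj, "A") # 500
#' @export
exposure <- function(trajectory, species) {
  unknown <- setdiff(species, names(trajectory))
  if (length(unknown)) {
    stop("species not in trajectory: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vapply(species, function(s) {
    pracma::trapz(trajectory$time_s, trajectory[[s]])
  }, numeric(1))
}

#' Exposure table for every species of a trajectory
#'
#' @inheritParams exposure
#' @return A tibble with columns `species` and `exposure_nM_s`, plus the
#'   horizon as the `horizon_s` attribute.
#' @export
exposure_table <- function(trajectory) {
  sp <- setdiff(names(trajectory), "time_s")
  structure(
    tibble::tibble(species = sp,
                   exposure_nM_s = unname(exposure(trajectory, sp))),
    horizon_s = max(trajectory$time_s))
}

#' Phospho-percentage of a species pair
#'
#' `100 * p_exposure / base_exposure`: the exposure of the phosphorylated
#' form relative to the exposure of the unphosphorylated form (not of the
#' total pool — the convention the scenario tables use).
#'
#' @param p_exposure Exposure of the phosphorylated form (nM*s, >= 0).
#' @param base_exposure Exposure of the unphosphorylated form (nM*s, > 0).
#' @return Percentage (full precision; display rounding is the caller's
#'   concern).
#' @examples
#' phospho_percentage(268.18, 3931.82) # 6.8207...
#' @export
phospho_percentage <- function(p_exposure, base_exposure) {
  if (any(base_exposure <= 0)) {
    stop("base_exposure must be > 0", call. = FALSE)
  }
  100 * p_exposure / base_exposure
}

#' Relative activity of the free target
#'
#' `100 * free / total`, with `total` the target pool at the initial time
#' point (free + phosphorylated + inhibitor-bound).
#'
#' @param free_target Free (active) target concentration, nM.
#' @param total_at_t0 Total target pool at t = 0, nM (> 0).
#' @return Percentage.
#' @export
relative_activity <- function(free_target, total_at_t0) {
  if (any(total_at_t0 <= 0)) stop("total_at_t0 must be > 0", call. = FALSE)
  100 * free_target / total_at_t0
}

# round-half-up to `digits`, for display parity with the printed tables
# (base round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Scenario comparison report of AKT / GSK3B exposures
#'
#' Builds the standard comparison table: one column per scenario, rows for
#' the target-inhibitor complex (when any scenario has a binding reaction),
#' AKT, pAKT, pAKT\%, GSK3B, pGSK3B and pGSK3B\%. Percentage rows are
#' p-form exposure over unphosphorylated-form exposure (see
#' [phospho_percentage()]). Values are kept at full precision; `print()`
#' shows them rounded half-up to two decimals.
#'
#' @param results Named list of `aktpi_trajectory` objects sharing the same
#'   output grid (e.g. from [run_scenarios()]).
#' @return An `aktpi_report` tibble: column `quantity` then one numeric
#'   column per scenario.
#' @export
scenario_report <- function(results) {
  stopifnot(is.list(results), length(results) >= 1,
            !is.null(names(results)))
  grids <- lapply(results, function(tr) tr$time_s)
  if (!all(vapply(grids[-1], identical, logical(1), grids[[1]]))) {
    stop("trajectories do not share the same output grid", call. = FALSE)
  }
  complex_of <- function(tr) {
    grep("^GSK3B-", setdiff(names(tr), "time_s"), value = TRUE)
  }
  complexes <- unique(unlist(lapply(results, complex_of)))
  cols <- lapply(results, function(tr) {
    ex <- function(s) {
      if (s %in% names(tr)) unname(exposure(tr, s)) else 0
    }
    vals <- c()
    for (cx in complexes) vals <- c(vals, ex(cx))
    c(vals,
      ex("AKT"), ex("pAKT"), phospho_percentage(ex("pAKT"), ex("AKT")),
      ex("GSK3B"), ex("pGSK3B"),
      phospho_percentage(ex("pGSK3B"), ex("GSK3B")))
  })
  quantity <- c(if (length(complexes)) paste(complexes, "Complex"),
                "AKT", "pAKT", "pAKT%", "GSK3B", "pGSK3B", "pGSK3B%")
  out <- tibble::tibble(quantity = quantity)
  for (nm in names(results)) out[[nm]] <- cols[[nm]]
  structure(out, class = c("aktpi_report", class(out)))
}

#' @export
print.aktpi_report <- function(x, ...) {
  shown <- tibble::as_tibble(x)
  for (nm in setdiff(names(shown), "quantity")) {
    shown[[nm]] <- round_half_up(shown[[nm]], 2)
  }
  cat("Scenario exposure report (nM*s; % rows in percent; 2 dp display)\n")
  print(as.data.frame(shown), row.names = FALSE)
  invisible(x)
}

#' Write a scenario report as CSV (full precision)
#'
#' @param report An `aktpi_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  readr::write_csv(tibble::as_tibble(report), path)
  invisible(path)
}
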