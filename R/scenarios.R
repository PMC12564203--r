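# Drug interventions as declarative transforms of (network, init): scaling
# of initial AKT / PIP2 pools and reversible competitive inhibitor binding
# to GSK3B parameterised by Ki (= koff/kon). Only the ratio koff/kon is
# constrained by the equilibrium data, so kon is derived from a reference
# koff; equilibrium-sensitive outputs depend on the reference only weakly
# once binding equilibrates well inside the horizon.

scenario_names <- c("control", "akt_modulation", "pip2_modulation",
                    "gsk3b_binding", "total_effects", "curcumin")

#' Convert a binding constant Ki into kinetic on/off rate constants
#'
#' Fixes the dissociation rate at `koff_ref` and sets
#' `kon = koff_ref / ki`, so that `koff / kon = ki` holds exactly.
#'
#' @param ki Equilibrium inhibition constant in nM (> 0).
#' @param koff_ref Reference dissociation rate in 1/s (> 0). Default 0.1/s,
#'   fast enough that binding equilibrates well within the default horizon.
#' @return A list with elements `kon` (nM^-1 s^-1) and `koff` (s^-1).
#' @examples
#' ki_to_rate_constants(1000) # kon = 1e-4
#' @export
ki_to_rate_constants <- function(ki, koff_ref = 0.1) {
  if (!is.numeric(ki) || ki <= 0) stop("ki must be > 0", call. = FALSE)
  if (!is.numeric(koff_ref) || koff_ref <= 0) {
    stop("koff_ref must be > 0", call. = FALSE)
  }
  list(kon = koff_ref / ki, koff = koff_ref)
}

#' Equilibrium fractional occupancy of the target by an inhibitor
#'
#' In the excess-inhibitor regime (dose much larger than the total target
#' pool) the bound fraction of the target at equilibrium is
#' `dose / (dose + ki)`; at `dose = ki` this is one half, the defining
#' property of a half-inhibition constant.
#'
#' @param dose Free inhibitor concentration in nM (> 0).
#' @param ki Binding constant in nM (> 0).
#' @return Bound fraction in `[0, 1)`.
#' @export
equilibrium_occupancy <- function(dose, ki) {
  stopifnot(dose > 0, ki > 0)
  dose / (dose + ki)
}

new_inhibitor <- function(name, dose, ki, ic50 = NA_real_, koff_ref = 0.1,
                          target = "GSK3B") {
  rates <- ki_to_rate_constants(ki, koff_ref)
  if (dose <= 0) stop("dose must be > 0", call. = FALSE)
  list(name = name, dose = dose, ki = ki, ic50 = ic50,
       kon = rates$kon, koff = rates$koff, target = target,
       species = switch(name, lithium = "Li", curcumin = "Cur",
                        paste0(toupper(substr(name, 1, 1)),
                               substr(name, 2, 3))))
}

#' Construct a named intervention scenario
#'
#' Canonical parameterizations:
#' \describe{
#'   \item{control}{identity transform.}
#'   \item{akt_modulation}{initial AKT scaled by 1.30 (the 30\% increase in
#'     AKT observed under therapeutic lithium).}
#'   \item{pip2_modulation}{initial PIP2 scaled by 0.63 (the 37\% PIP2
#'     depletion attributed to IMPase inhibition by lithium).}
#'   \item{gsk3b_binding}{reversible lithium-GSK3B binding, dose 1000 nM,
#'     Ki 1000 nM.}
#'   \item{total_effects}{all three lithium mechanisms combined.}
#'   \item{curcumin}{reversible curcumin-GSK3B binding, dose 1000 nM,
#'     Ki 66.3 nM (taken equal to the reported IC50 for this competitive
#'     inhibitor in the low-substrate regime).}
#' }
#'
#' @param name One of `"control"`, `"akt_modulation"`, `"pip2_modulation"`,
#'   `"gsk3b_binding"`, `"total_effects"`, `"curcumin"`.
#' @param dose,ki Optional overrides of the inhibitor dose / Ki (nM).
#' @param koff_ref Reference dissociation rate passed to
#'   [ki_to_rate_constants()].
#' @return An `aktpi_scenario` list: `name`, `akt_scale`, `pip2_scale`,
#'   and `inhibitor` (`NULL` or an inhibitor spec).
#' @export
make_scenario <- function(name, dose = NULL, ki = NULL, koff_ref = 0.1) {
  if (!is.character(name) || length(name) != 1 ||
      !(name %in% scenario_names)) {
    stop("unknown scenario; valid names: ",
         paste(scenario_names, collapse = ", "), call. = FALSE)
  }
  li <- function() new_inhibitor("lithium", dose %||% 1000, ki %||% 1000,
                                 koff_ref = koff_ref)
  cur <- function() new_inhibitor("curcumin", dose %||% 1000, ki %||% 66.3,
                                  ic50 = 66.3, koff_ref = koff_ref)
  sc <- switch(name,
    control = list(akt_scale = 1, pip2_scale = 1, inhibitor = NULL),
    akt_modulation = list(akt_scale = 1.30, pip2_scale = 1, inhibitor = NULL),
    pip2_modulation = list(akt_scale = 1, pip2_scale = 0.63, inhibitor = NULL),
    gsk3b_binding = list(akt_scale = 1, pip2_scale = 1, inhibitor = li()),
    total_effects = list(akt_scale = 1.30, pip2_scale = 0.63,
                         inhibitor = li()),
    curcumin = list(akt_scale = 1, pip2_scale = 1, inhibitor = cur())
  )
  structure(c(list(name = name), sc), class = "aktpi_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a scenario to a network and initial state
#'
#' Scales the initial AKT and PIP2 pools, and, when the scenario carries an
#' inhibitor, extends the network with the inhibitor species, the
#' target-inhibitor complex, and the reversible binding reaction
#' `target + inhibitor = complex` with the scenario's (kon, koff). The
#' inhibitor is depletable: it is consumed into the complex, which at the
#' doses used (far above the target pool) is indistinguishable from a
#' clamped inhibitor. All other species are untouched.
#'
#' @param network A `reaction_network`.
#' @param init Initial state tibble (`species`, `concentration_nM`) or
#'   named vector, complete for `network`.
#' @param scenario An `aktpi_scenario` from [make_scenario()].
#' @return A list with elements `network` and `init` (init as a tibble).
#' @export
apply_scenario <- function(network, init, scenario) {
  stopifnot(inherits(scenario, "aktpi_scenario"))
  state <- as_state_vector(init, network)
  scale_pool <- function(state, species, factor) {
    if (species %in% names(state)) {
      state[[species]] <- factor * state[[species]]
    } else if (factor != 1) {
      stop("scenario scales '", species, "' but it is not in the network",
           call. = FALSE)
    }
    state
  }
  state <- scale_pool(state, "AKT", scenario$akt_scale)
  state <- scale_pool(state, "PIP2", scenario$pip2_scale)
  net <- network
  inh <- scenario$inhibitor
  if (!is.null(inh)) {
    if (!(inh$target %in% network$species$name)) {
      stop("inhibitor target '", inh$target, "' is not in the network",
           call. = FALSE)
    }
    complex <- paste0(inh$target, "-", inh$species)
    net$species <- dplyr::bind_rows(
      net$species,
      tibble::tibble(
        name = c(inh$species, complex),
        description = c(paste0(inh$name, " (free)"),
                        paste0(inh$target, "-", inh$name, " complex"))))
    reac <- stats::setNames(c(1, 1), c(inh$target, inh$species))
    prod_ <- stats::setNames(1, complex)
    net$reactions <- dplyr::bind_rows(
      net$reactions,
      tibble::tibble(
        id = max(as.integer(net$reactions$id)) + 1L,
        reversible = TRUE, kind = "mass_rev",
        kf = inh$kon, kb = inh$koff, vmax = 0, km = 0,
        reactants = list(reac), products = list(prod_),
        catalysts = list(character(0))))
    state[[inh$species]] <- inh$dose
    state[[complex]] <- 0
    state <- state[net$species$name]
  }
  list(network = net,
       init = tibble::tibble(species = names(state),
                             concentration_nM = unname(state)))
}

#' Simulate a set of scenarios on a common baseline
#'
#' Convenience wrapper: applies each scenario to `(network, init)` and
#' integrates it with shared solver settings.
#'
#' @inheritParams apply_scenario
#' @param scenarios Character vector of scenario names, or a list of
#'   `aktpi_scenario` objects.
#' @param settings A [solver_settings()] object shared by all runs.
#' @return Named list of `aktpi_trajectory` objects.
#' @export
run_scenarios <- function(network, init, scenarios,
                          settings = solver_settings()) {
  if (is.character(scenarios)) scenarios <- lapply(scenarios, make_scenario)
  names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  lapply(scenarios, function(sc) {
    mod <- apply_scenario(network, init, sc)
    simulate_network(mod$network, mod$init, settings)
  })
}

#' @export
print.aktpi_scenario <- function(x, ...) {
  inh <- if (is.null(x$inhibitor)) "none" else {
    sprintf("%s %g nM (Ki %g nM)", x$inhibitor$name, x$inhibitor$dose,
            x$inhibitor$ki)
  }
  cat(sprintf("<scenario: %s> AKT x%.2f, PIP2 x%.2f, inhibitor: %s\n",
              x$name, x$akt_scale, x$pip2_scale, inh))
  invisible(x)
}
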