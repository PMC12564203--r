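# Right-hand-side assembly and deterministic integration. The network is
# compiled once into a stoichiometry matrix (catalysts contribute net zero)
# plus a vectorised per-reaction rate function, then handed to the stiff
# adaptive solver.

#' Solver settings for network integration
#'
#' @param horizon Simulation end time in seconds (> 0). Default 600 s: the
#'   interesting transient structure of the crosstalk model (including the
#'   pGSK3B sub-peak near 310 s) sits well inside it.
#' @param output_step Uniform output grid spacing in seconds. Default 0.1 s.
#' @param rel_tol,abs_tol Relative / absolute (nM) integrator tolerances.
#'   Tight defaults (1e-8, 1e-10) because exposure integrals accumulate
#'   drift over the horizon.
#' @param max_step Maximum internal step in seconds (`Inf` = unrestricted).
#' @return A `solver_settings` list.
#' @export
solver_settings <- function(horizon = 600, output_step = 0.1,
                            rel_tol = 1e-8, abs_tol = 1e-10,
                            max_step = Inf) {
  stopifnot(horizon > 0, output_step > 0, rel_tol > 0, abs_tol > 0,
            max_step > 0)
  structure(list(horizon = horizon, output_step = output_step,
                 rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step),
            class = "solver_settings")
}

as_state_vector <- function(init, network = NULL) {
  if (is.data.frame(init)) {
    stopifnot(all(c("species", "concentration_nM") %in% names(init)))
    state <- stats::setNames(init$concentration_nM, init$species)
  } else if (is.numeric(init) && !is.null(names(init))) {
    state <- init
  } else {
    stop("init must be a tibble with columns species, concentration_nM, ",
         "or a named numeric vector", call. = FALSE)
  }
  if (!is.null(network)) {
    missing <- setdiff(network$species$name, names(state))
    if (length(missing)) {
      stop("init is missing species: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    state <- state[network$species$name]
  }
  state
}

#' Instantaneous rate of a single reaction
#'
#' Irreversible mass action: `kf * prod(reactants^stoich)`; reversible mass
#' action additionally subtracts `kb * prod(products^stoich)`;
#' Michaelis-Menten: `vmax * S / (km + S)` on the single substrate.
#'
#' @param reaction One row of a network's `reactions` tibble (a one-row
#'   data frame or an equivalent list with the same fields).
#' @param state Named numeric vector or `species`/`concentration_nM` tibble
#'   covering all reactants (and products, if reversible).
#' @return Net rate in nM/s.
#' @export
reaction_rate <- function(reaction, state) {
  state <- as_state_vector(state)
  if (is.data.frame(reaction)) reaction <- as.list(reaction[1, ])
  unwrap <- function(x) if (is.list(x)) x[[1]] else x
  reac <- unwrap(reaction$reactants)
  prod_ <- unwrap(reaction$products)
  need <- names(reac)
  if (reaction$kind == "mass_rev") need <- c(need, names(prod_))
  unknown <- setdiff(need, names(state))
  if (length(unknown)) {
    stop("state does not cover species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mono <- function(stoich) {
    if (!length(stoich)) return(1)
    prod(state[names(stoich)]^stoich)
  }
  unname(switch(reaction$kind,
    mass_irrev = reaction$kf * mono(reac),
    mass_rev = reaction$kf * mono(reac) - reaction$kb * mono(prod_),
    michaelis_menten = {
      s <- state[[names(reac)[1]]]
      reaction$vmax * s / (reaction$km + s)
    },
    stop("unknown rate law kind: ", reaction$kind, call. = FALSE)
  ))
}

# Compile a network into (stoichiometry matrix, rate function). Catalysts
# appear on both sides, so their net column entry is zero while they still
# enter the forward rate monomial.
compile_network <- function(network) {
  diags <- validate_network(network)
  if (nrow(diags)) {
    stop("network fails validation:\n",
         paste(sprintf("  [%s] %s", diags$where, diags$message),
               collapse = "\n"), call. = FALSE)
  }
  sp <- network$species$name
  rt <- network$reactions
  nr <- nrow(rt)
  S <- matrix(0, nrow = length(sp), ncol = nr, dimnames = list(sp, NULL))
  for (j in seq_len(nr)) {
    reac <- rt$reactants[[j]]
    prod_ <- rt$products[[j]]
    for (s in names(reac)) S[s, j] <- S[s, j] - reac[[s]]
    for (s in names(prod_)) S[s, j] <- S[s, j] + prod_[[s]]
    for (s in rt$catalysts[[j]]) S[s, j] <- S[s, j] + rt$reactants[[j]][[s]]
  }
  ridx <- lapply(rt$reactants, function(v) match(names(v), sp))
  pidx <- lapply(rt$products, function(v) match(names(v), sp))
  rsto <- lapply(rt$reactants, unname)
  psto <- lapply(rt$products, unname)
  kind <- rt$kind
  kf <- rt$kf; kb <- rt$kb; vmax <- rt$vmax; km <- rt$km
  rates <- function(y) {
    v <- numeric(nr)
    for (j in seq_len(nr)) {
      v[j] <- switch(kind[j],
        mass_irrev = kf[j] * prod(y[ridx[[j]]]^rsto[[j]]),
        mass_rev = kf[j] * prod(y[ridx[[j]]]^rsto[[j]]) -
                   kb[j] * prod(y[pidx[[j]]]^psto[[j]]),
        michaelis_menten = {
          s <- y[ridx[[j]][1]]
          vmax[j] * s / (km[j] + s)
        })
    }
    v
  }
  list(species = sp, S = S, rates = rates)
}

#' Assemble the derivative operator for a network
#'
#' Returns a function mapping a state (named vector or tibble) to the
#' per-species time derivative d[x]/dt = sum over reactions of
#' (net stoichiometry of x) x (reaction rate), in nM/s. Catalysts
#' contribute net zero; degradation ("Null") products contribute nothing.
#'
#' @param network A `reaction_network` that passes [validate_network()].
#' @return A function `state -> named numeric vector` of derivatives.
#' @export
assemble_rhs <- function(network) {
  cmp <- compile_network(network)
  function(state) {
    y <- as_state_vector(state)[cmp$species]
    drop(cmp$S %*% cmp$rates(y))
  }
}

#' Integrate a reaction network over time
#'
#' Deterministic integration with the adaptive, stiff-capable `lsoda`
#' method from \pkg{deSolve}, sampled on the uniform output grid of
#' `settings`.
#'
#' @param network A `reaction_network`.
#' @param init Initial state: tibble with columns `species`,
#'   `concentration_nM` (or a named numeric vector), complete for the
#'   network and non-negative.
#' @param settings A [solver_settings()] object.
#' @return An `aktpi_trajectory`: a tibble with column `time_s` followed by
#'   one concentration column (nM) per species, carrying the settings and
#'   network name as attributes.
#' @examples
#' net <- crosstalk_network()
#' init <- default_initial_conditions()
#' traj <- simulate_network(net, init, solver_settings(horizon = 10))
#' @export
simulate_network <- function(network, init, settings = solver_settings()) {
  stopifnot(inherits(settings, "solver_settings"))
  y0 <- as_state_vector(init, network)
  if (any(y0 < 0)) {
    stop("negative initial concentration for: ",
         paste(names(y0)[y0 < 0], collapse = ", "), call. = FALSE)
  }
  cmp <- compile_network(network)
  times <- seq(0, settings$horizon, by = settings$output_step)
  rhs <- function(t, y, parms) list(drop(cmp$S %*% cmp$rates(y)))
  # integrate two orders tighter than the reporting tolerance so the
  # non-negativity noise bound (>= -abs_tol) holds with margin: lsoda's
  # accumulated undershoot around zero can slightly exceed its per-step
  # atol, so the contract bound cannot double as the solver tolerance.
  args <- list(y = y0, times = times, func = rhs, parms = NULL,
               rtol = settings$rel_tol, atol = settings$abs_tol / 100)
  if (is.finite(settings$max_step)) args$hmax <- settings$max_step
  # lsoda first (nonstiff/stiff switching); its switching heuristic can
  # stall on strongly stiff exponential-growth phases, so a failed run is
  # retried once with the pure-BDF stiff integrator at the same
  # tolerances. Both attempts are deterministic.
  out <- NULL
  for (method in c("lsoda", "bdf")) {
    cand <- suppressWarnings(do.call(deSolve::ode, c(args, method = method)))
    istate <- attr(cand, "istate")
    failed <- (!is.null(istate) && istate[1] < 0) ||
      nrow(cand) < length(times) || !all(is.finite(cand))
    if (!failed) {
      out <- cand
      break
    }
  }
  if (is.null(out)) {
    t_fail <- cand[nrow(cand), 1]
    stop(sprintf("integration failed at t = %g s", t_fail), call. = FALSE)
  }
  vals <- out[, -1, drop = FALSE]
  low <- min(vals)
  if (low < -settings$abs_tol) {
    stop(sprintf(
      "concentration fell below -abs_tol (min %.3g nM); tighten tolerances",
      low), call. = FALSE)
  }
  traj <- tibble::as_tibble(as.data.frame(out))
  names(traj)[1] <- "time_s"
  structure(traj,
            class = c("aktpi_trajectory", class(traj)),
            settings = settings,
            network_name = network$name)
}

#' Write / read a trajectory as CSV
#'
#' CSV with a `time_s` column then one column per species (nM).
#'
#' @param trajectory An `aktpi_trajectory` (or compatible data frame).
#' @param path File path.
#' @return `path` (writer, invisibly) or the trajectory tibble (reader).
#' @export
write_trajectory_csv <- function(trajectory, path) {
  readr::write_csv(tibble::as_tibble(trajectory), path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  traj <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot("time_s" %in% names(traj))
  structure(traj, class = c("aktpi_trajectory", class(traj)))
}
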