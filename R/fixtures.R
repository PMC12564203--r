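# Synthetic baseline inputs. The published model's initial concentrations
# live in supplementary material that only constrains their range
# (0.0009-300 nM, insulin stimulus included), so the default state shipped
# here is an explicit, version-pinned synthetic guess with that structure:
# abundant substrate pools at 10-300 nM, an insulin bolus, and every
# complex / phospho-form at zero pre-stimulus. It is NOT the published
# value set; absolute exposures are therefore not comparable, while
# orderings between scenarios are.

#' Default synthetic initial conditions for the crosstalk network
#'
#' A frozen, documented baseline state: substrate pools (IR, IRS, AKT,
#' GSK3B, PIP2, PI, G, PKC, PTP1B, PI3K, PTEN) at 10-300 nM, an insulin
#' bolus of 100 nM, and all intermediates, complexes and phospho-forms at
#' 0. All values lie in [0, 300] nM. Identical on every call (read from a
#' version-pinned CSV shipped with the package); synthetic, not the
#' published supplementary values.
#'
#' @return A tibble with columns `species`, `concentration_nM` covering
#'   every crosstalk species.
#' @export
default_initial_conditions <- function() {
  path <- system.file("extdata", "synthetic_baseline_initial_conditions.csv",
                      package = "aktpi", mustWork = TRUE)
  readr::read_csv(path, col_types = "cd")
}

#' Load user-supplied initial conditions from CSV
#'
#' Expects columns `species,concentration_nM`. Species names are resolved
#' through the alias map ([resolve_species()]), so underscored or
#' Greek-beta spellings are accepted. Species of the network missing from
#' the file default to 0 with a warning.
#'
#' @param path CSV file path.
#' @param network Network whose species set the state must cover.
#' @return A complete `species`/`concentration_nM` tibble in network order.
#' @export
load_initial_conditions <- function(path, network = crosstalk_network()) {
  raw <- tryCatch(
    readr::read_csv(path, col_types = "cd"),
    error = function(e) stop("cannot read '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!all(c("species", "concentration_nM") %in% names(raw))) {
    stop("'", path, "' must have columns species,concentration_nM",
         call. = FALSE)
  }
  bad <- which(is.na(raw$concentration_nM) | raw$concentration_nM < 0)
  if (length(bad)) {
    stop(sprintf("negative or missing concentration at data row %d (%s)",
                 bad[1], raw$species[bad[1]]), call. = FALSE)
  }
  canon <- resolve_species(raw$species, strict = FALSE)
  if (anyNA(canon)) {
    stop(sprintf("unresolvable species name at data row %d ('%s')",
                 which(is.na(canon))[1], raw$species[which(is.na(canon))[1]]),
         call. = FALSE)
  }
  state <- stats::setNames(raw$concentration_nM, canon)
  missing <- setdiff(network$species$name, names(state))
  if (length(missing)) {
    warning("species missing from '", path, "' set to 0: ",
            paste(missing, collapse = ", "), call. = FALSE)
    state[missing] <- 0
  }
  state <- state[network$species$name]
  tibble::tibble(species = names(state), concentration_nM = unname(state))
}

#' Construct a fixture set
#'
#' A fixture set bundles an initial state with optional per-reaction rate
#' constant overrides, a label and the seed that produced it.
#'
#' @param init `species`/`concentration_nM` tibble.
#' @param parameter_overrides Tibble with columns `reaction_id`, `constant`
#'   (one of `"kf"`, `"kb"`, `"vmax"`, `"km"`) and `value`, or `NULL`.
#' @param label Free-text label.
#' @param seed Integer seed that generated the set, or `NA`.
#' @return An `aktpi_fixture_set` list.
#' @export
fixture_set <- function(init, parameter_overrides = NULL,
                        label = "default", seed = NA_integer_) {
  structure(list(init = init, parameter_overrides = parameter_overrides,
                 label = label, seed = seed),
            class = "aktpi_fixture_set")
}

#' Apply a fixture set's parameter overrides to a network
#'
#' @param network A `reaction_network`.
#' @param fixture An `aktpi_fixture_set`.
#' @return The network with the overridden rate constants.
#' @export
apply_parameter_overrides <- function(network, fixture) {
  ov <- fixture$parameter_overrides
  if (is.null(ov) || !nrow(ov)) return(network)
  rt <- network$reactions
  for (i in seq_len(nrow(ov))) {
    j <- match(ov$reaction_id[i], rt$id)
    if (is.na(j)) stop("override names unknown reaction id ",
                       ov$reaction_id[i], call. = FALSE)
    rt[[ov$constant[i]]][j] <- ov$value[i]
  }
  network$reactions <- rt
  network
}

#' Seeded multiplicative-noise ensemble of fixture sets
#'
#' Each member multiplies every nonzero initial concentration and every
#' nonzero rate constant of `network` by independent lognormal noise with
#' coefficient of variation `cv` and unit mean. Lognormal noise keeps all
#' quantities positive; the seed is an explicit argument, never global
#' state.
#'
#' @param base An `aktpi_fixture_set` (e.g.
#'   `fixture_set(default_initial_conditions())`).
#' @param n Number of members (>= 1).
#' @param cv Coefficient of variation of the noise (>= 0; 0 reproduces the
#'   base).
#' @param seed Integer seed.
#' @param network Network whose rate constants are perturbed.
#' @return A list of `n` `aktpi_fixture_set` objects.
#' @export
perturbed_ensemble <- function(base, n, cv, seed,
                               network = crosstalk_network()) {
  stopifnot(inherits(base, "aktpi_fixture_set"), n >= 1, cv >= 0)
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- -sdlog^2 / 2 # unit-mean multiplier
  rt <- network$reactions
  const_rows <- dplyr::bind_rows(lapply(c("kf", "kb", "vmax", "km"),
    function(k) {
      tibble::tibble(reaction_id = rt$id, constant = k, value = rt[[k]])
    }))
  const_rows <- dplyr::filter(const_rows, .data$value > 0)
  rng <- function(m) stats::rlnorm(m, meanlog, sdlog)
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    init <- base$init
    nz <- init$concentration_nM > 0
    init$concentration_nM[nz] <- init$concentration_nM[nz] * rng(sum(nz))
    ov <- const_rows
    ov$value <- ov$value * rng(nrow(ov))
    fixture_set(init, ov, label = sprintf("%s-perturbed-%03d", base$label, i),
                seed = seed)
  }))
}

#' Write fixture CSVs (initial conditions and parameter overrides)
#'
#' Writes `<label>_init.csv` (`species,concentration_nM`) and, when
#' overrides are present, `<label>_parameters.csv`
#' (`reaction_id,constant,value`) under `dir`.
#'
#' @param fixture An `aktpi_fixture_set`.
#' @param dir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_fixture_csv <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(fixture$label, "_init.csv"))
  readr::write_csv(fixture$init, paths[1])
  if (!is.null(fixture$parameter_overrides)) {
    p2 <- file.path(dir, paste0(fixture$label, "_parameters.csv"))
    readr::write_csv(fixture$parameter_overrides, p2)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
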