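# Test helpers: a self-contained fixed-step RK4 stepper (independent of
# the deSolve-based integration path it is used to check) and compact
# constructors for tiny ad-hoc reaction networks.

# Classic RK4 with a hand-supplied derivative function f(y) -> dy.
rk4_integrate <- function(f, y0, h, horizon, keep_every = 1L) {
  n_steps <- round(horizon / h)
  out_times <- numeric(0)
  out <- NULL
  y <- y0
  keep <- seq(0, n_steps, by = keep_every)
  out <- matrix(NA_real_, nrow = length(keep), ncol = length(y0),
                dimnames = list(NULL, names(y0)))
  out_times <- keep * h
  out[1, ] <- y0
  row <- 2L
  for (i in seq_len(n_steps)) {
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i %in% keep) {
      out[row, ] <- y
      row <- row + 1L
    }
  }
  list(times = out_times, values = out)
}

# Minimal custom network builder for tests. Each reaction is a list:
# list(id, from = named stoich, to = named stoich, kf, kb = 0,
#      reversible = FALSE, kind).
tiny_network <- function(species, reactions, name = "tiny",
                         catalyst_mode = "literal") {
  rows <- lapply(reactions, function(r) {
    tibble::tibble(
      id = as.integer(r$id),
      reversible = isTRUE(r$reversible),
      kind = r$kind %||% if (isTRUE(r$reversible)) "mass_rev" else "mass_irrev",
      kf = r$kf %||% 0, kb = r$kb %||% 0,
      vmax = r$vmax %||% 0, km = r$km %||% 0,
      reactants = list(r$from),
      products = list(r$to %||% stats::setNames(numeric(0), character(0))),
      catalysts = list(r$catalysts %||% character(0))
    )
  })
  aktpi:::new_reaction_network(
    name,
    tibble::tibble(name = species, description = ""),
    dplyr::bind_rows(rows),
    catalyst_mode
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sp <- function(...) {
  x <- c(...)
  stats::setNames(as.numeric(x), names(x))
}

state_tbl <- function(...) {
  v <- sp(...)
  tibble::tibble(species = names(v), concentration_nM = unname(v))
}

# Exposure-percentage pairs printed in the lithium comparison tables
# (p-form exposure, unphosphorylated-form exposure, printed percent).
# The binding-condition pAKT% cell is omitted: it is inconsistent with its
# own printed exposure cells (14.82/473.58 = 3.13, printed 1.88).
printed_percentage_triples <- function() {
  tibble::tribble(
    ~p,      ~base,    ~pct,
    8.92,    473.58,   1.88,   # crosstalk, untreated, pAKT%
    19.26,   818.24,   2.35,   # crosstalk, lithium, pAKT%
    9.37,    162.00,   5.78,   # PI3K-only, untreated, pAKT%
    10.48,   571.93,   1.83,   # PI3K-only, lithium, pAKT%
    268.18,  3931.82,  6.82,   # crosstalk, untreated, pGSK3B%
    327.48,  2327.35,  14.07,  # crosstalk, lithium, pGSK3B%
    275.06,  3924.94,  7.01,   # PI3K-only, untreated, pGSK3B%
    303.57,  3896.44,  7.79,   # PI3K-only, lithium, pGSK3B%
    11.66,   782.62,   1.49,   # AKT-modulation, pAKT%
    335.00,  3865.00,  8.67,   # AKT-modulation, pGSK3B%
    8.90,    496.51,   1.79,   # PIP2-modulation, pAKT%
    264.81,  3935.19,  6.73,   # PIP2-modulation, pGSK3B%
    267.81,  2363.27,  11.33   # binding condition, pGSK3B%
  )
}
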