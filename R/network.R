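# Canonical species of the integrated crosstalk model. "GSK3B" is the ASCII
# canonical form of GSK3beta; user-facing aliases are handled by
# resolve_species(). Complexes and phospho-forms start at zero pre-stimulus.
crosstalk_species <- function() {
  tibble::tribble(
    ~name,        ~description,
    "I",          "insulin",
    "IR",         "insulin receptor",
    "IRL",        "insulin-receptor complex",
    "IRp",        "phosphorylated (active) insulin receptor",
    "IRi",        "internalized insulin receptor",
    "IRS",        "insulin receptor substrate",
    "IRp-IRS",    "active receptor bound to IRS",
    "IRp-IRSp",   "active receptor bound to phosphorylated IRS",
    "PTP1B",      "protein tyrosine phosphatase 1B",
    "PI3K",       "phosphoinositide 3-kinase",
    "IRSp-PI3K",  "phosphorylated IRS bound to PI3K",
    "PIP2",       "phosphatidylinositol 4,5-bisphosphate",
    "PIP3",       "phosphatidylinositol 3,4,5-trisphosphate",
    "PTEN",       "phosphatase and tensin homolog",
    "AKT",        "protein kinase B",
    "pAKT",       "phosphorylated (active) AKT",
    "GSK3B",      "glycogen synthase kinase 3 beta (active)",
    "pGSK3B",     "phosphorylated (inactive) GSK3 beta",
    "IP3",        "inositol 1,4,5-trisphosphate",
    "DAG",        "diacylglycerol",
    "Ins",        "myo-inositol",
    "PI",         "phosphatidylinositol",
    "PIP",        "phosphatidylinositol 4-phosphate",
    "G",          "G protein (inactive)",
    "G-a",        "G protein (active)",
    "PKC",        "protein kinase C (inactive)",
    "PKC-a",      "protein kinase C (active)"
  )
}

# Enzymatic reactants regenerated on the product side in catalytic mode.
catalytic_roles <- c(
  "9" = "PTP1B", "12" = "IRSp-PI3K", "13" = "PTEN",
  "16" = "pAKT", "24" = "G-a", "26" = "DAG"
)

# One row per reaction of the integrated network. reactants/products are
# named numeric vectors of stoichiometries; "Null" products are encoded as
# an empty product list (pure degradation).
crosstalk_reactions <- function(catalyst_mode = c("literal", "catalytic")) {
  catalyst_mode <- match.arg(catalyst_mode)
  sp <- function(...) {
    x <- c(...)
    stats::setNames(as.numeric(x), names(x))
  }
  none <- stats::setNames(numeric(0), character(0))
  rx <- function(id, reactants, products, kind, kf = 0, kb = 0,
                 vmax = 0, km = 0, reversible = FALSE) {
    tibble::tibble(
      id = as.integer(id), reversible = reversible, kind = kind,
      kf = kf, kb = kb, vmax = vmax, km = km,
      reactants = list(reactants), products = list(products),
      catalysts = list(character(0))
    )
  }
  reactions <- dplyr::bind_rows(
    rx(1, sp(I = 1, IR = 1), sp(IRL = 1), "mass_rev", kf = 3.33e-4, kb = 1,
       reversible = TRUE),
    rx(2, sp(IRL = 1), sp(IRp = 1), "mass_irrev", kf = 1.66),
    rx(3, sp(IRp = 1), sp(IRi = 1), "michaelis_menten", vmax = 333, km = 266),
    rx(4, sp(IRi = 1), sp(IRL = 1), "mass_irrev", kf = 0.0166),
    rx(5, sp(IRp = 1), none, "mass_irrev", kf = 1.85e-4),
    rx(6, sp(IRp = 1, IRS = 1), sp(`IRp-IRS` = 1), "mass_rev",
       kf = 0.1066, kb = 3.75, reversible = TRUE),
    rx(7, sp(`IRp-IRS` = 1), sp(IRS = 1), "mass_irrev", kf = 1.85e-4),
    rx(8, sp(`IRp-IRS` = 1), sp(`IRp-IRSp` = 1), "mass_irrev", kf = 0.66),
    rx(9, sp(`IRp-IRSp` = 1, PTP1B = 1), sp(`IRp-IRS` = 1), "mass_irrev",
       kf = 8.75e-5),
    rx(10, sp(`IRp-IRSp` = 1), none, "mass_irrev", kf = 0.001),
    rx(11, sp(`IRp-IRSp` = 1, PI3K = 1), sp(`IRSp-PI3K` = 1), "mass_rev",
       kf = 2.6e-6, kb = 1.55, reversible = TRUE),
    rx(12, sp(`IRSp-PI3K` = 1, PIP2 = 1), sp(PIP3 = 1), "mass_irrev",
       kf = 0.055),
    rx(13, sp(PIP3 = 1, PTEN = 1), sp(PIP2 = 1), "mass_irrev", kf = 0.7025),
    rx(14, sp(AKT = 1, PIP3 = 1), sp(pAKT = 1), "mass_irrev", kf = 3.36),
    rx(15, sp(pAKT = 1), sp(AKT = 1), "mass_irrev", kf = 1.188e-6),
    # "ppAKT" in the source table is identified with pAKT: no reaction
    # produces a distinct doubly-phosphorylated form, which would therefore
    # stay at zero forever. Documented alias, see resolve_species().
    rx(16, sp(pAKT = 1, GSK3B = 1), sp(pGSK3B = 1), "mass_irrev", kf = 0.05),
    rx(17, sp(pGSK3B = 1), sp(GSK3B = 1), "mass_irrev", kf = 0.015),
    rx(18, sp(PIP2 = 1), sp(IP3 = 1, DAG = 1), "mass_irrev", kf = 500.25),
    rx(19, sp(IP3 = 1), sp(Ins = 1), "mass_irrev", kf = 10),
    rx(20, sp(Ins = 1), sp(PI = 1), "mass_irrev", kf = 0.7081),
    # printed as reversible ("=") but with no reverse constant: kb = 0,
    # reversibility flag retained.
    rx(21, sp(PI = 1), sp(PIP = 1), "mass_rev", kf = 0.4, kb = 0,
       reversible = TRUE),
    rx(22, sp(PIP = 1), sp(PIP2 = 1), "mass_rev", kf = 60, kb = 5,
       reversible = TRUE),
    rx(23, sp(G = 1), sp(`G-a` = 1), "mass_rev", kf = 5.18e-6, kb = 0.085,
       reversible = TRUE),
    rx(24, sp(PIP2 = 1, `G-a` = 1), sp(DAG = 1), "mass_irrev", kf = 77.16),
    rx(25, sp(DAG = 1), sp(PIP2 = 1), "mass_irrev", kf = 0.0077),
    rx(26, sp(DAG = 1, PKC = 1), sp(`PKC-a` = 1), "mass_irrev", kf = 1.311),
    rx(27, sp(`PKC-a` = 1), sp(PKC = 1), "mass_irrev", kf = 0.0295),
    rx(28, sp(PIP3 = 1), none, "mass_irrev", kf = 3.33)
  )
  if (catalyst_mode == "catalytic") {
    for (i in seq_len(nrow(reactions))) {
      cat_sp <- unname(catalytic_roles[as.character(reactions$id[i])])
      if (!is.na(cat_sp)) reactions$catalysts[[i]] <- cat_sp
    }
  }
  reactions
}

new_reaction_network <- function(name, species, reactions, catalyst_mode) {
  structure(
    list(name = name, species = species, reactions = reactions,
         catalyst_mode = catalyst_mode),
    class = "reaction_network"
  )
}

#' Build the integrated PI3K/AKT + PI-cycle crosstalk network
#'
#' Constructs the 28-reaction insulin signalling network coupling the
#' PI3K/AKT cascade (insulin binding, receptor and IRS phosphorylation,
#' PI3K recruitment, PIP3 production, AKT activation and GSK3beta
#' phosphorylation) to the phosphatidylinositol second-messenger cycle
#' (PIP2 hydrolysis to IP3/DAG and resynthesis via inositol, PI and PIP).
#' All kinetic constants are compiled in; first-order constants are in
#' s^-1, second-order in nM^-1 s^-1, and the receptor-internalization step
#' follows a single-substrate Michaelis-Menten law (Vmax in nM/s, Km in nM).
#'
#' @param catalyst_mode `"literal"` (default) treats every listed reactant
#'   as consumed, exactly as written by mass action; `"catalytic"`
#'   regenerates the enzymatic reactants (PTP1B, the IRS-PI3K complex,
#'   PTEN, pAKT, active G protein, DAG) on the product side, so their net
#'   stoichiometry is zero. Both conventions ship because the literature
#'   notation is ambiguous; scenario orderings are mode-independent.
#' @return A `reaction_network` object: a list with `name`, a `species`
#'   tibble (`name`, `description`), and a `reactions` tibble (one row per
#'   reaction with rate-law kind, constants and stoichiometry list-columns).
#' @examples
#' net <- crosstalk_network()
#' nrow(net$reactions) # 28
#' @seealso [pi3k_only_network()], [validate_network()], [simulate_network()]
#' @export
crosstalk_network <- function(catalyst_mode = c("literal", "catalytic")) {
  catalyst_mode <- match.arg(catalyst_mode)
  new_reaction_network("crosstalk", crosstalk_species(),
                       crosstalk_reactions(catalyst_mode), catalyst_mode)
}

#' Build the PI3K/AKT-only reduction of the crosstalk network
#'
#' The insulin cascade, AKT/GSK3beta phosphorylation cycle and PIP3
#' degradation (reactions 1-17 and 28) without the phosphatidylinositol
#' cycle, GPCR or PKC branches. Used as the comparison model that lacks
#' PIP2 resynthesis.
#'
#' @inheritParams crosstalk_network
#' @return A `reaction_network` with 18 reactions and the non-PI-cycle
#'   species only.
#' @export
pi3k_only_network <- function(catalyst_mode = c("literal", "catalytic")) {
  catalyst_mode <- match.arg(catalyst_mode)
  keep_ids <- c(1:17, 28L)
  reactions <- dplyr::filter(crosstalk_reactions(catalyst_mode),
                             .data$id %in% keep_ids)
  used <- unique(unlist(lapply(seq_len(nrow(reactions)), function(i) {
    c(names(reactions$reactants[[i]]), names(reactions$products[[i]]))
  })))
  species <- dplyr::filter(crosstalk_species(), .data$name %in% used)
  new_reaction_network("pi3k_only", species, reactions, catalyst_mode)
}

#' Validate a reaction network
#'
#' Checks the structural invariants: unique species names, no declared
#' "Null" species, every referenced species declared, positive integer
#' stoichiometries, non-negative rate constants, rate-law/constant
#' consistency (Michaelis-Menten needs vmax, km > 0 and no mass-action
#' constants; irreversible mass action needs kb = 0), and catalysts being a
#' subset of reactants.
#'
#' @param network A `reaction_network`.
#' @return A tibble of diagnostics with columns `where` (reaction id or
#'   species name) and `message`; zero rows iff the network is well formed.
#' @export
validate_network <- function(network) {
  diags <- list()
  note <- function(where, message) {
    diags[[length(diags) + 1L]] <<- tibble::tibble(
      where = as.character(where), message = message)
  }
  sp <- network$species$name
  if (anyDuplicated(sp)) {
    note(sp[duplicated(sp)][1], "duplicated species name")
  }
  if ("Null" %in% sp) note("Null", "'Null' is a sink, not a species")
  rt <- network$reactions
  for (i in seq_len(nrow(rt))) {
    id <- rt$id[i]
    reac <- rt$reactants[[i]]
    prod <- rt$products[[i]]
    for (s in setdiff(c(names(reac), names(prod)), sp)) {
      note(s, sprintf("reaction %s references undeclared species '%s'", id, s))
    }
    if (anyDuplicated(names(reac)) || anyDuplicated(names(prod))) {
      note(id, sprintf("reaction %s lists a species twice on one side", id))
    }
    stoich <- c(reac, prod)
    if (length(stoich) && (any(stoich <= 0) || any(stoich != round(stoich)))) {
      note(id, sprintf("reaction %s has a non-positive-integer stoichiometry", id))
    }
    consts <- c(kf = rt$kf[i], kb = rt$kb[i], vmax = rt$vmax[i], km = rt$km[i])
    if (any(consts < 0)) {
      note(id, sprintf("reaction %s has a negative rate constant", id))
    }
    if (rt$kind[i] == "michaelis_menten" &&
        !(rt$vmax[i] > 0 && rt$km[i] > 0 && rt$kf[i] == 0 && rt$kb[i] == 0)) {
      note(id, sprintf("reaction %s: Michaelis-Menten law needs vmax, km > 0 and kf = kb = 0", id))
    }
    if (rt$kind[i] == "mass_irrev" && rt$kb[i] != 0) {
      note(id, sprintf("reaction %s: irreversible mass action must have kb = 0", id))
    }
    extra <- setdiff(rt$catalysts[[i]], names(reac))
    if (length(extra)) {
      note(id, sprintf("reaction %s: catalyst '%s' is not a reactant", id, extra[1]))
    }
  }
  if (length(diags)) dplyr::bind_rows(diags) else {
    tibble::tibble(where = character(0), message = character(0))
  }
}

#' Resolve species aliases to canonical names
#'
#' Canonical names use hyphens for complexes (`"IRp-IRSp"`, `"G-a"`,
#' `"PKC-a"`) and ASCII `"GSK3B"`/`"pGSK3B"` for GSK3beta. Underscored
#' forms, Greek-beta spellings, and the `"ppAKT"` alias of `"pAKT"` are all
#' accepted.
#'
#' @param x Character vector of species names.
#' @return Character vector of canonical names; unresolvable names are
#'   returned as `NA` with a warning unless `strict = TRUE`, in which case
#'   they raise an error.
#' @param strict Error on unresolvable names instead of returning `NA`.
#' @export
resolve_species <- function(x, strict = FALSE) {
  canon <- crosstalk_species()$name
  extra <- c("Li", "Cur", "GSK3B-Li", "GSK3B-Cur")
  table <- c(canon, extra)
  key <- function(s) {
    s <- gsub("_", "-", s)
    s <- gsub("\u03b2", "B", s) # Greek beta
    s <- sub("^ppAKT$", "pAKT", s)
    s <- sub("^(p?)GSK3b$", "\\1GSK3B", s)
    toupper(s)
  }
  lookup <- stats::setNames(table, key(table))
  out <- unname(lookup[key(x)])
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    msg <- sprintf("unresolvable species name(s): %s",
                   paste(unique(x[bad]), collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  out
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network: %s> %d species, %d reactions (catalyst mode: %s)\n",
              x$name, nrow(x$species), nrow(x$reactions), x$catalyst_mode))
  invisible(x)
}
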