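# Plain-text reaction-table serialization. One reaction per line:
#   "1: I + IR = IRL | kf=0.000333 kb=1"       (reversible mass action)
#   "2: IRL -> IRp | kf=1.66"                  (irreversible)
#   "3: IRp -> IRi | MM vmax=333 km=266"       (Michaelis-Menten)
#   "13: PIP3 + PTEN -> PIP2 | kf=0.7025 cat=PTEN"
# "Null" on the product side means pure degradation. Constants are written
# with 17 significant digits so that write -> read is numerically exact.

fmt_num <- function(x) sprintf("%.17g", x)

side_to_text <- function(stoich) {
  if (!length(stoich)) return("Null")
  paste(ifelse(stoich == 1, names(stoich),
               paste(fmt_num(stoich), names(stoich))),
        collapse = " + ")
}

parse_side <- function(text) {
  text <- trimws(text)
  if (text == "Null") return(stats::setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(text, "+", fixed = TRUE)[[1]])
  out <- vapply(terms, function(tm) {
    parts <- strsplit(tm, "\\s+")[[1]]
    if (length(parts) == 1) 1 else as.numeric(parts[1])
  }, numeric(1))
  names(out) <- vapply(terms, function(tm) {
    parts <- strsplit(tm, "\\s+")[[1]]
    parts[length(parts)]
  }, character(1))
  out
}

#' Write a reaction network to the plain-text reaction-table format
#'
#' @param network A `reaction_network`.
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @seealso [read_reaction_table()]
#' @export
write_reaction_table <- function(network, path) {
  lines <- c(
    sprintf("# network: %s", network$name),
    sprintf("# catalyst_mode: %s", network$catalyst_mode)
  )
  rt <- network$reactions
  for (i in seq_len(nrow(rt))) {
    arrow <- if (rt$reversible[i]) "=" else "->"
    lhs <- sprintf("%s: %s %s %s", rt$id[i],
                   side_to_text(rt$reactants[[i]]), arrow,
                   side_to_text(rt$products[[i]]))
    rhs <- if (rt$kind[i] == "michaelis_menten") {
      sprintf("MM vmax=%s km=%s", fmt_num(rt$vmax[i]), fmt_num(rt$km[i]))
    } else if (rt$reversible[i]) {
      sprintf("kf=%s kb=%s", fmt_num(rt$kf[i]), fmt_num(rt$kb[i]))
    } else {
      sprintf("kf=%s", fmt_num(rt$kf[i]))
    }
    if (length(rt$catalysts[[i]])) {
      rhs <- paste0(rhs, " cat=", paste(rt$catalysts[[i]], collapse = ","))
    }
    lines <- c(lines, paste(lhs, "|", rhs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a reaction network from the plain-text reaction-table format
#'
#' Species are re-declared from the canonical species table where names are
#' known (descriptions restored), in canonical order; unknown species get an
#' empty description.
#'
#' @param path File path written by [write_reaction_table()].
#' @return A `reaction_network`.
#' @export
read_reaction_table <- function(path) {
  lines <- readLines(path)
  hdr <- function(field, default) {
    m <- grep(sprintf("^# %s:", field), lines, value = TRUE)
    if (length(m)) trimws(sub(sprintf("^# %s:", field), "", m[1])) else default
  }
  name <- hdr("network", "custom")
  catalyst_mode <- hdr("catalyst_mode", "literal")
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- lapply(body, function(ln) {
    halves <- strsplit(ln, "|", fixed = TRUE)[[1]]
    if (length(halves) != 2) stop("malformed reaction line: ", ln, call. = FALSE)
    eqn <- trimws(halves[1]); spec <- trimws(halves[2])
    id <- trimws(sub(":.*$", "", eqn))
    eqn <- trimws(sub("^[^:]*:", "", eqn))
    reversible <- grepl("(^|\\s)=(\\s|$)", eqn)
    arrow <- if (reversible) "=" else "->"
    sides <- strsplit(eqn, arrow, fixed = TRUE)[[1]]
    if (length(sides) != 2) stop("malformed equation: ", eqn, call. = FALSE)
    toks <- strsplit(spec, "\\s+")[[1]]
    is_mm <- identical(toks[1], "MM")
    kv <- toks[grepl("=", toks, fixed = TRUE)]
    vals <- stats::setNames(
      sub("^[^=]*=", "", kv),
      sub("=.*$", "", kv)
    )
    num <- function(k) if (k %in% names(vals)) as.numeric(vals[[k]]) else 0
    tibble::tibble(
      id = if (grepl("^[0-9]+$", id)) as.integer(id) else id,
      reversible = reversible,
      kind = if (is_mm) "michaelis_menten"
             else if (num("kb") > 0 || reversible) "mass_rev" else "mass_irrev",
      kf = num("kf"), kb = num("kb"), vmax = num("vmax"), km = num("km"),
      reactants = list(parse_side(sides[1])),
      products = list(parse_side(sides[2])),
      catalysts = list(
        if ("cat" %in% names(vals)) strsplit(vals[["cat"]], ",")[[1]]
        else character(0))
    )
  })
  reactions <- dplyr::bind_rows(rows)
  used <- unique(unlist(lapply(seq_len(nrow(reactions)), function(i) {
    c(names(reactions$reactants[[i]]), names(reactions$products[[i]]))
  })))
  canon <- crosstalk_species()
  species <- dplyr::bind_rows(
    dplyr::filter(canon, .data$name %in% used),
    tibble::tibble(name = setdiff(used, canon$name), description = "")
  )
  new_reaction_network(name, species, reactions, catalyst_mode)
}

#' Export the species list of a network as CSV
#'
#' Columns `name`, `description`.
#'
#' @inheritParams write_reaction_table
#' @return `path`, invisibly.
#' @export
write_species_csv <- function(network, path) {
  readr::write_csv(network$species, path)
  invisible(path)
}
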