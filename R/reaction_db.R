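# Reaction universe: molecules with elemental formulas and atom lists,
# stoichiometric reactions with EC annotations and direction constraints,
# and per-reaction atom mappings. File formats are KEGG-like flat TSVs.

#' Construct a molecule
#'
#' @param id molecule identifier.
#' @param formula elemental formula string (e.g. `"C6H12O6"`) or named
#'   count vector.
#' @param atoms optional character vector of per-atom element labels
#'   (1-based atom indices); defaults to the formula expanded in order.
#' @return object of class `molecule`.
#' @export
molecule <- function(id, formula, atoms = NULL) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (is.null(atoms)) {
    atoms <- rep(names(counts), times = counts)
  }
  tab <- table(atoms)
  for (el in names(tab)) {
    if (is.na(counts[el]) || counts[el] != tab[[el]]) {
      stop(sprintf("molecule %s: atom list inconsistent with formula for %s",
                   id, el), call. = FALSE)
    }
  }
  structure(list(id = id, counts = counts, atoms = atoms),
            class = "molecule")
}

parse_formula <- function(s) {
  parts <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  parts <- parts[parts != ""]
  if (paste(parts, collapse = "") != s) {
    stop(sprintf("cannot parse formula '%s'", s), call. = FALSE)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- as.integer(ifelse(grepl("[0-9]+$", parts),
                         sub("^[A-Za-z]+", "", parts), "1"))
  out <- tapply(n, el, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Construct a reaction
#'
#' @param id reaction identifier.
#' @param substrates,products named integer vectors: molecule id ->
#'   positive coefficient. Substrate and product molecule sets must be
#'   disjoint.
#' @param ec character vector of complete EC numbers (empty = spontaneous).
#' @param direction `"forward"`, `"reverse"` or `"reversible"`.
#' @param flags named logical list (`general`, `balanced`, ...).
#' @return object of class `reaction`.
#' @export
reaction <- function(id, substrates, products, ec = character(),
                     direction = c("reversible", "forward", "reverse"),
                     flags = list()) {
  direction <- match.arg(direction)
  if (length(ec) > 0) check_complete_ec(ec)
  if (any(substrates < 1) || any(products < 1)) {
    stop(sprintf("reaction %s: coefficients must be >= 1", id), call. = FALSE)
  }
  overlap <- intersect(names(substrates), names(products))
  if (length(overlap) > 0) {
    flags$repeated_molecule <- TRUE
  }
  structure(list(id = id, substrates = substrates, products = products,
                 ec = ec, direction = direction, flags = flags),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  side <- function(v) paste(sprintf("%d %s", unname(v), names(v)),
                            collapse = " + ")
  arrow <- switch(x$direction, forward = "=>", reverse = "<=",
                  reversible = "<=>")
  cat(sprintf("%s: %s %s %s [%s]\n", x$id, side(x$substrates), arrow,
              side(x$products),
              if (length(x$ec)) paste(x$ec, collapse = ";") else "spontaneous"))
  invisible(x)
}

#' Assemble a reaction database
#'
#' @param molecules list of [molecule()]s.
#' @param reactions list of [reaction()]s.
#' @param mappings named list (by reaction id) of atom-mapping data frames
#'   (columns `sub_mol`, `sub_occ`, `sub_atom`, `prod_mol`, `prod_occ`,
#'   `prod_atom`).
#' @param nutrients character vector of nutrient molecule ids.
#' @return object of class `reaction_db`.
#' @export
reaction_db <- function(molecules, reactions, mappings = list(),
                        nutrients = character()) {
  names(molecules) <- vapply(molecules, `[[`, "", "id")
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  for (r in reactions) {
    unknown <- setdiff(c(names(r$substrates), names(r$products)),
                       names(molecules))
    if (length(unknown) > 0) {
      stop(sprintf("reaction %s references unknown molecule(s): %s",
                   r$id, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  if (length(mappings) > 0) {
    unknown <- setdiff(names(mappings), names(reactions))
    if (length(unknown) > 0) {
      stop(sprintf("mapping(s) for unknown reaction(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  bad_nut <- setdiff(nutrients, names(molecules))
  if (length(bad_nut) > 0) {
    stop(sprintf("unknown nutrient molecule(s): %s",
                 paste(bad_nut, collapse = ", ")), call. = FALSE)
  }
  structure(list(molecules = molecules, reactions = reactions,
                 mappings = mappings, nutrients = nutrients),
            class = "reaction_db")
}

#' @export
print.reaction_db <- function(x, ...) {
  cat(sprintf(
    "reaction database: %d molecules, %d reactions (%d mapped), %d nutrients\n",
    length(x$molecules), length(x$reactions), length(x$mappings),
    length(x$nutrients)))
  invisible(x)
}

#' Remove blacklisted "general" reactions
#'
#' Drops reactions that refer to general molecule categories rather than
#' fully specified reactants; the blacklist is an explicit id set (one id
#' per line in file form). Unknown ids are ignored with a warning.
#'
#' @param db a [reaction_db()].
#' @param blacklist character vector of reaction ids.
#' @return filtered [reaction_db()].
#' @export
filter_general <- function(db, blacklist) {
  unknown <- setdiff(blacklist, names(db$reactions))
  if (length(unknown) > 0) {
    warning(sprintf("blacklist id(s) not in database: %s",
                    paste(unknown, collapse = ", ")))
  }
  hit <- intersect(blacklist, names(db$reactions))
  if (length(hit) > 0) {
    message(sprintf("removed %d general reaction(s): %s", length(hit),
                    paste(hit, collapse = ", ")))
  }
  db$reactions <- db$reactions[setdiff(names(db$reactions), hit)]
  db$mappings <- db$mappings[intersect(names(db$mappings),
                                       names(db$reactions))]
  db
}

# formulas of the species that may be added during balancing
.balance_additions <- list(water = c(H = 2L, O = 1L),
                           proton = c(H = 1L),
                           c1 = c(C = 1L, H = 2L, O = 3L)) # carbonic acid

#' Mass-balance a reaction by integer programming
#'
#' Finds integer stoichiometric coefficients satisfying elementwise
#' balance such that every existing reactant keeps at least its original
#' coefficient, no coefficient exceeds `max_coef` (15), and the total
#' coefficient sum is minimal. Water and protons may be added to either
#' side; at most a single C1 unit (carbonic acid) may be added in total.
#' Infeasible reactions are flagged unbalanced and excluded from
#' reconstruction downstream; reactions with a reactant lacking a formula
#' are flagged `missing_formula` (their direction constraints must then be
#' curated manually).
#'
#' @param rxn a [reaction()].
#' @param molecules named list of [molecule()]s.
#' @param elements elements subject to balancing.
#' @param max_coef coefficient upper bound (15).
#' @param water_id,proton_id,c1_id molecule ids used for added species.
#' @return the balanced [reaction()] (flag `balanced = TRUE`), or the
#'   input flagged `balanced = FALSE`.
#' @export
balance_reaction <- function(rxn, molecules,
                             elements = c("C", "H", "O", "N", "S", "P"),
                             max_coef = 15, water_id = "WATER",
                             proton_id = "PROTON", c1_id = "C1") {
  mols <- c(names(rxn$substrates), names(rxn$products))
  have <- vapply(mols, function(m) {
    !is.null(molecules[[m]]) && length(molecules[[m]]$counts) > 0
  }, logical(1))
  if (!all(have)) {
    rxn$flags$balanced <- FALSE
    rxn$flags$missing_formula <- TRUE
    return(rxn)
  }
  if (isTRUE(rxn$flags$repeated_molecule)) {
    rxn$flags$balanced <- FALSE
    return(rxn)
  }
  count_of <- function(m, el) {
    cnt <- molecules[[m]]$counts[el]
    ifelse(is.na(cnt), 0L, cnt)
  }
  ns <- length(rxn$substrates); np <- length(rxn$products)
  add <- .balance_additions
  # variables: existing substrate coefs, existing product coefs,
  # water_s, water_p, proton_s, proton_p, c1_s, c1_p
  nvar <- ns + np + 6L
  lb <- c(unname(rxn$substrates), unname(rxn$products), rep(0, 6))
  ub <- c(rep(max_coef, ns + np), rep(max_coef, 4), 1, 1)
  els <- intersect(elements,
                   unique(c(unlist(lapply(mols, function(m)
                     names(molecules[[m]]$counts))),
                     unlist(lapply(add, names)))))
  A_eq <- matrix(0, length(els), nvar)
  for (i in seq_along(els)) {
    el <- els[i]
    A_eq[i, seq_len(ns)] <- vapply(names(rxn$substrates), count_of,
                                   numeric(1), el = el)
    A_eq[i, ns + seq_len(np)] <- -vapply(names(rxn$products), count_of,
                                         numeric(1), el = el)
    addc <- function(sp) ifelse(is.na(add[[sp]][el]), 0, add[[sp]][el])
    A_eq[i, ns + np + 1:6] <- c(addc("water"), -addc("water"),
                                addc("proton"), -addc("proton"),
                                addc("c1"), -addc("c1"))
  }
  b_eq <- rep(0, length(els))
  A_le <- matrix(0, 1, nvar)
  A_le[1, ns + np + 5:6] <- 1 # at most one C1 unit in total
  # closed-form addition repair at the original coefficients: the added
  # species form a triangular system over C (carbonic acid), then O
  # (water), then H (protons); if feasible it seeds the search and one LP
  # relaxation bound usually certifies it as optimal outright
  incumbent <- NULL
  orig <- c(unname(rxn$substrates), unname(rxn$products))
  d <- as.vector(A_eq[, seq_len(ns + np), drop = FALSE] %*% orig)
  names(d) <- els
  imb <- function(el) if (el %in% els) d[[el]] else 0
  c_net <- imb("C") # c_p - c_s must equal this
  if (abs(c_net) <= 1 && all(d[setdiff(els, c("C", "H", "O"))] == 0)) {
    w_net <- imb("O") - 3 * c_net
    h_net <- imb("H") - 2 * w_net - 2 * c_net
    if (abs(w_net) <= max_coef && abs(h_net) <= max_coef) {
      x0 <- c(orig, max(-w_net, 0), max(w_net, 0), max(-h_net, 0),
              max(h_net, 0), max(-c_net, 0), max(c_net, 0))
      incumbent <- list(objval = sum(x0), x = x0)
    }
  }
  if (!is.null(incumbent)) {
    rel <- lp_solve(rep(1, nvar), lb, ub, A_eq, b_eq, A_le, 1,
                    maximize = FALSE)
    if (rel$status == "optimal" &&
        ceiling(rel$objval - 1e-6) >= incumbent$objval) {
      sol <- list(status = "optimal", objval = incumbent$objval,
                  x = incumbent$x)
    } else {
      sol <- milp_solve(obj = rep(1, nvar), lb = lb, ub = ub,
                        A_eq = A_eq, b_eq = b_eq, A_le = A_le, b_le = 1,
                        maximize = FALSE, incumbent = incumbent)
    }
  } else {
    sol <- milp_solve(obj = rep(1, nvar), lb = lb, ub = ub,
                      A_eq = A_eq, b_eq = b_eq, A_le = A_le, b_le = 1,
                      maximize = FALSE)
  }
  if (sol$status != "optimal") {
    rxn$flags$balanced <- FALSE
    return(rxn)
  }
  x <- round(sol$x)
  subs <- stats::setNames(x[seq_len(ns)], names(rxn$substrates))
  prods <- stats::setNames(x[ns + seq_len(np)], names(rxn$products))
  extra <- x[ns + np + 1:6]
  names(extra) <- c(water_id, water_id, proton_id, proton_id, c1_id, c1_id)
  for (i in c(1, 3, 5)) if (extra[i] > 0) {
    subs[names(extra)[i]] <- unname(extra[i])
  }
  for (i in c(2, 4, 6)) if (extra[i] > 0) {
    prods[names(extra)[i]] <- unname(extra[i])
  }
  out <- reaction(rxn$id, subs, prods, rxn$ec, rxn$direction, rxn$flags)
  if (isTRUE(out$flags$repeated_molecule)) {
    out$flags$balanced <- FALSE
    return(out)
  }
  out$flags$balanced <- TRUE
  out
}

#' Balance every reaction of a database
#'
#' Runs [balance_reaction()] over the reaction table, registering the
#' standard added species (water, proton, carbonic acid) in the molecule
#' table when used.
#'
#' @inheritParams balance_reaction
#' @param db a [reaction_db()].
#' @return the database with balanced reactions and updated flags.
#' @export
balance_db <- function(db, elements = c("C", "H", "O", "N", "S", "P"),
                       max_coef = 15) {
  std <- list(molecule("WATER", "H2O"), molecule("PROTON", "H"),
              molecule("C1", "CH2O3"))
  for (m in std) if (is.null(db$molecules[[m$id]])) db$molecules[[m$id]] <- m
  db$reactions <- lapply(db$reactions, balance_reaction,
                         molecules = db$molecules, elements = elements,
                         max_coef = max_coef)
  db
}

# enumerate atom slots (mol, occurrence, atom index, element) for one side
atom_slots <- function(side, molecules, elements = NULL) {
  out <- do.call(rbind, lapply(names(side), function(m) {
    at <- molecules[[m]]$atoms
    k <- side[[m]]
    data.frame(mol = m, occ = rep(seq_len(k), each = length(at)),
               atom = rep(seq_along(at), times = k),
               element = rep(at, times = k), stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(mol = character(), occ = integer(), atom = integer(),
                      element = character())
  }
  if (!is.null(elements)) out <- out[out$element %in% elements, , drop = FALSE]
  out
}

#' Validate an atom mapping
#'
#' A complete atom mapping is a bijection from substrate atoms to product
#' atoms over the tracked elements, preserving element labels. The check
#' reports every violating pair rather than stopping at the first.
#'
#' @param rxn a balanced [reaction()].
#' @param mapping data.frame with columns `sub_mol`, `sub_occ`,
#'   `sub_atom`, `prod_mol`, `prod_occ`, `prod_atom`.
#' @param molecules named list of [molecule()]s.
#' @param elements elements the mapping is expected to cover; defaults to
#'   the elements appearing in the mapped atoms.
#' @return list with `ok` (logical) and `violations` (character vector of
#'   human-readable problems).
#' @export
validate_mapping <- function(rxn, mapping, molecules, elements = NULL) {
  viol <- character()
  el_of <- function(mol, atom) {
    a <- molecules[[mol]]$atoms
    ifelse(atom >= 1 & atom <= length(a), a[pmin(pmax(atom, 1), length(a))],
           NA_character_)
  }
  sub_el <- mapply(el_of, mapping$sub_mol, mapping$sub_atom)
  prod_el <- mapply(el_of, mapping$prod_mol, mapping$prod_atom)
  bad_idx <- which(is.na(sub_el) | is.na(prod_el))
  for (i in bad_idx) {
    viol <- c(viol, sprintf("row %d: atom index out of range", i))
  }
  mism <- which(!is.na(sub_el) & !is.na(prod_el) & sub_el != prod_el)
  for (i in mism) {
    viol <- c(viol, sprintf("row %d: element changes %s -> %s (%s:%d -> %s:%d)",
                            i, sub_el[i], prod_el[i], mapping$sub_mol[i],
                            mapping$sub_atom[i], mapping$prod_mol[i],
                            mapping$prod_atom[i]))
  }
  skey <- paste(mapping$sub_mol, mapping$sub_occ, mapping$sub_atom)
  pkey <- paste(mapping$prod_mol, mapping$prod_occ, mapping$prod_atom)
  if (anyDuplicated(skey)) viol <- c(viol, "substrate atom mapped twice")
  if (anyDuplicated(pkey)) viol <- c(viol, "product atom mapped twice")
  if (is.null(elements)) {
    elements <- unique(stats::na.omit(c(sub_el, prod_el)))
  }
  ss <- atom_slots(rxn$substrates, molecules, elements)
  pp <- atom_slots(rxn$products, molecules, elements)
  miss_s <- setdiff(paste(ss$mol, ss$occ, ss$atom), skey)
  miss_p <- setdiff(paste(pp$mol, pp$occ, pp$atom), pkey)
  if (length(miss_s) > 0) {
    viol <- c(viol, sprintf("%d substrate atom(s) unmapped", length(miss_s)))
  }
  if (length(miss_p) > 0) {
    viol <- c(viol, sprintf("%d product atom(s) unmapped", length(miss_p)))
  }
  list(ok = length(viol) == 0, violations = viol)
}

#' Greedy atom mapping
#'
#' Element-wise greedy assignment of substrate atoms to product atoms in
#' deterministic order. The result is a valid complete mapping whenever
#' the reaction is balanced over the tracked elements; it makes no claim
#' of chemical optimality (no bond-preservation objective) and is intended
#' for synthetic universes and as a stand-in where curated mappings are
#' not supplied.
#'
#' @param rxn a balanced [reaction()].
#' @param molecules named list of [molecule()]s.
#' @param elements elements to map; default all elements present.
#' @return mapping data.frame as accepted by [validate_mapping()].
#' @export
greedy_map <- function(rxn, molecules, elements = NULL) {
  ss <- atom_slots(rxn$substrates, molecules, elements)
  pp <- atom_slots(rxn$products, molecules, elements)
  out <- list()
  for (el in sort(unique(c(ss$element, pp$element)))) {
    s <- ss[ss$element == el, , drop = FALSE]
    p <- pp[pp$element == el, , drop = FALSE]
    if (nrow(s) != nrow(p)) {
      stop(sprintf(
        "reaction %s: element %s multiset mismatch (%d vs %d atoms); not balanced",
        rxn$id, el, nrow(s), nrow(p)), call. = FALSE)
    }
    if (nrow(s) == 0) next
    out[[el]] <- data.frame(sub_mol = s$mol, sub_occ = s$occ,
                            sub_atom = s$atom, prod_mol = p$mol,
                            prod_occ = p$occ, prod_atom = p$atom,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(sub_mol = character(), sub_occ = integer(),
                      sub_atom = integer(), prod_mol = character(),
                      prod_occ = integer(), prod_atom = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
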