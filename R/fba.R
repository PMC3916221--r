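# Steady-state constraint-based analyses of reconstructed networks:
# biomass component yields and complex-aware gene-knockout growth calls.

#' Build a stoichiometric flux model
#'
#' Assembles the metabolite-by-reaction stoichiometric matrix of a
#' reaction set with flux bounds from direction constraints, exchange
#' reactions opened only for media metabolites, and a biomass
#' pseudo-reaction from a composition table. Optional linear couplings
#' implement the bicarbonate rule (CO2 production must not exceed
#' bicarbonate intake) and a fixed ATP/O flux-ratio equality.
#'
#' Conventions: exchange reaction `EX_<met>` carries stoichiometry
#' `-1 * met`, so positive flux exports and negative flux imports; its
#' lower bound is `-max_uptake` from the media table. A biomass component
#' not produced by any reaction leaves its metabolite row with a single
#' entry, forcing zero biomass flux (structural unproducibility appears as
#' yield 0, no special casing).
#'
#' @param db a [reaction_db()].
#' @param reactions reaction ids to include (e.g.
#'   `recon$accepted$reaction`); default all.
#' @param media data.frame `metabolite`, `max_uptake`.
#' @param biomass data.frame `metabolite`, `coefficient` (consumed
#'   proportions), or `NULL` for a model without a biomass objective.
#' @param directions optional data.frame `reaction`, `lb`, `ub` overriding
#'   the bounds implied by each reaction's direction field.
#' @param max_flux magnitude bound applied to otherwise unbounded fluxes.
#' @param co2_rule optional `c(co2 = <exchange id>, bicarb = <exchange
#'   id>)` enforcing CO2 production <= bicarbonate uptake.
#' @param atp_o optional `list(atp = <rxn id>, o2 = <rxn id>, ratio = 1)`
#'   flux-ratio equality `v_atp = ratio * v_o2`.
#' @return object of class `flux_model`.
#' @export
flux_model <- function(db, reactions = NULL, media, biomass = NULL,
                       directions = NULL, max_flux = 1000,
                       co2_rule = NULL, atp_o = NULL) {
  if (is.null(reactions)) reactions <- names(db$reactions)
  rl <- db$reactions[reactions]
  mets <- sort(unique(c(unlist(lapply(rl, function(r)
    c(names(r$substrates), names(r$products)))),
    media$metabolite,
    if (!is.null(biomass)) biomass$metabolite)))
  rids <- names(rl)
  ex_ids <- paste0("EX_", media$metabolite)
  all_ids <- c(rids, ex_ids, if (!is.null(biomass)) "BIOMASS")
  S <- matrix(0, length(mets), length(all_ids),
              dimnames = list(mets, all_ids))
  lb <- stats::setNames(numeric(length(all_ids)), all_ids)
  ub <- stats::setNames(numeric(length(all_ids)), all_ids)
  for (id in rids) {
    r <- rl[[id]]
    S[names(r$substrates), id] <- S[names(r$substrates), id] - r$substrates
    S[names(r$products), id] <- S[names(r$products), id] + r$products
    lb[id] <- if (r$direction %in% c("reversible", "reverse")) -max_flux else 0
    ub[id] <- if (r$direction %in% c("reversible", "forward")) max_flux else 0
  }
  for (i in seq_along(ex_ids)) {
    S[media$metabolite[i], ex_ids[i]] <- -1
    lb[ex_ids[i]] <- -media$max_uptake[i]
    ub[ex_ids[i]] <- max_flux
  }
  if (!is.null(biomass)) {
    S[biomass$metabolite, "BIOMASS"] <- -biomass$coefficient
    lb["BIOMASS"] <- 0
    ub["BIOMASS"] <- max_flux
  }
  if (!is.null(directions)) {
    unknown <- setdiff(directions$reaction, all_ids)
    if (length(unknown) > 0) {
      stop(sprintf("direction constraint for unknown reaction(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    lb[directions$reaction] <- directions$lb
    ub[directions$reaction] <- directions$ub
  }
  ineq <- list()
  if (!is.null(co2_rule)) {
    a <- stats::setNames(numeric(length(all_ids)), all_ids)
    a[co2_rule[["co2"]]] <- 1   # production (positive exchange flux)
    a[co2_rule[["bicarb"]]] <- 1 # uptake is negative exchange flux
    ineq <- c(ineq, list(list(a = a, b = 0)))
  }
  eq <- list()
  if (!is.null(atp_o)) {
    a <- stats::setNames(numeric(length(all_ids)), all_ids)
    a[atp_o$atp] <- 1
    a[atp_o$o2] <- -(if (is.null(atp_o$ratio)) 1 else atp_o$ratio)
    eq <- c(eq, list(list(a = a, b = 0)))
  }
  structure(list(S = S, lb = lb, ub = ub, mets = mets, rxns = all_ids,
                 objective = if (!is.null(biomass)) "BIOMASS" else NULL,
                 ineq = ineq, eq = eq, max_flux = max_flux),
            class = "flux_model")
}

#' @export
print.flux_model <- function(x, ...) {
  cat(sprintf("flux model: %d metabolites x %d reactions%s\n",
              nrow(x$S), ncol(x$S),
              if (is.null(x$objective)) "" else
                sprintf(" (objective %s)", x$objective)))
  invisible(x)
}

#' Maximum steady-state yield of a flux
#'
#' Linear-program maximum of the objective flux subject to `S v = 0`, the
#' flux bounds and any coupling constraints. Yields within `tol` of zero
#' are reported as exactly 0; an infeasible positive objective also yields
#' 0.
#'
#' @param model a [flux_model()].
#' @param objective reaction id to maximize; defaults to the model
#'   objective (biomass).
#' @param tol degeneracy tolerance (1e-6).
#' @return named list `yield` (non-negative), `status`, `fluxes` (named
#'   vector, `NULL` when infeasible).
#' @export
max_yield <- function(model, objective = model$objective, tol = 1e-6) {
  if (is.null(objective) || !(objective %in% model$rxns)) {
    stop("objective reaction not in model", call. = FALSE)
  }
  if (any(!is.finite(model$lb)) || any(!is.finite(model$ub))) {
    bad <- model$rxns[!is.finite(model$lb) | !is.finite(model$ub)]
    stop(sprintf("unbounded flux bound(s) on: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  n <- ncol(model$S)
  obj <- stats::setNames(numeric(n), model$rxns)
  obj[objective] <- 1
  A_eq <- model$S
  b_eq <- rep(0, nrow(model$S))
  for (e in model$eq) {
    A_eq <- rbind(A_eq, e$a)
    b_eq <- c(b_eq, e$b)
  }
  A_le <- NULL; b_le <- NULL
  if (length(model$ineq) > 0) {
    A_le <- do.call(rbind, lapply(model$ineq, `[[`, "a"))
    b_le <- vapply(model$ineq, `[[`, numeric(1), "b")
  }
  sol <- lp_solve(obj, model$lb, model$ub, A_eq, b_eq, A_le, b_le,
                  maximize = TRUE)
  if (sol$status != "optimal") {
    return(list(yield = 0, status = sol$status, fluxes = NULL))
  }
  y <- sol$objval
  list(yield = if (abs(y) < tol) 0 else y, status = "optimal",
       fluxes = stats::setNames(sol$x, model$rxns))
}

#' Per-component biomass yields
#'
#' Maximum producible flux of each biomass component, obtained by adding
#' a temporary demand reaction per component and maximizing it.
#'
#' @param model a [flux_model()].
#' @param components metabolite ids; defaults to the metabolites consumed
#'   by the biomass reaction.
#' @return named numeric vector of yields (0 for absent or unproducible
#'   components).
#' @export
component_yields <- function(model, components = NULL) {
  if (is.null(components)) {
    components <- model$mets[model$S[, "BIOMASS"] < 0]
  }
  vapply(components, function(met) {
    if (!(met %in% model$mets)) return(0)
    m2 <- model
    dm <- paste0("DM_", met)
    m2$S <- cbind(m2$S, stats::setNames(numeric(nrow(m2$S)), NULL))
    colnames(m2$S)[ncol(m2$S)] <- dm
    m2$S[met, dm] <- -1
    m2$lb <- c(m2$lb, stats::setNames(0, dm))
    m2$ub <- c(m2$ub, stats::setNames(m2$max_flux, dm))
    m2$rxns <- c(m2$rxns, dm)
    for (i in seq_along(m2$ineq)) {
      m2$ineq[[i]]$a <- c(m2$ineq[[i]]$a, stats::setNames(0, dm))
    }
    for (i in seq_along(m2$eq)) {
      m2$eq[[i]]$a <- c(m2$eq[[i]]$a, stats::setNames(0, dm))
    }
    max_yield(m2, dm)$yield
  }, numeric(1))
}

#' Reactions deleted by a gene knockout under the complex rule
#'
#' Deleting a gene inactivates every protein complex containing it. A
#' co-member gene counts as lost only when it belongs to at least one
#' complex and no complex containing it remains functional (evaluated to
#' a fixpoint). A reaction is removed only when, for every EC number
#' associated with it, no functional gene annotated with that EC remains
#' (functional paralogs rescue the reaction).
#'
#' @param gene gene id to knock out.
#' @param complex_map list with `complexes` (data.frame `complex`,
#'   `gene`), `gene_ec` (data.frame `gene`, `ec`) and `ec_rxn`
#'   (data.frame `ec`, `reaction`); see [build_complex_map()].
#' @return list with `reactions` (ids to remove) and `lost_genes`.
#' @export
knockout_deletions <- function(gene, complex_map) {
  genes <- unique(c(complex_map$complexes$gene, complex_map$gene_ec$gene))
  if (!(gene %in% genes)) {
    stop(sprintf("unknown gene: %s", gene), call. = FALSE)
  }
  cx <- complex_map$complexes
  lost <- gene
  repeat {
    dead_cx <- unique(cx$complex[cx$gene %in% lost])
    in_cx <- unique(cx$gene)
    newly <- vapply(setdiff(in_cx, lost), function(g) {
      my_cx <- cx$complex[cx$gene == g]
      all(my_cx %in% dead_cx)
    }, logical(1))
    newly <- setdiff(in_cx, lost)[newly]
    if (length(newly) == 0) break
    lost <- c(lost, newly)
  }
  functional <- setdiff(genes, lost)
  ge <- complex_map$gene_ec
  live_ecs <- unique(ge$ec[ge$gene %in% functional])
  er <- complex_map$ec_rxn
  mapped_rxns <- unique(er$reaction)
  removed <- vapply(mapped_rxns, function(r) {
    ecs <- er$ec[er$reaction == r]
    length(ecs) > 0 && !any(ecs %in% live_ecs)
  }, logical(1))
  list(reactions = sort(mapped_rxns[removed]), lost_genes = sort(lost))
}

#' Assemble a gene-complex-EC-reaction association map
#'
#' @param complexes data.frame `complex`, `gene`.
#' @param gene_ec data.frame `gene`, `ec`.
#' @param db optional [reaction_db()] used to derive the EC-to-reaction
#'   table; alternatively pass `ec_rxn` directly.
#' @param ec_rxn data.frame `ec`, `reaction`.
#' @export
build_complex_map <- function(complexes, gene_ec, db = NULL, ec_rxn = NULL) {
  if (is.null(ec_rxn)) {
    if (is.null(db)) stop("need db or ec_rxn", call. = FALSE)
    ec_rxn <- do.call(rbind, lapply(db$reactions, function(r) {
      if (length(r$ec) == 0) return(NULL)
      data.frame(ec = r$ec, reaction = r$id, stringsAsFactors = FALSE)
    }))
    if (is.null(ec_rxn)) {
      ec_rxn <- data.frame(ec = character(), reaction = character())
    }
  }
  list(complexes = complexes, gene_ec = gene_ec, ec_rxn = ec_rxn)
}

#' Growth call for one knockout case
#'
#' Zeroes the deleted reactions' bounds, recomputes the biomass maximum,
#' and normalizes by the wild-type maximum. The prediction agrees with
#' the observation when the absolute difference of the two normalized
#' growth rates (both in \[0, 1\]) is at most 0.5. Growth predictions
#' (normalized rate > 0.5) classify as TP when correct and FP when not;
#' no-growth predictions as TN / FN. Cases whose deletion set is empty
#' are flagged trivial and excluded from headline metrics downstream.
#'
#' @param model wild-type [flux_model()] with a biomass objective.
#' @param deletions reaction ids removed by the knockout.
#' @param observed normalized observed growth rate in \[0, 1\].
#' @return list of class `growth_call`: `normalized`, `observed`, `call`,
#'   `trivial`.
#' @export
predict_growth <- function(model, deletions, observed) {
  stopifnot(observed >= 0, observed <= 1)
  wild <- max_yield(model)
  if (wild$status != "optimal" || wild$yield <= 0) {
    stop("wild-type model has no positive biomass flux", call. = FALSE)
  }
  mut <- model
  hit <- intersect(deletions, mut$rxns)
  mut$lb[hit] <- 0
  mut$ub[hit] <- 0
  g <- max_yield(mut)$yield / wild$yield
  g <- min(max(g, 0), 1)
  predicted_growth <- g > 0.5
  correct <- abs(g - observed) <= 0.5
  call <- if (predicted_growth) {
    if (correct) "TP" else "FP"
  } else {
    if (correct) "TN" else "FN"
  }
  structure(list(normalized = g, observed = observed, call = call,
                 trivial = length(deletions) == 0),
            class = "growth_call")
}

#' @export
print.growth_call <- function(x, ...) {
  cat(sprintf("%s: predicted %.3f vs observed %.3f%s\n", x$call,
              x$normalized, x$observed, if (x$trivial) " (trivial)" else ""))
  invisible(x)
}

#' Confusion metrics over growth calls
#'
#' @param calls list of [predict_growth()] results.
#' @param drop_trivial exclude cases with empty deletion sets (default).
#' @return list with counts `tp`, `fp`, `tn`, `fn`, `total` and
#'   `sensitivity`, `specificity`, `precision`, `f1`.
#' @export
growth_confusion <- function(calls, drop_trivial = TRUE) {
  if (drop_trivial) calls <- Filter(function(x) !x$trivial, calls)
  lab <- vapply(calls, `[[`, "", "call")
  tp <- sum(lab == "TP"); fp <- sum(lab == "FP")
  tn <- sum(lab == "TN"); fn <- sum(lab == "FN")
  safe <- function(a, b) if (b > 0) a / b else NA_real_
  prec <- safe(tp, tp + fp)
  sens <- safe(tp, tp + fn)
  list(tp = tp, fp = fp, tn = tn, fn = fn, total = length(calls),
       sensitivity = sens, specificity = safe(tn, tn + fp),
       precision = prec,
       f1 = if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
         2 * prec * sens / (prec + sens) else NA_real_)
}

#' @rdname flux_model
#' @param path file path.
#' @export
read_media <- function(path) {
  read_tsv_checked(path, c("metabolite", "max_uptake"), "max_uptake")
}

#' @rdname flux_model
#' @export
read_biomass <- function(path) {
  read_tsv_checked(path, c("metabolite", "coefficient"), "coefficient")
}

#' @rdname flux_model
#' @export
read_directions <- function(path) {
  read_tsv_checked(path, c("reaction", "lb", "ub"), c("lb", "ub"))
}

#' Export a flux model as a MatrixMarket S-matrix plus bounds TSV
#'
#' @param model a [flux_model()].
#' @param dir output directory (`S.mtx`, `bounds.tsv`, `metabolites.txt`,
#'   `reactions.txt`).
#' @export
write_flux_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- which(model$S != 0, arr.ind = TRUE)
  con <- file(file.path(dir, "S.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nrow(model$S), ncol(model$S), nrow(nz))),
             con)
  o <- order(nz[, 2], nz[, 1])
  writeLines(sprintf("%d %d %.10g", nz[o, 1], nz[o, 2], model$S[nz[o, ,
             drop = FALSE]]), con)
  close(con)
  write_tsv(data.frame(reaction = model$rxns, lb = unname(model$lb),
                       ub = unname(model$ub)), file.path(dir, "bounds.tsv"))
  writeLines(model$mets, file.path(dir, "metabolites.txt"))
  writeLines(model$rxns, file.path(dir, "reactions.txt"))
  invisible(dir)
}
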