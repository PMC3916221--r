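# Phase II: greedy assembly of a gapless, atom-traced metabolic network.
# Reactions carry a logarithmic cost derived from the phase-one posteriors;
# the assembler adds a candidate reaction only when a cheap biosynthesis
# pathway connects every one of its substrate atoms to the nutrient set,
# pulling in weakly supported gap-filling reactions only when connectivity
# demands them.

#' Logarithmic reaction costs from enzyme posteriors
#'
#' Each reaction is assigned `-ln(p) + base_cost` where `p` is the maximum
#' posterior over the reaction's annotated ECs (the enzyme giving maximal
#' support), floored to keep costs finite. Reactions without any EC
#' annotation (spontaneous) get the fixed `spontaneous_cost`.
#'
#' @param posteriors named numeric vector, EC -> posterior, for the species
#'   being reconstructed (one node of the phylogeny).
#' @param db a [reaction_db()].
#' @param base_cost non-negative cost added to every scored reaction.
#' @param spontaneous_cost fixed cost for EC-less reactions.
#' @param posterior_floor floor applied to posteriors (default 1e-12).
#' @return named numeric vector of costs, one per reaction in `db`.
#' @export
reaction_costs <- function(posteriors, db, base_cost = 1,
                           spontaneous_cost = 2, posterior_floor = 1e-12) {
  stopifnot(base_cost >= 0)
  vapply(db$reactions, function(r) {
    if (length(r$ec) == 0) return(spontaneous_cost)
    p <- posteriors[r$ec]
    p <- max(c(p[!is.na(p)], posterior_floor))
    -log(max(p, posterior_floor)) + base_cost
  }, numeric(1))
}

#' Convert a posterior threshold to a cost threshold
#'
#' @param p posterior probability threshold.
#' @param base_cost base cost used in [reaction_costs()].
#' @export
posterior_to_cost <- function(p, base_cost = 1) {
  -log(p) + base_cost
}

atom_node <- function(mol, atom) paste0(mol, "#", atom)

# unique tracked substrate/product atom nodes of a reaction, read off its
# atom mapping (only mapped atoms take part in connectivity)
mapping_atoms <- function(mapping) {
  list(sub = unique(atom_node(mapping$sub_mol, mapping$sub_atom)),
       prod = unique(atom_node(mapping$prod_mol, mapping$prod_atom)))
}

#' Build the atom graph of a reaction universe
#'
#' Nodes are (molecule, atom index) pairs of every mapped atom plus one
#' atom node per nutrient-molecule atom; a directed edge labeled with the
#' reaction id connects each mapped substrate atom to its product atom
#' (occurrences collapsed). Reversible reactions contribute edges in both
#' directions; direction-constrained reactions only one. A synthetic
#' source vertex feeds every nutrient atom with zero-cost edges so that
#' multi-source reachability and shortest paths reduce to single-source
#' operations.
#'
#' @param db a [reaction_db()] with validated mappings.
#' @param reactions reaction ids to include (default: all balanced, mapped
#'   reactions).
#' @return list of class `atom_graph`: `graph` (igraph), `source` (vertex
#'   name), `sub_atoms`/`prod_atoms` (per-reaction atom node lists),
#'   `reactions`.
#' @export
build_atom_graph <- function(db, reactions = NULL) {
  if (is.null(reactions)) {
    reactions <- names(db$reactions)[vapply(db$reactions, function(r) {
      !isTRUE(r$flags$balanced == FALSE) && !is.null(db$mappings[[r$id]])
    }, logical(1))]
  } else {
    unmapped <- reactions[vapply(reactions, function(id)
      is.null(db$mappings[[id]]), logical(1))]
    if (length(unmapped) > 0) {
      stop(sprintf("reaction(s) without atom mapping: %s",
                   paste(unmapped, collapse = ", ")), call. = FALSE)
    }
  }
  reactions <- sort(reactions)
  src <- "..nutrients.."
  from <- character(); to <- character(); lab <- character()
  sub_atoms <- list(); prod_atoms <- list()
  for (id in reactions) {
    m <- db$mappings[[id]]
    a <- atom_node(m$sub_mol, m$sub_atom)
    b <- atom_node(m$prod_mol, m$prod_atom)
    keep <- !duplicated(paste(a, b))
    a <- a[keep]; b <- b[keep]
    dir <- db$reactions[[id]]$direction
    if (dir %in% c("forward", "reversible")) {
      from <- c(from, a); to <- c(to, b); lab <- c(lab, rep(id, length(a)))
    }
    if (dir %in% c("reverse", "reversible")) {
      from <- c(from, b); to <- c(to, a); lab <- c(lab, rep(id, length(a)))
    }
    ma <- mapping_atoms(m)
    sub_atoms[[id]] <- sort(ma$sub)
    prod_atoms[[id]] <- sort(ma$prod)
  }
  nutrient_atoms <- unlist(lapply(db$nutrients, function(m) {
    atom_node(m, seq_along(db$molecules[[m]]$atoms))
  }))
  verts <- sort(unique(c(from, to, nutrient_atoms)))
  from <- c(rep(src, length(nutrient_atoms)), from)
  to <- c(nutrient_atoms, to)
  lab <- c(rep(NA_character_, length(nutrient_atoms)), lab)
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(c(src, verts))
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$reaction <- lab
  structure(list(graph = g, source = src, sub_atoms = sub_atoms,
                 prod_atoms = prod_atoms, reactions = reactions),
            class = "atom_graph")
}

#' @export
print.atom_graph <- function(x, ...) {
  cat(sprintf("atom graph: %d atom nodes, %d edges, %d reactions\n",
              igraph::vcount(x$graph) - 1L, igraph::ecount(x$graph),
              length(x$reactions)))
  invisible(x)
}

edge_weights <- function(ag, costs, free) {
  rxn <- igraph::E(ag$graph)$reaction
  w <- unname(costs[rxn])
  w[is.na(rxn) | rxn %in% free] <- 0
  w[is.na(w)] <- Inf
  w
}

#' Atoms reachable from the nutrient set
#'
#' @param ag an [build_atom_graph()] object.
#' @param allowed reaction ids whose edges may be used.
#' @return character vector of reachable atom node names.
#' @export
reachable_atoms <- function(ag, allowed) {
  keep <- which(is.na(igraph::E(ag$graph)$reaction) |
                  igraph::E(ag$graph)$reaction %in% allowed)
  sg <- igraph::subgraph_from_edges(ag$graph, keep, delete.vertices = FALSE)
  out <- igraph::subcomponent(sg, ag$source, mode = "out")
  setdiff(names(out), ag$source)
}

#' Estimated cost of adding a reaction to the network
#'
#' The ordering heuristic of the assembler: for each substrate atom of the
#' candidate, the cost of the cheapest reaction path from the nutrients
#' (edges of already-accepted reactions cost zero, other edges their
#' reaction's cost), summed over substrate atoms. Unreachable atoms make
#' the estimate infinite.
#'
#' @param rxn reaction id.
#' @param ag an [build_atom_graph()] object.
#' @param costs named cost vector ([reaction_costs()]).
#' @param accepted reaction ids already in the network.
#' @return non-negative estimate (possibly `Inf`).
#' @export
estimate_addition_cost <- function(rxn, ag, costs, accepted = character()) {
  w <- edge_weights(ag, costs, accepted)
  d <- igraph::distances(ag$graph, v = ag$source, mode = "out", weights = w)
  sum(d[1, ag$sub_atoms[[rxn]]])
}

flagged_atoms <- function(ag, accepted, pathway, rxn) {
  members <- c(pathway, rxn)
  need <- unique(unlist(ag$sub_atoms[members], use.names = FALSE))
  reach <- reachable_atoms(ag, c(accepted, members))
  sort(setdiff(need, reach))
}

#' Search for a gapless biosynthesis pathway supporting a reaction
#'
#' Best-first search over partial pathways, kept in a priority queue by
#' accumulated cost (each member reaction counted once; accepted reactions
#' are free). The cheapest partial pathway is expanded by the `k` cheapest
#' linear reaction paths that connect the nutrients to its first flagged
#' atom (an atom of a pathway member's substrate not yet traced to
#' nutrients). A pathway with no flagged atoms is complete; the first
#' complete pathway popped is cost-minimal. Search stops at `budget`
#' expansions (reported as a search-limit rejection, distinct from a cost
#' rejection).
#'
#' @param rxn candidate reaction id (its own cost is not part of the
#'   pathway cost; the caller screens it against the acceptance threshold).
#' @param ag an [build_atom_graph()] object.
#' @param costs named cost vector.
#' @param accepted reaction ids already in the network.
#' @param rho_reject maximum admissible pathway cost.
#' @param k linear reaction paths considered per flagged atom.
#' @param budget maximum number of queue expansions.
#' @return on success a list with `reactions` (gapfill pathway members)
#'   and `cost`; on failure a list with `reactions = NULL` and `reason`
#'   (`"cost"`, `"budget"` or `"unreachable"`).
#' @export
find_gapfill_pathway <- function(rxn, ag, costs, accepted = character(),
                                 rho_reject = posterior_to_cost(1e-4),
                                 k = 5, budget = 10000) {
  queue_cost <- numeric(0)
  queue_size <- integer(0)
  queue_key <- character(0)
  queue_set <- list()
  queue_flag <- list()
  seen <- character(0)

  push <- function(set, cost) {
    key <- paste(set, collapse = "|")
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    fl <- flagged_atoms(ag, accepted, set, rxn)
    queue_cost <<- c(queue_cost, cost)
    queue_size <<- c(queue_size, length(set))
    queue_key <<- c(queue_key, key)
    queue_set[[length(queue_set) + 1L]] <<- set
    queue_flag[[length(queue_flag) + 1L]] <<- fl
    invisible()
  }
  pop <- function() {
    o <- order(queue_cost, queue_size, queue_key)[1]
    out <- list(cost = queue_cost[o], set = queue_set[[o]],
                flagged = queue_flag[[o]])
    queue_cost <<- queue_cost[-o]
    queue_size <<- queue_size[-o]
    queue_key <<- queue_key[-o]
    queue_set[[o]] <<- NULL
    queue_flag[[o]] <<- NULL
    out
  }

  push(character(0), 0)
  expansions <- 0L
  cost_pruned <- FALSE
  while (length(queue_cost) > 0) {
    node <- pop()
    if (length(node$flagged) == 0) {
      if (node$cost <= rho_reject) {
        return(list(reactions = node$set, cost = node$cost))
      }
      return(list(reactions = NULL, reason = "cost"))
    }
    expansions <- expansions + 1L
    if (expansions > budget) {
      return(list(reactions = NULL, reason = "budget"))
    }
    target <- node$flagged[1]
    free <- c(accepted, node$set, rxn)
    w <- edge_weights(ag, costs, free)
    paths <- tryCatch(
      suppressWarnings(igraph::k_shortest_paths(
        ag$graph, from = ag$source, to = target, k = k, weights = w,
        mode = "out")$epaths),
      error = function(e) list())
    for (ep in paths) {
      rids <- igraph::E(ag$graph)$reaction[as.integer(ep)]
      new <- setdiff(rids[!is.na(rids)], free)
      if (length(new) == 0) next
      set <- sort(unique(c(node$set, new)))
      cost <- sum(costs[set])
      if (!is.finite(cost) || cost > rho_reject) {
        cost_pruned <- TRUE
        next
      }
      push(set, cost)
    }
  }
  list(reactions = NULL,
       reason = if (cost_pruned) "cost" else "unreachable")
}

#' Reconstruct a gapless metabolic network for one species
#'
#' The phase-two assembler. Candidate reactions are those whose cost is at
#' most `rho_accept`; they are visited in increasing order of estimated
#' addition cost ([estimate_addition_cost()], re-estimated after every
#' accepted addition). For each candidate a gapless biosynthesis pathway
#' from the nutrients is sought ([find_gapfill_pathway()]); on success the
#' candidate and the pathway members are added (members whose own cost
#' exceeds `rho_accept` carry provenance `"gapfill"`), on failure the
#' candidate is rejected (policy `"reject"`, keeping the network gapless)
#' or added with a gap flag (policy `"add_with_gap"`). Ties break by
#' reaction id, making the reconstruction deterministic.
#'
#' @param db a [reaction_db()] with balanced, mapped reactions and a
#'   non-empty nutrient set.
#' @param costs named cost vector from [reaction_costs()].
#' @param rho_accept acceptance threshold on reaction cost; the default
#'   corresponds to posterior 0.5 at base cost 1.
#' @param rho_reject rejection threshold on gapfill pathway cost; the
#'   default corresponds to posterior 1e-4 at base cost 1.
#' @param policy `"reject"` or `"add_with_gap"`.
#' @param k,budget search parameters of [find_gapfill_pathway()].
#' @param species species (tree node) label recorded in the result.
#' @return object of class `reconstruction` with `accepted` (data.frame
#'   `reaction`, `cost`, `provenance`, `gap_flag`), `rejected`
#'   (data.frame `reaction`, `reason`) and the call parameters.
#' @export
reconstruct <- function(db, costs,
                        rho_accept = posterior_to_cost(0.5),
                        rho_reject = posterior_to_cost(1e-4),
                        policy = c("reject", "add_with_gap"),
                        k = 5, budget = 10000, species = NA_character_) {
  policy <- match.arg(policy)
  if (length(db$nutrients) == 0) {
    stop("nutrient set must be non-empty", call. = FALSE)
  }
  ag <- build_atom_graph(db)
  costs <- costs[ag$reactions]
  if (any(!is.finite(costs))) {
    stop("costs must be finite for every mapped reaction", call. = FALSE)
  }
  candidates <- sort(names(costs)[costs <= rho_accept])
  accepted <- character(0)
  prov <- character(0)
  gap_flag <- logical(0)
  rejected <- data.frame(reaction = character(), reason = character(),
                         stringsAsFactors = FALSE)
  while (length(candidates) > 0) {
    w <- edge_weights(ag, costs, accepted)
    d <- igraph::distances(ag$graph, v = ag$source, mode = "out", weights = w)
    est <- vapply(candidates, function(id) sum(d[1, ag$sub_atoms[[id]]]),
                  numeric(1))
    ord <- order(est, candidates)
    id <- candidates[ord[1]]
    candidates <- setdiff(candidates, id)
    if (!is.finite(est[ord[1]])) {
      path <- list(reactions = NULL, reason = "unreachable")
    } else {
      path <- find_gapfill_pathway(id, ag, costs, accepted, rho_reject,
                                   k, budget)
    }
    if (!is.null(path$reactions)) {
      new <- c(id, setdiff(path$reactions, accepted))
      accepted <- c(accepted, new)
      prov <- c(prov, ifelse(costs[new] > rho_accept, "gapfill", "scored"))
      gap_flag <- c(gap_flag, rep(FALSE, length(new)))
      candidates <- setdiff(candidates, new)
    } else if (policy == "add_with_gap") {
      accepted <- c(accepted, id)
      prov <- c(prov, "scored")
      gap_flag <- c(gap_flag, TRUE)
    } else {
      rejected <- rbind(rejected,
                        data.frame(reaction = id, reason = path$reason,
                                   stringsAsFactors = FALSE))
    }
  }
  o <- order(accepted)
  structure(list(
    species = species,
    accepted = data.frame(reaction = accepted[o],
                          cost = unname(costs[accepted[o]]),
                          provenance = prov[o], gap_flag = gap_flag[o],
                          stringsAsFactors = FALSE),
    rejected = rejected,
    nutrients = db$nutrients,
    params = list(rho_accept = rho_accept, rho_reject = rho_reject,
                  policy = policy, k = k, budget = budget)),
    class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("gapless reconstruction%s: %d reactions (%d gapfill), %d rejected\n",
              if (is.na(x$species)) "" else sprintf(" [%s]", x$species),
              nrow(x$accepted), sum(x$accepted$provenance == "gapfill"),
              nrow(x$rejected)))
  invisible(x)
}

#' @export
summary.reconstruction <- function(object, ...) {
  acc <- object$accepted
  out <- list(species = object$species,
              n_accepted = nrow(acc),
              n_gapfill = sum(acc$provenance == "gapfill"),
              n_gapped = sum(acc$gap_flag),
              rejected_by_reason = table(object$rejected$reason),
              params = object$params)
  class(out) <- "summary.reconstruction"
  out
}

#' @export
print.summary.reconstruction <- function(x, ...) {
  cat(sprintf("species: %s\naccepted: %d (gapfill %d, gap-flagged %d)\n",
              x$species, x$n_accepted, x$n_gapfill, x$n_gapped))
  if (length(x$rejected_by_reason)) {
    cat("rejections:\n"); print(x$rejected_by_reason)
  }
  cat(sprintf("thresholds: accept %.4g, reject %.4g; policy %s\n",
              x$params$rho_accept, x$params$rho_reject, x$params$policy))
  invisible(x)
}

#' @rdname reconstruct
#' @param recon a `reconstruction`.
#' @param path output TSV path.
#' @export
write_reconstruction <- function(recon, path) {
  write_tsv(recon$accepted, path)
}

#' Predicted EC numbers of a reconstruction
#'
#' @param recon a `reconstruction`.
#' @param db the [reaction_db()] used to build it.
#' @return sorted character vector of complete EC numbers carried by
#'   accepted reactions.
#' @export
reconstruction_ecs <- function(recon, db) {
  sort(unique(unlist(lapply(db$reactions[recon$accepted$reaction],
                            `[[`, "ec"))))
}
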