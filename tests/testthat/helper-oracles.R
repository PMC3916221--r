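# Independent oracles: brute-force enumeration and hand-rolled graph
# search, deliberately sharing no code paths with the package internals.

# exact marginal posteriors by enumerating all joint presence states
enum_posterior <- function(tree, edge_cpds, evidence = NULL,
                           root_prior = 0.5) {
  n <- tree$n
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  pg <- stats::setNames(edge_cpds$p_gain, edge_cpds$child)
  ps <- stats::setNames(edge_cpds$p_stay, edge_cpds$child)
  jp <- apply(states, 1, function(s) {
    p <- if (s[tree$root] == 1) root_prior else 1 - root_prior
    for (v in seq_len(n)) {
      if (v == tree$root) next
      nm <- tree$names[v]
      pr <- if (s[tree$parent[v]] == 1) ps[[nm]] else pg[[nm]]
      p <- p * (if (s[v] == 1) pr else 1 - pr)
    }
    if (!is.null(evidence)) {
      for (nm in rownames(evidence)) {
        v <- match(nm, tree$names)
        p <- p * evidence[nm, s[v] + 1]
      }
    }
    p
  })
  marg <- vapply(seq_len(n), function(v) sum(jp[states[, v] == 1]) / sum(jp),
                 numeric(1))
  stats::setNames(marg, tree$names)
}

# minimal parsimony change count by enumerating internal labelings
enum_fitch <- function(tree, leaf_states) {
  internal <- which(!tree$is_leaf)
  full <- integer(tree$n)
  full[tree$is_leaf] <- leaf_states[tree$names[tree$is_leaf]]
  if (length(internal) == 0) return(0L)
  combos <- as.matrix(expand.grid(rep(list(0:1), length(internal))))
  edges <- which(tree$parent != 0L)
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    full[internal] <- combos[i, ]
    ch <- sum(full[edges] != full[tree$parent[edges]])
    if (ch < best) best <- ch
  }
  best
}

# minimal balanced coefficient sum by exhaustive search over the existing
# coefficient grid, with per-assignment addition repair done by direct
# elementary arithmetic (water fixes O, protons fix H, at most one
# carbonic acid fixes C)
exhaustive_balance <- function(rxn, molecules,
                               elements = c("C", "H", "O", "N", "S", "P"),
                               max_coef = 15) {
  mols <- c(names(rxn$substrates), names(rxn$products))
  sign <- c(rep(1, length(rxn$substrates)), rep(-1, length(rxn$products)))
  els <- intersect(elements, unique(c("C", "H", "O",
                                      unlist(lapply(mols, function(m)
                                        names(molecules[[m]]$counts))))))
  cnt <- sapply(mols, function(m) {
    v <- molecules[[m]]$counts[els]
    v[is.na(v)] <- 0L
    v
  })
  cnt <- matrix(cnt, nrow = length(els), dimnames = list(els, mols))
  orig <- c(unname(rxn$substrates), unname(rxn$products))
  grids <- lapply(orig, function(o) o:max_coef)
  grid <- as.matrix(expand.grid(grids))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    x <- grid[i, ]
    d <- as.vector(cnt %*% (x * sign)) # substrate minus product totals
    names(d) <- els
    other <- setdiff(els, c("C", "H", "O"))
    if (length(other) > 0 && any(d[other] != 0)) next
    dc <- if ("C" %in% els) d[["C"]] else 0
    if (abs(dc) > 1) next
    dw <- (if ("O" %in% els) d[["O"]] else 0) - 3 * dc
    dh <- (if ("H" %in% els) d[["H"]] else 0) - 2 * dw - 2 * dc
    if (abs(dw) > max_coef || abs(dh) > max_coef) next
    total <- sum(x) + abs(dw) + abs(dh) + abs(dc)
    if (total < best) best <- total
  }
  best
}

# hand-rolled BFS gaplessness certificate over mapping-pair edges
bfs_gapless <- function(db, accepted) {
  atom_id <- function(mol, atom) paste0(mol, "#", atom)
  edges_from <- character(0)
  edges_to <- character(0)
  sub_atoms <- list()
  for (id in accepted) {
    m <- db$mappings[[id]]
    a <- atom_id(m$sub_mol, m$sub_atom)
    b <- atom_id(m$prod_mol, m$prod_atom)
    dir <- db$reactions[[id]]$direction
    if (dir %in% c("forward", "reversible")) {
      edges_from <- c(edges_from, a); edges_to <- c(edges_to, b)
    }
    if (dir %in% c("reverse", "reversible")) {
      edges_from <- c(edges_from, b); edges_to <- c(edges_to, a)
    }
    sub_atoms[[id]] <- unique(a)
  }
  reached <- unique(unlist(lapply(db$nutrients, function(m)
    atom_id(m, seq_along(db$molecules[[m]]$atoms)))))
  repeat {
    new <- unique(edges_to[edges_from %in% reached])
    new <- setdiff(new, reached)
    if (length(new) == 0) break
    reached <- c(reached, new)
  }
  gapless <- all(vapply(accepted, function(id)
    all(sub_atoms[[id]] %in% reached), logical(1)))
  list(gapless = gapless, reached = reached)
}

# minimum-cost gapfill set by subset enumeration: cheapest P such that in
# accepted + P + rxn every member of P + rxn has all substrate atoms
# reachable
enum_gapfill <- function(db, costs, rxn, accepted = character()) {
  pool <- setdiff(names(db$mappings), c(accepted, rxn))
  best <- Inf
  best_set <- NULL
  for (mask in 0:(2^length(pool) - 1)) {
    set <- pool[bitwAnd(mask, 2^(seq_along(pool) - 1)) > 0]
    cost <- sum(costs[set])
    if (cost >= best) next
    res <- bfs_gapless(db, c(accepted, set, rxn))
    atom_id <- function(mol, atom) paste0(mol, "#", atom)
    need_ok <- all(vapply(c(set, rxn), function(id) {
      m <- db$mappings[[id]]
      all(unique(atom_id(m$sub_mol, m$sub_atom)) %in% res$reached)
    }, logical(1)))
    if (need_ok) {
      best <- cost
      best_set <- set
    }
  }
  list(cost = best, set = best_set)
}

# random rooted bifurcating tree with simple labels
random_tree <- function(n_leaves) {
  rooted_tree(ape::rtree(n_leaves,
                         tip.label = paste0("t", seq_len(n_leaves))))
}

# random edge CPD table for a tree
random_edge_cpds <- function(tree) {
  child <- tree$names[which(tree$parent != 0L)]
  data.frame(parent = tree$names[tree$parent[which(tree$parent != 0L)]],
             child = child,
             p_gain = stats::runif(length(child), 0.02, 0.45),
             p_stay = stats::runif(length(child), 0.55, 0.98),
             stringsAsFactors = FALSE)
}
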