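test_that("reaction costs follow the max-posterior log rule", {
  db <- chain_db(ecs = c("1.1.1.1", "2.2.2.2", "3.3.3.3"))
  post <- c("1.1.1.1" = 1.0, "2.2.2.2" = exp(-2), "3.3.3.3" = 0.25)
  costs <- reaction_costs(post, db, base_cost = 0)
  expect_equal(unname(costs["r1"]), 0)
  costs2 <- reaction_costs(post, db, base_cost = 0.5)
  expect_equal(unname(costs2["r2"]), 2.5)
  # a reaction annotated with several ECs uses the best-supported one
  db2 <- chain_db()
  db2$reactions[["r1"]]$ec <- c("1.1.1.1", "9.9.9.9")
  post2 <- c("1.1.1.1" = 0.9, "9.9.9.9" = 0.1)
  expect_equal(unname(reaction_costs(post2, db2, base_cost = 0)["r1"]),
               -log(0.9))
  # spontaneous reactions get the fixed cost; unseen posteriors the floor
  db3 <- chain_db()
  db3$reactions[["r2"]]$ec <- character()
  c3 <- reaction_costs(c("1.1.1.1" = 0.5), db3, spontaneous_cost = 2)
  expect_equal(unname(c3["r2"]), 2)
  expect_equal(unname(c3["r3"]), -log(1e-12) + 1)
})

test_that("the atom graph encodes mapped atom transfer with directions", {
  db <- chain_db()
  ag <- build_atom_graph(db)
  # no accepted reactions: only the nutrient's own atoms are reachable
  # (every atom of a nutrient molecule is a source, carbons are #1-#2)
  expect_setequal(reachable_atoms(ag, character()), paste0("A#", 1:8))
  expect_setequal(reachable_atoms(ag, "r1"),
                  c(paste0("A#", 1:8), "B#1", "B#2"))
  expect_setequal(setdiff(reachable_atoms(ag, c("r1", "r2", "r3")),
                          paste0("A#", 1:8)),
                  paste0(rep(c("B", "C", "D"), each = 2), "#", 1:2))
  # edge count: one per mapping pair plus one source edge per nutrient atom
  expect_equal(igraph::ecount(ag$graph),
               8 + sum(vapply(db$mappings, nrow, 0L)))
  # the independent BFS certificate agrees along the chain
  oracle <- bfs_gapless(db, c("r1", "r2", "r3"))
  expect_true(oracle$gapless)
  expect_setequal(setdiff(oracle$reached, reachable_atoms(ag,
                  c("r1", "r2", "r3"))), character())
  # a reversible reaction also carries atoms backwards
  dbr <- chain_db(directions = c("forward", "reversible", "forward"))
  agr <- build_atom_graph(dbr)
  expect_true("B#1" %in% reachable_atoms(agr, "r2") == FALSE)
  dbr$nutrients <- "C"
  agr2 <- build_atom_graph(dbr)
  expect_true(all(c("B#1", "B#2") %in% reachable_atoms(agr2, "r2")))
  expect_error(build_atom_graph(db, "missing"), "without atom mapping")
})

test_that("addition cost estimates sum per-atom shortest paths", {
  db <- chain_db()
  ag <- build_atom_graph(db)
  costs <- c(r1 = 1, r2 = 2, r3 = 4)
  # substrates already nutrients: estimate 0
  expect_equal(estimate_addition_cost("r1", ag, costs), 0)
  # two carbon atoms of B each need the r1 path
  expect_equal(estimate_addition_cost("r2", ag, costs), 2)
  expect_equal(estimate_addition_cost("r3", ag, costs), 6)
  # accepted reactions are free
  expect_equal(estimate_addition_cost("r3", ag, costs,
                                      accepted = c("r1", "r2")), 0)
  # a single-atom precursor one cheap reaction away costs that reaction
  mols <- lapply(c("N1", "U", "V"), molecule, formula = "CH2O")
  rxns <- list(
    reaction("p1", c(N1 = 1), c(U = 1), direction = "forward"),
    reaction("p2", c(U = 1), c(V = 1), direction = "forward"))
  db1 <- reaction_db(mols, rxns, nutrients = "N1")
  db1 <- balance_db(db1)
  db1$mappings <- lapply(db1$reactions, greedy_map,
                         molecules = db1$molecules, elements = "C")
  ag1 <- build_atom_graph(db1)
  expect_equal(estimate_addition_cost("p2", ag1, c(p1 = 0.7, p2 = 1)), 0.7)
  # unreachable substrate: infinite estimate
  db2 <- chain_db()
  db2$mappings[["r1"]] <- NULL
  ag2 <- build_atom_graph(db2)
  expect_equal(estimate_addition_cost("r2", ag2, costs), Inf)
})

test_that("gapfill search finds minimum-cost pathways or reports why not", {
  db <- chain_db()
  ag <- build_atom_graph(db)
  costs <- c(r1 = 1, r2 = 0.4, r3 = 0.2)
  # substrates all nutrients: empty pathway at zero cost
  p0 <- find_gapfill_pathway("r1", ag, costs, rho_reject = 10)
  expect_equal(p0$reactions, character(0))
  expect_equal(p0$cost, 0)
  # two-step biosynthesis route assembled and certified minimal
  p3 <- find_gapfill_pathway("r3", ag, costs, rho_reject = 5, k = 10)
  expect_setequal(p3$reactions, c("r1", "r2"))
  expect_equal(p3$cost, 1.4)
  oracle <- enum_gapfill(db, costs, "r3")
  expect_equal(p3$cost, oracle$cost)
  # the same route beyond the rejection threshold is refused
  pr <- find_gapfill_pathway("r3", ag, costs, rho_reject = 1.3, k = 10)
  expect_null(pr$reactions)
  expect_equal(pr$reason, "cost")
  # exhausted search budget is reported distinctly
  pb <- find_gapfill_pathway("r3", ag, costs, rho_reject = 5, budget = 0)
  expect_equal(pb$reason, "budget")
  # cheaper of two parallel routes wins
  dd <- diamond_db()
  agd <- build_atom_graph(dd)
  cd <- c(r1 = 0.3, r2 = 0.3, r3 = 0.1, r4 = 2, r5 = 0.2)
  pd <- find_gapfill_pathway("r5", agd, cd, rho_reject = 10, k = 10)
  expect_setequal(pd$reactions, c("r1", "r2"))
  expect_equal(pd$cost, enum_gapfill(dd, cd, "r5")$cost)
  # disconnected substrate: unreachable
  db2 <- chain_db()
  db2$mappings[["r1"]] <- NULL
  ag2 <- build_atom_graph(db2)
  pu <- find_gapfill_pathway("r3", ag2, costs, rho_reject = 10)
  expect_equal(pu$reason, "unreachable")
})

test_that("gapfill optimality holds on random small universes", {
  set.seed(101)
  checked <- 0
  for (i in 1:8) {
    u <- generate_universe(n_molecules = 9, n_reactions = 11, n_ec = 8,
                           n_nutrients = 3, seed = 200 + i)
    db <- u$db
    if (length(db$mappings) < 4) next
    ag <- build_atom_graph(db)
    costs <- setNames(runif(length(ag$reactions), 0.1, 2), ag$reactions)
    # the deepest reaction (largest addition estimate) as target
    est <- vapply(ag$reactions, estimate_addition_cost, numeric(1),
                  ag = ag, costs = costs)
    target <- names(which.max(replace(est, !is.finite(est), -1)))
    got <- find_gapfill_pathway(target, ag, costs, rho_reject = 50,
                                k = 1000, budget = 1e5)
    want <- enum_gapfill(db, costs, target)
    if (is.null(got$reactions)) {
      expect_false(is.finite(want$cost))
    } else {
      expect_equal(got$cost, want$cost, tolerance = 1e-9)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 3)
})

test_that("reconstruction accepts, gapfills and rejects as configured", {
  # every candidate fed by nutrients: all accepted, no gapfill
  db <- chain_db()
  db$nutrients <- c("A", "B", "C")
  costs <- c(r1 = 1, r2 = 1, r3 = 1)
  rec <- reconstruct(db, costs, rho_accept = 1.5, species = "sp")
  expect_equal(rec$accepted$reaction, c("r1", "r2", "r3"))
  expect_true(all(rec$accepted$provenance == "scored"))
  expect_equal(nrow(rec$rejected), 0)
  # a high-probability reaction pulls in its low-probability precursor
  db2 <- chain_db()
  costs2 <- c(r1 = 5, r2 = 0.5, r3 = 0.6) # r1 unsupported but needed
  rec2 <- reconstruct(db2, costs2, rho_accept = 1.7, rho_reject = 10)
  expect_setequal(rec2$accepted$reaction, c("r1", "r2", "r3"))
  expect_equal(rec2$accepted$provenance[rec2$accepted$reaction == "r1"],
               "gapfill")
  expect_equal(rec2$accepted$provenance[rec2$accepted$reaction == "r2"],
               "scored")
  # under a tight rejection threshold the dependents are rejected instead
  rec3 <- reconstruct(db2, costs2, rho_accept = 1.7, rho_reject = 2)
  expect_false("r2" %in% rec3$accepted$reaction)
  expect_true(all(rec3$rejected$reason == "cost"))
  # ... and policy add_with_gap admits them with an explicit gap flag
  rec4 <- reconstruct(db2, costs2, rho_accept = 1.7, rho_reject = 2,
                      policy = "add_with_gap")
  expect_true("r2" %in% rec4$accepted$reaction)
  expect_true(rec4$accepted$gap_flag[rec4$accepted$reaction == "r2"])
  # determinism: identical inputs give identical reconstructions
  expect_identical(reconstruct(db2, costs2)$accepted,
                   reconstruct(db2, costs2)$accepted)
})

test_that("accepted scored reactions grow with the acceptance threshold", {
  u <- generate_universe(n_molecules = 25, n_reactions = 45, n_ec = 30,
                         seed = 17)
  set.seed(18)
  post <- setNames(runif(length(u$ec_universe)), u$ec_universe)
  costs <- reaction_costs(post, u$db)
  prev <- character(0)
  for (p in c(0.9, 0.6, 0.3, 0.05)) {
    rec <- reconstruct(u$db, costs, rho_accept = posterior_to_cost(p))
    scored <- rec$accepted$reaction[rec$accepted$provenance == "scored"]
    expect_true(all(prev %in% scored))
    prev <- scored
  }
})

test_that("reject-policy reconstructions are certified gapless by BFS", {
  for (s in 1:3) {
    u <- generate_universe(n_molecules = 30, n_reactions = 60, n_ec = 40,
                           seed = 300 + s)
    set.seed(400 + s)
    post <- setNames(rbeta(length(u$ec_universe), 0.6, 0.6), u$ec_universe)
    costs <- reaction_costs(post, u$db)
    rec <- reconstruct(u$db, costs)
    expect_true(bfs_gapless(u$db, rec$accepted$reaction)$gapless)
  }
})

test_that("SBML export is valid, annotated and byte-deterministic", {
  db <- chain_db()
  costs <- c(r1 = 0.2, r2 = 0.5, r3 = 0.9)
  rec <- reconstruct(db, costs, species = "yeast-like")
  d <- withr::local_tempdir()
  f1 <- file.path(d, "model.sbml")
  export_sbml(rec, db, f1)
  s <- read_sbml_summary(f1)
  expect_equal(s$n_reactions, 3)
  expect_equal(s$n_species, 4)
  expect_equal(sort(s$reactions$id), c("r1", "r2", "r3"))
  expect_true(all(s$reactions$provenance == "scored"))
  expect_true(all(s$reactions$n_atom_pairs == 2))
  expect_equal(s$reactions$ec[s$reactions$id == "r1"], "1.1.1.1")
  # write -> read -> write gives identical bytes
  f2 <- file.path(d, "model2.sbml")
  export_sbml(rec, db, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # empty reconstruction still produces a valid document
  rec0 <- reconstruct(db, costs + 100, rho_accept = 1)
  f0 <- file.path(d, "empty.sbml")
  export_sbml(rec0, db, f0)
  s0 <- read_sbml_summary(f0)
  expect_equal(s0$n_reactions, 0)
  expect_equal(s0$n_species, 1) # the nutrient
})
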