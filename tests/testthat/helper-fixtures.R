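# Small hand-built fixtures assembled in code.

# linear chain A -> B -> C -> D of two-carbon molecules (identical
# formulas, so the equations balance as written); A is the nutrient
chain_db <- function(ecs = c("1.1.1.1", "2.2.2.2", "3.3.3.3"),
                     directions = rep("forward", 3)) {
  mols <- lapply(c("A", "B", "C", "D"), molecule, formula = "C2H4O2")
  rxns <- list(
    reaction("r1", c(A = 1), c(B = 1), ec = ecs[1],
             direction = directions[1]),
    reaction("r2", c(B = 1), c(C = 1), ec = ecs[2],
             direction = directions[2]),
    reaction("r3", c(C = 1), c(D = 1), ec = ecs[3],
             direction = directions[3]))
  db <- reaction_db(mols, rxns, nutrients = "A")
  db <- balance_db(db)
  db$mappings <- lapply(db$reactions, greedy_map, molecules = db$molecules,
                        elements = "C")
  db
}

# two parallel two-step routes to a product, for gapfill scenarios:
#   N -r1-> X -r2-> P      (cheap route)
#   N -r3-> Y -r4-> P      (alternative route)
#   P -r5-> Q              (the well-supported target)
diamond_db <- function() {
  mols <- lapply(c("N", "X", "Y", "P", "Q"), molecule, formula = "C3H6O3")
  rxns <- list(
    reaction("r1", c(N = 1), c(X = 1), ec = "1.1.1.1", direction = "forward"),
    reaction("r2", c(X = 1), c(P = 1), ec = "1.1.1.2", direction = "forward"),
    reaction("r3", c(N = 1), c(Y = 1), ec = "1.1.1.3", direction = "forward"),
    reaction("r4", c(Y = 1), c(P = 1), ec = "1.1.1.4", direction = "forward"),
    reaction("r5", c(P = 1), c(Q = 1), ec = "1.1.1.5", direction = "forward"))
  db <- reaction_db(mols, rxns, nutrients = "N")
  db <- balance_db(db)
  db$mappings <- lapply(db$reactions, greedy_map, molecules = db$molecules,
                        elements = "C")
  db
}

# random small balanced toy reaction over C/H/O (occasionally N) for the
# balancing oracle comparisons
random_toy_reaction <- function(id = "toy", p_nitrogen = 0.15) {
  n_sub <- sample(1:2, 1)
  n_prod <- sample(1:2, 1)
  total <- n_sub + n_prod
  mols <- lapply(seq_len(total), function(i) {
    f <- c(C = sample(1:4, 1), H = sample(1:8, 1), O = sample(0:3, 1))
    if (stats::runif(1) < p_nitrogen) f["N"] <- sample(0:1, 1)
    f <- f[f > 0]
    molecule(sprintf("%s_m%d", id, i), f)
  })
  names(mols) <- vapply(mols, `[[`, "", "id")
  subs <- stats::setNames(sample(1:2, n_sub, replace = TRUE),
                          names(mols)[seq_len(n_sub)])
  prods <- stats::setNames(sample(1:2, n_prod, replace = TRUE),
                           names(mols)[n_sub + seq_len(n_prod)])
  list(rxn = reaction(id, subs, prods), molecules = mols)
}

# tiny flux model: exchange A -> A -> P chain with optional branch
toy_chain_model <- function(uptake = 1) {
  mols <- lapply(c("A", "P"), molecule, formula = "C1H2O1")
  rxns <- list(reaction("v1", c(A = 1), c(P = 1), direction = "forward"))
  db <- reaction_db(mols, rxns)
  flux_model(db, media = data.frame(metabolite = "A", max_uptake = uptake),
             biomass = data.frame(metabolite = "P", coefficient = 1))
}

# gene-complex association fixture mirroring the published knockout example
fig6_map <- function() {
  complexes <- data.frame(
    complex = c("K1", "K1", "K2", "K2", "K3", "K3", "K4", "K4"),
    gene = c("YEL039C", "YDL178W", "YEL039C", "YEL071W",
             "YEL071W", "YJR048W", "YEL039C", "YJR048W"),
    stringsAsFactors = FALSE)
  gene_ec <- data.frame(gene = c("YDL178W", "YEL071W", "YJR048W"),
                        ec = c("1.2.1.1", "1.2.1.2", "1.2.1.3"),
                        stringsAsFactors = FALSE)
  ec_rxn <- data.frame(ec = c("1.2.1.1", "1.2.1.2", "1.2.1.3"),
                       reaction = c("rx1", "rx2", "rx3"),
                       stringsAsFactors = FALSE)
  build_complex_map(complexes, gene_ec, ec_rxn = ec_rxn)
}
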