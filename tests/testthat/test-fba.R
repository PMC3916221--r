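# hand-built flux models with closed-form LP optima

test_that("linear chain and branch yields match closed-form solutions", {
  # A_ext -> A -> P with uptake bound 1 and 1:1 stoichiometry: yield 1
  m <- toy_chain_model(uptake = 1)
  res <- max_yield(m)
  expect_equal(res$yield, 1)
  expect_equal(unname(res$fluxes["EX_A"]), -1)
  # doubling the uptake doubles the yield (bound relaxation monotonicity)
  expect_equal(max_yield(toy_chain_model(uptake = 2))$yield, 2)
  # branch: A -> B (v1), 2 B -> P (v2): max P = uptake / 2
  mols <- lapply(c("A", "B", "P"), molecule, formula = "CH2O")
  rxns <- list(reaction("v1", c(A = 1), c(B = 1), direction = "forward"),
               reaction("v2", c(B = 2), c(P = 1), direction = "forward"))
  db <- reaction_db(mols, rxns)
  mod <- flux_model(db, media = data.frame(metabolite = "A",
                                           max_uptake = 1),
                    biomass = data.frame(metabolite = "P", coefficient = 1))
  expect_equal(max_yield(mod)$yield, 0.5)
  # reaction made irreversible against the productive direction: yield 0
  mod2 <- flux_model(db, media = data.frame(metabolite = "A",
                                            max_uptake = 1),
                     biomass = data.frame(metabolite = "P",
                                          coefficient = 1),
                     directions = data.frame(reaction = "v1", lb = -1000,
                                             ub = 0))
  expect_equal(max_yield(mod2)$yield, 0)
  # closing the exchange forbids any positive biomass
  mod3 <- flux_model(db, media = data.frame(metabolite = "A",
                                            max_uptake = 0),
                     biomass = data.frame(metabolite = "P",
                                          coefficient = 1))
  expect_equal(max_yield(mod3)$yield, 0)
})

test_that("absent biomass components force zero yield structurally", {
  mols <- lapply(c("A", "P"), molecule, formula = "CH2O")
  rxns <- list(reaction("v1", c(A = 1), c(P = 1), direction = "forward"))
  db <- reaction_db(mols, rxns)
  # biomass needs P and a ghost component never produced
  mod <- flux_model(db, media = data.frame(metabolite = "A",
                                           max_uptake = 1),
                    biomass = data.frame(metabolite = c("P", "GHOST"),
                                         coefficient = c(1, 0.1)))
  expect_equal(max_yield(mod)$yield, 0)
  ys <- component_yields(mod)
  expect_equal(unname(ys["GHOST"]), 0)
  expect_equal(unname(ys["P"]), 1)
})

test_that("the bicarbonate coupling caps CO2 production", {
  # v1 releases CO2 (exported); v2 consumes the bicarbonate taken up
  mols <- list(molecule("A", "C2H4O2"), molecule("P", "CH2O"),
               molecule("CO2", "CO2"), molecule("HCO3", "CH2O3"),
               molecule("W", "CH2O2"))
  names(mols) <- c("A", "P", "CO2", "HCO3", "W")
  rxns <- list(reaction("v1", c(A = 1), c(P = 1, CO2 = 1),
                        direction = "forward"),
               reaction("v2", c(HCO3 = 1), c(W = 1),
                        direction = "forward"))
  db <- reaction_db(mols, rxns)
  media <- data.frame(metabolite = c("A", "CO2", "HCO3", "W"),
                      max_uptake = c(1, 0, 0.4, 0))
  mod <- flux_model(db, media = media,
                    biomass = data.frame(metabolite = "P", coefficient = 1),
                    co2_rule = c(co2 = "EX_CO2", bicarb = "EX_HCO3"))
  # CO2 production (= flux v1) may not exceed bicarbonate intake (<= 0.4)
  expect_equal(max_yield(mod)$yield, 0.4)
  # without the rule the full uptake converts
  mod_free <- flux_model(db, media = media,
                         biomass = data.frame(metabolite = "P",
                                              coefficient = 1))
  expect_equal(max_yield(mod_free)$yield, 1)
})

test_that("the ATP/O flux-ratio equality binds", {
  # respiration toy: v_atp produces ATPp from A; v_o2 burns A with O2
  mols <- lapply(c("A", "ATPp", "W", "O2"), molecule, formula = "CH2O")
  rxns <- list(reaction("v_atp", c(A = 1), c(ATPp = 1),
                        direction = "forward"),
               reaction("v_o2", c(A = 1, O2 = 1), c(W = 2),
                        direction = "forward"))
  db <- reaction_db(mols, rxns)
  mod <- flux_model(db,
                    media = data.frame(metabolite = c("A", "O2", "W"),
                                       max_uptake = c(10, 2, 0)),
                    biomass = data.frame(metabolite = "ATPp",
                                         coefficient = 1),
                    atp_o = list(atp = "v_atp", o2 = "v_o2", ratio = 1))
  # ATP flux is tied to the oxygen-consuming flux, itself capped at 2
  expect_equal(max_yield(mod)$yield, 2)
})

test_that("complex-aware knockouts reproduce the consensus-model pattern", {
  cm <- fig6_map()
  # knocking out YEL039C kills every complex containing it; YDL178W has
  # no other complex and is lost, YEL071W survives through its complex
  # with YJR048W, so only YDL178W's reaction goes
  res <- knockout_deletions("YEL039C", cm)
  expect_true("YDL178W" %in% res$lost_genes)
  expect_false("YEL071W" %in% res$lost_genes)
  expect_false("YJR048W" %in% res$lost_genes)
  expect_equal(res$reactions, "rx1")
  expect_error(knockout_deletions("YZZ999W", cm), "unknown gene")
})

test_that("paralogs outside complexes rescue reactions", {
  cm <- fig6_map()
  # a second gene with YDL178W's EC, not in any complex
  cm$gene_ec <- rbind(cm$gene_ec,
                      data.frame(gene = "YPL999W", ec = "1.2.1.1"))
  res <- knockout_deletions("YEL039C", cm)
  expect_equal(res$reactions, character(0))
  # an EC carried by no reaction deletes nothing
  cm2 <- fig6_map()
  cm2$ec_rxn <- cm2$ec_rxn[0, ]
  expect_equal(knockout_deletions("YDL178W", cm2)$reactions, character(0))
})

test_that("growth calls follow the half-unit agreement rule", {
  m <- toy_chain_model(uptake = 1)
  # empty deletion set: trivial case, normalized growth one
  g0 <- predict_growth(m, character(), observed = 1)
  expect_true(g0$trivial)
  expect_equal(g0$normalized, 1)
  expect_equal(g0$call, "TP")
  # deleting the only route with no observed growth: correct no-growth
  g1 <- predict_growth(m, "v1", observed = 0)
  expect_equal(g1$normalized, 0)
  expect_equal(g1$call, "TN")
  # predicted growth 1 against observed 0: FP; observed 1 with predicted
  # 0: FN
  expect_equal(predict_growth(m, character(), observed = 0)$call, "FP")
  expect_equal(predict_growth(m, "v1", observed = 1)$call, "FN")
})

test_that("confusion metrics over growth calls match hand counts", {
  m <- toy_chain_model(uptake = 1)
  cases <- list( # (deletions, observed) -> expected call
    list(character(), 1, "TP", TRUE), # trivial, excluded
    list("v1", 0, "TN", FALSE),
    list("v1", 1, "FN", FALSE),
    list(character(), 0, "FP", TRUE), # trivial, excluded
    list("v1", 0, "TN", FALSE),
    list("v1", 0.8, "FN", FALSE))
  calls <- lapply(cases, function(cs) predict_growth(m, cs[[1]], cs[[2]]))
  expect_equal(vapply(calls, `[[`, "", "call"),
               vapply(cases, `[[`, "", 3))
  conf <- growth_confusion(calls)
  expect_equal(c(conf$tp, conf$fp, conf$tn, conf$fn), c(0, 0, 2, 2))
  expect_equal(conf$total, 4)
  expect_equal(conf$specificity, 1)
  # identities on a random fixture with both growth and no-growth calls
  set.seed(131)
  obs <- runif(20)
  dels <- lapply(rbinom(20, 1, 0.5), function(k)
    if (k == 1) "v1" else character())
  calls2 <- mapply(function(d, o) predict_growth(m, d, o), dels, obs,
                   SIMPLIFY = FALSE)
  conf2 <- growth_confusion(calls2, drop_trivial = FALSE)
  expect_equal(conf2$tp + conf2$fp + conf2$tn + conf2$fn, 20)
  if (conf2$tp + conf2$fn > 0) {
    expect_equal(conf2$sensitivity, conf2$tp / (conf2$tp + conf2$fn))
  }
  # knockout monotonicity: deleting more never helps
  expect_lte(predict_growth(m, "v1", 0)$normalized,
             predict_growth(m, character(), 0)$normalized)
})

test_that("flux models export to MatrixMarket with bounds", {
  m <- toy_chain_model()
  d <- withr::local_tempdir()
  write_flux_model(m, d)
  header <- readLines(file.path(d, "S.mtx"), n = 2)
  expect_match(header[1], "MatrixMarket")
  dims <- as.integer(strsplit(header[2], " ")[[1]])
  expect_equal(dims[1:2], dim(m$S))
  b <- read_directions(file.path(d, "bounds.tsv"))
  expect_equal(b$reaction, m$rxns)
})
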