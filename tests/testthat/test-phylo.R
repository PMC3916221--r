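test_that("Fitch parsimony handles canonical cases", {
  tr <- rooted_tree("((a,b),(c,d));")
  all_on <- setNames(rep(1, 4), c("a", "b", "c", "d"))
  res <- fitch_parsimony(tr, all_on)
  expect_equal(res$changes, 0)
  expect_true(all(res$states == 1))
  # clade-split states: one change, deterministic root resolution
  res2 <- fitch_parsimony(tr, c(a = 1, b = 1, c = 0, d = 0))
  expect_equal(res2$changes, 1)
  expect_equal(enum_fitch(tr, c(a = 1, b = 1, c = 0, d = 0)), 1)
  expect_equal(unname(res2$states[tr$root]), 0) # ambiguity -> absent
  # star tree with one present leaf among five
  star <- rooted_tree("(a,b,c,d,e);")
  res3 <- fitch_parsimony(star, c(a = 1, b = 0, c = 0, d = 0, e = 0))
  expect_equal(res3$changes, 1)
  expect_equal(unname(res3$states[star$names[star$root]]), 0)
  expect_error(fitch_parsimony(tr, c(a = 1, b = 0, c = 0)), "missing")
})

test_that("Fitch change counts equal exhaustive minima on random trees", {
  set.seed(31)
  for (i in 1:40) {
    tr <- random_tree(sample(3:7, 1))
    states <- setNames(rbinom(sum(tr$is_leaf), 1, 0.5),
                       tr$names[tr$is_leaf])
    res <- fitch_parsimony(tr, states)
    expect_equal(res$changes, enum_fitch(tr, states))
    # the returned labeling attains the reported count
    edges <- which(tr$parent != 0L)
    attained <- sum(res$states[tr$names[edges]] !=
                      res$states[tr$names[tr$parent[edges]]])
    expect_equal(attained, res$changes)
  }
})

test_that("edge CPD estimation counts and smooths transitions", {
  tr <- rooted_tree("(a,b);")
  # 10 ECs: parent (root) state and child states chosen to give the edge
  # to 'a' exactly 2 gains among 8 parent-absent cases
  root <- c(rep(0, 10))
  a <- c(1, 1, rep(0, 8))
  b <- rep(0, 10)
  m <- rbind(a = a, b = b, anc1 = root)
  cp <- estimate_edge_cpds(tr, m, pseudocount = 0)
  expect_equal(cp$p_gain[cp$child == "a"], 0.2)
  # pseudocount arithmetic on all-identical states
  m1 <- rbind(a = rep(1, 5), b = rep(1, 5), anc1 = rep(1, 5))
  cp1 <- estimate_edge_cpds(tr, m1, pseudocount = 1)
  expect_equal(cp1$p_stay, rep((5 + 1) / (5 + 2), 2))
  expect_equal(cp1$p_gain, rep(1 / 2, 2)) # no parent-absent observations
  # transition-count conservation across edges
  set.seed(5)
  tr2 <- random_tree(6)
  full <- matrix(rbinom(tr2$n * 20, 1, 0.5), tr2$n, 20,
                 dimnames = list(tr2$names, paste0("e", 1:20)))
  cp2 <- estimate_edge_cpds(tr2, full, pseudocount = 0)
  edges <- which(tr2$parent != 0L)
  total01 <- sum(full[edges, ] == 1 & full[tr2$parent[edges], ] == 0)
  expect_equal(sum(cp2$n01), total01)
  expect_equal(sum(cp2$n0 + cp2$n1), length(edges) * 20)
  # global mode pools every edge to the same estimate
  cpg <- estimate_edge_cpds(tr2, full, mode = "global")
  expect_equal(length(unique(cpg$p_gain)), 1)
})

test_that("kernel density estimates are normalized and match a naive sum", {
  set.seed(41)
  x <- rgamma(40, 2, scale = 3)
  kde <- score_kde(x, n_reg = 20, reg_max = max(x))
  grid <- seq(-40, 80, length.out = 4000)
  integral <- sum(diff(grid) * (head(kde_density(kde, grid), -1) +
                                  tail(kde_density(kde, grid), -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-6)
  # naive-sum oracle at arbitrary query points
  q <- c(0, 1.7, 5.3, 12)
  naive <- sapply(q, function(z)
    mean(dnorm(z, mean = kde$points, sd = kde$bw)))
  expect_equal(kde_density(kde, q), naive, tolerance = 1e-12)
  # degenerate sample: bandwidth floor gives a symmetric density about 0
  k0 <- score_kde(rep(0, 5), n_reg = 0, reg_max = 0)
  expect_gt(k0$bw, 0)
  expect_equal(kde_density(k0, 0.5), kde_density(k0, -0.5))
  # strictly positive on the observed range
  expect_true(all(kde_density(kde, seq(0, max(x), length.out = 50)) > 0))
})

test_that("posterior inference is exact against joint enumeration", {
  expect_equal(unname(posterior_inference(single_node_tree("s"),
                                          data.frame(child = character(),
                                                     p_gain = numeric(),
                                                     p_stay = numeric()),
                                          root_prior = 0.5)), 0.5)
  # uninformative evidence: posterior equals the prior propagated through
  # the CPDs; with p_gain = p_stay = q every non-root node sits at q
  tr <- rooted_tree("((a,b),c);")
  q <- 0.3
  cpds <- data.frame(child = tr$names[tr$parent != 0],
                     p_gain = q, p_stay = q)
  post <- posterior_inference(tr, cpds, root_prior = 0.8)
  expect_equal(unname(post[tr$names[tr$root]]), 0.8)
  expect_equal(unname(post[c("a", "b", "c")]), rep(q, 3))
  set.seed(51)
  for (i in 1:40) {
    tr <- random_tree(sample(2:5, 1))
    cpds <- random_edge_cpds(tr)
    leaves <- tr$names[tr$is_leaf]
    ev <- matrix(runif(2 * length(leaves), 0.05, 3), ncol = 2,
                 dimnames = list(leaves, c("absent", "present")))
    rp <- runif(1, 0.2, 0.8)
    post <- posterior_inference(tr, cpds, ev, rp)
    expect_equal(max(abs(post[tr$names] -
                           enum_posterior(tr, cpds, ev, rp))), 0,
                 tolerance = 1e-9)
    expect_true(all(post >= 0 & post <= 1))
  }
})

test_that("stronger present-evidence never lowers a leaf posterior", {
  set.seed(61)
  for (i in 1:10) {
    tr <- random_tree(5)
    cpds <- random_edge_cpds(tr)
    leaves <- tr$names[tr$is_leaf]
    ev <- matrix(runif(2 * length(leaves), 0.1, 2), ncol = 2,
                 dimnames = list(leaves, c("absent", "present")))
    base <- posterior_inference(tr, cpds, ev)
    for (lam in c(1.5, 4, 20)) {
      ev2 <- ev
      ev2[1, "present"] <- ev[1, "present"] * lam
      boosted <- posterior_inference(tr, cpds, ev2)
      expect_gte(boosted[leaves[1]], base[leaves[1]] - 1e-12)
    }
  }
})

test_that("the fitted presence model has coherent shape and methods", {
  set.seed(71)
  tr <- random_tree(5)
  leaves <- tr$names[tr$is_leaf]
  ecs <- sprintf("1.1.1.%d", 1:6)
  presence <- matrix(rbinom(30, 1, 0.5), 5, 6,
                     dimnames = list(leaves, ecs))
  scores <- simulate_scores(presence, seed = 72)
  fit <- presence_model(tr, scores, presence)
  expect_s3_class(fit, "presence_model")
  expect_equal(dim(fit$posteriors), c(tr$n, 6))
  expect_true(all(fit$posteriors >= 0 & fit$posteriors <= 1))
  tab <- predict(fit, format = "table")
  expect_equal(nrow(tab), tr$n * 6)
  expect_named(tab, c("node", "ec", "posterior"))
  expect_equal(nrow(coef(fit)), tr$n - 1)
  sim1 <- simulate(fit, nsim = 3, seed = 9)
  sim2 <- simulate(fit, nsim = 3, seed = 9)
  expect_identical(sim1, sim2)
  expect_output(print(fit), "presence model")
  # posterior table round-trips
  d <- withr::local_tempdir()
  f <- file.path(d, "post.tsv")
  write_posteriors(tab, f)
  expect_equal(read_posteriors(f), tab, tolerance = 1e-12)
})

test_that("phylogeny-aware posteriors beat the naive classifier under masking", {
  # half the focal species' evidence rows removed: relatives must fill in
  set.seed(81)
  tr <- random_tree(8)
  leaves <- tr$names[tr$is_leaf]
  ecs <- sprintf("4.2.1.%d", 1:60)
  presence <- simulate_evolution(tr, ecs, gain = 0.05, loss = 0.1,
                                 root_prob = 0.6, seed = 82)
  scores <- simulate_scores(presence[leaves, ], seed = 83)
  focal <- leaves[1]
  keep <- !(scores$species == focal &
              seq_len(nrow(scores)) %in%
              sample(which(scores$species == focal),
                     floor(0.5 * sum(scores$species == focal))))
  fit <- presence_model(tr, scores[keep, ], presence[leaves, ], ecs = ecs)
  gold <- ecs[presence[focal, ] == 1]
  auc_phylo <- roc_auc(fit$posteriors[focal, ], gold, ecs)$auc
  naive <- naive_presence_posterior(scores[keep, ], fit$evidence_cpds,
                                    fit$prior_freq, focal, ecs)
  auc_naive <- roc_auc(naive[1, ], gold, ecs)$auc
  expect_gt(auc_phylo, auc_naive)
})
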