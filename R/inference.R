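#' Exact posterior inference of enzyme presence on a tree
#'
#' Belief propagation (the polytree algorithm specialized to trees) over
#' the per-enzyme Bayesian network whose topology follows the phylogeny:
#' binary presence nodes for every species, edge conditional probabilities
#' `p_gain = P(child present | parent absent)` and
#' `p_stay = P(child present | parent present)`, a Bernoulli root prior,
#' and per-leaf evidence entering as the likelihood of the observed score
#' pair given presence state. One upward (likelihood) pass and one
#' downward (marginalization) pass give the exact marginal posterior of
#' presence at every node.
#'
#' @param tree a [rooted_tree()].
#' @param edge_cpds data.frame as returned by [estimate_edge_cpds()]
#'   (columns `child`, `p_gain`, `p_stay`, names matching tree nodes).
#' @param evidence numeric matrix with rows named by node and columns
#'   `absent`, `present`: likelihood of that node's observations under
#'   each state. Nodes without a row (ancestors) carry no evidence.
#' @param root_prior prior probability of presence at the root
#'   (default 0.5, a uniform root distribution).
#' @return named vector of posterior presence probabilities, one per node.
#' @export
posterior_inference <- function(tree, edge_cpds, evidence = NULL,
                                root_prior = 0.5) {
  tree <- rooted_tree(tree)
  n <- tree$n
  ci <- match(tree$names, edge_cpds$child)
  if (any(is.na(ci[-tree$root]))) {
    stop("edge_cpds must cover every non-root node", call. = FALSE)
  }
  # trans[[v]]: 2x2 matrix P(child state | parent state), rows parent
  # states (absent, present), for the edge above v
  trans <- vector("list", n)
  for (v in seq_len(n)) {
    if (v == tree$root) next
    pg <- edge_cpds$p_gain[ci[v]]
    ps <- edge_cpds$p_stay[ci[v]]
    trans[[v]] <- rbind(c(1 - pg, pg), c(1 - ps, ps))
  }
  ev <- matrix(1, n, 2)
  if (!is.null(evidence)) {
    idx <- match(rownames(evidence), tree$names)
    if (anyNA(idx)) stop("evidence rows must name tree nodes", call. = FALSE)
    ev[idx, ] <- as.matrix(evidence[, c("absent", "present")])
  }
  # upward pass: lambda[v, s] propto P(evidence below v | state(v) = s)
  lambda <- matrix(1, n, 2)
  up_msg <- vector("list", n) # message from v to its parent, length-2
  for (v in tree$postorder) {
    l <- ev[v, ]
    for (c in tree$children[[v]]) l <- l * up_msg[[c]]
    if (sum(l) <= 0) stop("zero likelihood during upward pass", call. = FALSE)
    l <- l / sum(l) # rescale against underflow; marginals unaffected
    lambda[v, ] <- l
    if (v != tree$root) up_msg[[v]] <- as.vector(trans[[v]] %*% l)
  }
  # downward pass: pi[v, s] propto P(state(v) = s | evidence outside
  # subtree(v)); root uses the prior
  pi_msg <- matrix(0, n, 2)
  pi_msg[tree$root, ] <- c(1 - root_prior, root_prior)
  posterior <- numeric(n)
  for (v in rev(tree$postorder)) { # parents before children
    belief <- pi_msg[v, ] * lambda[v, ]
    posterior[v] <- belief[2] / sum(belief)
    for (c in tree$children[[v]]) {
      above <- pi_msg[v, ] * ev[v, ]
      for (sib in tree$children[[v]]) {
        if (sib != c) above <- above * up_msg[[sib]]
      }
      down <- as.vector(t(trans[[c]]) %*% above)
      pi_msg[c, ] <- down / sum(down)
    }
  }
  stats::setNames(posterior, tree$names)
}

#' Fit the comparative enzyme-presence model
#'
#' The phase-one model: for every enzyme (EC number), a Bayesian network
#' over the phylogeny integrates reciprocal-search and remote-homology
#' evidence across species and yields the posterior probability of the
#' enzyme in every present and ancestral species. Fitting proceeds in
#' three estimation steps shared across enzymes, then one exact inference
#' per enzyme:
#'
#' 1. ancestral reference states by Fitch parsimony on the reference
#'    presence calls ([fitch_presence_matrix()]);
#' 2. per-edge gain/stay probabilities by counting transitions
#'    ([estimate_edge_cpds()]);
#' 3. the four evidence densities by kernel density estimation, pooled
#'    over all species and enzymes ([fit_evidence_cpds()]);
#' 4. per-EC belief propagation ([posterior_inference()]); species with no
#'    score row enter with score (0, 0), i.e. "no hit" is evidence, not
#'    missing data.
#'
#' @param tree a [rooted_tree()] (or newick path/string); leaf names are
#'   species identifiers.
#' @param scores score table (`species`, `ec`, `blast_score`, `gtg_score`).
#' @param reference binary leaf x EC matrix of reference presence calls
#'   used for CPD estimation.
#' @param pseudocount,cpd_mode passed to [estimate_edge_cpds()].
#' @param root_prior Bernoulli prior at the root (default 0.5).
#' @param n_reg,bw_floor_frac passed to [fit_evidence_cpds()].
#' @param ecs ECs to infer; defaults to the union of score-table and
#'   reference ECs (ECs absent from any downstream reaction database are
#'   retained here and filtered later).
#' @return object of class `presence_model` with the fitted CPDs and the
#'   posterior matrix (`node x EC`); see [predict.presence_model()],
#'   [simulate.presence_model()].
#' @export
presence_model <- function(tree, scores, reference, pseudocount = 1,
                           cpd_mode = "per_edge", root_prior = 0.5,
                           n_reg = 100, bw_floor_frac = 1e-3, ecs = NULL) {
  tree <- rooted_tree(tree)
  leaves <- tree$names[tree$is_leaf]
  if (!all(rownames(reference) %in% leaves)) {
    stop("reference rows must be tree leaves", call. = FALSE)
  }
  ref <- matrix(0L, length(leaves), ncol(reference),
                dimnames = list(leaves, colnames(reference)))
  ref[rownames(reference), ] <- reference
  full_states <- fitch_presence_matrix(tree, ref)
  edge_cpds <- estimate_edge_cpds(tree, full_states, pseudocount, cpd_mode)
  ev_cpds <- fit_evidence_cpds(scores, ref, n_reg, bw_floor_frac)
  if (is.null(ecs)) ecs <- sort(unique(c(scores$ec, colnames(ref))))

  cells <- expand.grid(species = leaves, ec = ecs, stringsAsFactors = FALSE)
  sc <- score_lookup(scores, cells$species, cells$ec)
  lik <- evidence_likelihood(ev_cpds, sc[, "blast_score"], sc[, "gtg_score"])
  post <- matrix(NA_real_, tree$n, length(ecs),
                 dimnames = list(tree$names, ecs))
  for (j in seq_along(ecs)) {
    rows <- which(cells$ec == ecs[j])
    ev <- lik[rows, , drop = FALSE]
    rownames(ev) <- cells$species[rows]
    post[, j] <- posterior_inference(tree, edge_cpds, ev, root_prior)[tree$names]
  }
  structure(list(tree = tree, edge_cpds = edge_cpds, evidence_cpds = ev_cpds,
                 posteriors = post, root_prior = root_prior,
                 prior_freq = mean(ref), call = match.call()),
            class = "presence_model")
}

#' @export
print.presence_model <- function(x, ...) {
  cat("Comparative enzyme-presence model\n")
  cat(sprintf("  phylogeny: %d species, %d ancestral nodes\n",
              sum(x$tree$is_leaf), x$tree$n - sum(x$tree$is_leaf)))
  cat(sprintf("  enzymes: %d ECs; root prior %.3g\n",
              ncol(x$posteriors), x$root_prior))
  invisible(x)
}

#' @export
summary.presence_model <- function(object, threshold = 0.5, ...) {
  post <- object$posteriors
  leaves <- object$tree$names[object$tree$is_leaf]
  res <- list(
    n_ec = ncol(post),
    per_species = colSums(t(post[leaves, , drop = FALSE]) >= threshold),
    edge_cpds = object$edge_cpds[c("parent", "child", "p_gain", "p_stay")],
    threshold = threshold)
  class(res) <- "summary.presence_model"
  res
}

#' @export
print.summary.presence_model <- function(x, ...) {
  cat(sprintf("enzyme calls at posterior >= %.2g (per species):\n", x$threshold))
  print(x$per_species)
  cat("edge transition probabilities:\n")
  print(x$edge_cpds, row.names = FALSE)
  invisible(x)
}

#' @export
coef.presence_model <- function(object, ...) {
  object$edge_cpds[c("parent", "child", "p_gain", "p_stay")]
}

#' Posterior presence probabilities from a fitted model
#'
#' @param object a [presence_model()].
#' @param nodes node names (default all).
#' @param ecs EC numbers (default all).
#' @param format `"matrix"` or long `"table"` (node, ec, posterior).
#' @param ... unused.
#' @export
predict.presence_model <- function(object, nodes = NULL, ecs = NULL,
                                   format = c("matrix", "table"), ...) {
  format <- match.arg(format)
  post <- object$posteriors
  if (!is.null(nodes)) post <- post[nodes, , drop = FALSE]
  if (!is.null(ecs)) post <- post[, ecs, drop = FALSE]
  if (format == "matrix") return(post)
  data.frame(node = rep(rownames(post), times = ncol(post)),
             ec = rep(colnames(post), each = nrow(post)),
             posterior = as.vector(post), stringsAsFactors = FALSE)
}

#' Simulate presence states from the fitted transition model
#'
#' Draws enzyme presence along the tree from the fitted root prior and
#' edge CPDs (ignoring evidence), one column per simulated enzyme.
#'
#' @param object a [presence_model()].
#' @param nsim number of enzymes to simulate.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @export
simulate.presence_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tree <- object$tree
  pg <- stats::setNames(object$edge_cpds$p_gain, object$edge_cpds$child)
  ps <- stats::setNames(object$edge_cpds$p_stay, object$edge_cpds$child)
  out <- matrix(0L, tree$n, nsim,
                dimnames = list(tree$names, paste0("sim", seq_len(nsim))))
  for (v in rev(tree$postorder)) {
    if (v == tree$root) {
      out[v, ] <- stats::rbinom(nsim, 1, object$root_prior)
    } else {
      p <- ifelse(out[tree$parent[v], ] == 1, ps[[tree$names[v]]],
                  pg[[tree$names[v]]])
      out[v, ] <- stats::rbinom(nsim, 1, p)
    }
  }
  out
}

#' Plot the fitted evidence densities
#'
#' Draws the four class-conditional score densities (BLAST and GTG
#' channels, present vs absent) of a fitted model.
#'
#' @param x a [presence_model()].
#' @param n_grid evaluation grid size.
#' @param ... passed to [graphics::plot()].
#' @export
plot.presence_model <- function(x, n_grid = 200, ...) {
  cp <- x$evidence_cpds
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (ch in c("blast", "gtg")) {
    kp <- cp[[paste0(ch, "_present")]]
    ka <- cp[[paste0(ch, "_absent")]]
    hi <- max(kp$points, ka$points)
    g <- seq(0, hi * 1.05, length.out = n_grid)
    dp <- kde_density(kp, g)
    da <- kde_density(ka, g)
    graphics::plot(g, dp, type = "l", col = "blue", xlab = paste(ch, "score"),
                   ylab = "density", ylim = range(0, dp, da), ...)
    graphics::lines(g, da, col = "red", lty = 2)
    graphics::legend("topright", c("present", "absent"), col = c("blue", "red"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Naive (no-phylogeny) presence classifier
#'
#' Baseline that scores each (species, EC) cell in isolation: the class
#' prior is the reference presence frequency and the likelihood is the
#' product of the two evidence densities; no information is shared across
#' species.
#'
#' @param scores score table.
#' @param evidence_cpds an [fit_evidence_cpds()] object.
#' @param prior prior presence probability (e.g. reference frequency).
#' @param species,ecs cells to score.
#' @return matrix species x EC of posterior presence probabilities.
#' @export
naive_presence_posterior <- function(scores, evidence_cpds, prior,
                                     species, ecs) {
  cells <- expand.grid(species = species, ec = ecs, stringsAsFactors = FALSE)
  sc <- score_lookup(scores, cells$species, cells$ec)
  lik <- evidence_likelihood(evidence_cpds, sc[, "blast_score"],
                             sc[, "gtg_score"])
  post <- prior * lik[, "present"] /
    (prior * lik[, "present"] + (1 - prior) * lik[, "absent"])
  matrix(post, length(species), length(ecs),
         dimnames = list(species, ecs))
}
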