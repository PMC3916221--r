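# Synthetic universes and simulated evidence with the statistical
# structure the two reconstruction phases assume: a layered biosynthesis
# universe whose planted network is gapless by construction, presence
# evolution along a tree, and class-conditional evidence scores.

#' Generate a synthetic reaction universe
#'
#' Builds a layered biosynthesis universe over carbon-skeleton molecules:
#' nutrients form layer zero, and every later molecule is first created by
#' a designated producer reaction whose substrates are already producible,
#' so the planted network (the producer reactions plus all extras) is
#' gapless from the nutrients by construction. Reactions conserve carbon
#' by design and are then mass-balanced over H and O by the integer
#' program ([balance_db()], which may add water and protons), and
#' carbon-mapped with [greedy_map()]. Each non-spontaneous reaction is
#' annotated with an EC number drawn from a pool of `n_ec` codes (some
#' codes annotate several reactions, as in real EC usage).
#'
#' @param n_molecules target molecule count (default 80).
#' @param n_reactions target reaction count (default 120; about 1.5
#'   reactions per molecule, the density of real reaction repositories).
#' @param n_ec EC pool size (default 150).
#' @param n_nutrients nutrient molecules, carbon counts cycling 1..4.
#' @param spont_frac fraction of spontaneous (EC-less) reactions.
#' @param seed RNG seed; the same seed reproduces the universe exactly.
#' @return object of class `synthetic_universe`: `db` (a
#'   [reaction_db()]), `producer_of` (molecule -> producing reaction),
#'   `planted` (reaction ids), `ec_universe`.
#' @export
generate_universe <- function(n_molecules = 80, n_reactions = 120,
                              n_ec = 150, n_nutrients = 6,
                              spont_frac = 0.05, seed = 1) {
  set.seed(seed)
  mol_carbons <- integer(0)
  mols <- list()
  new_mol <- function(c_count) {
    id <- sprintf("M%03d", length(mols) + 1L)
    h <- 2L * c_count + sample(0:2, 1)
    o <- sample.int(max(c_count, 1), 1)
    mols[[id]] <<- molecule(id, stats::setNames(c(c_count, h, o),
                                                c("C", "H", "O")))
    mol_carbons[id] <<- c_count
    id
  }
  nutrients <- vapply(seq_len(n_nutrients), function(i) {
    new_mol(((i - 1L) %% 4L) + 1L)
  }, "")
  producer_of <- character(0)
  reactions <- list()
  add_reaction <- function(subs, prods) {
    id <- sprintf("R%03d", length(reactions) + 1L)
    reactions[[id]] <<- reaction(
      id, stats::setNames(rep(1L, length(subs)), subs),
      stats::setNames(rep(1L, length(prods)), prods),
      direction = sample(c("forward", "reversible"), 1, prob = c(0.6, 0.4)))
    id
  }
  # spanning producers: every new molecule made from producible material
  producible <- nutrients
  attempts <- 0L
  while (length(mols) < n_molecules && length(reactions) < n_reactions &&
         attempts < 100L * n_molecules) {
    attempts <- attempts + 1L
    c_new <- sample.int(6, 1)
    # substrates with carbon total c_new from producible molecules
    cands <- producible[mol_carbons[producible] <= c_new]
    s1 <- cands[sample.int(length(cands), 1)]
    rest <- c_new - mol_carbons[[s1]]
    subs <- s1
    if (rest > 0) {
      extra <- producible[mol_carbons[producible] == rest & producible != s1]
      if (length(extra) == 0) next
      subs <- c(s1, extra[sample.int(length(extra), 1)])
    }
    m <- new_mol(c_new)
    rid <- add_reaction(subs, m)
    producer_of[m] <- rid
    producible <- c(producible, m)
  }
  # extra reactions among existing molecules, carbon-conserving
  tries <- 0L
  while (length(reactions) < n_reactions && tries < 50L * n_reactions) {
    tries <- tries + 1L
    ns <- sample(1:2, 1)
    subs <- sample(producible, ns)
    ctot <- sum(mol_carbons[subs])
    np <- sample(1:2, 1)
    prods <- character(0)
    pool <- setdiff(producible, subs)
    if (np == 1) {
      opts <- pool[mol_carbons[pool] == ctot]
      if (length(opts) == 0) next
      prods <- opts[sample.int(length(opts), 1)]
    } else {
      c1 <- sample.int(max(ctot - 1L, 1L), 1)
      o1 <- pool[mol_carbons[pool] == c1]
      o2 <- pool[mol_carbons[pool] == ctot - c1]
      if (length(o1) == 0 || length(o2) == 0) next
      p1 <- o1[sample.int(length(o1), 1)]
      o2 <- setdiff(o2, p1)
      if (length(o2) == 0) next
      prods <- c(p1, o2[sample.int(length(o2), 1)])
    }
    add_reaction(subs, prods)
  }
  ec_pool <- unique(sprintf("%d.%d.%d.%d",
                            sample.int(6, 4 * n_ec, replace = TRUE),
                            sample.int(20, 4 * n_ec, replace = TRUE),
                            sample.int(20, 4 * n_ec, replace = TRUE),
                            sample.int(99, 4 * n_ec, replace = TRUE)))[
                              seq_len(n_ec)]
  for (id in names(reactions)) {
    if (stats::runif(1) >= spont_frac) {
      reactions[[id]]$ec <- sample(ec_pool, 1)
    }
  }
  db <- reaction_db(mols, reactions, nutrients = nutrients)
  db <- balance_db(db)
  ok <- names(db$reactions)[vapply(db$reactions, function(r)
    isTRUE(r$flags$balanced), logical(1))]
  db$mappings <- stats::setNames(lapply(ok, function(id) {
    greedy_map(db$reactions[[id]], db$molecules, elements = "C")
  }), ok)
  structure(list(db = db, producer_of = producer_of,
                 planted = sort(names(db$reactions)),
                 ec_universe = sort(unique(unlist(lapply(db$reactions,
                                                         `[[`, "ec"))))),
            class = "synthetic_universe")
}

#' @export
print.synthetic_universe <- function(x, ...) {
  cat("synthetic universe\n  ")
  print(x$db)
  invisible(x)
}

#' Close a reaction set to gaplessness
#'
#' Adds the designated producer reaction of every substrate molecule that
#' the set cannot yet produce, iterating to a fixpoint. Because producers
#' form the planted spanning network, the result is gapless from the
#' nutrients.
#'
#' @param universe a [generate_universe()] result.
#' @param reactions reaction ids to close.
#' @return superset of `reactions` that is gapless.
#' @export
gapless_closure <- function(universe, reactions) {
  db <- universe$db
  set <- intersect(reactions, names(db$reactions))
  repeat {
    producible <- c(db$nutrients,
                    unlist(lapply(db$reactions[set], function(r)
                      names(r$products))))
    need <- setdiff(unlist(lapply(db$reactions[set], function(r)
      names(r$substrates))), producible)
    add <- stats::na.omit(unique(universe$producer_of[need]))
    add <- setdiff(add, set)
    if (length(add) == 0) break
    set <- c(set, add)
  }
  sort(set)
}

#' Simulate enzyme presence evolution along a tree
#'
#' Draws the root state from `root_prob` and flips states along each edge
#' with per-edge gain rate (absent parent -> present child) and loss rate
#' (present -> absent), independently for each enzyme.
#'
#' @param tree a [rooted_tree()].
#' @param ecs EC identifiers (one simulated character each).
#' @param gain,loss transition probabilities per edge, in \[0, 1\].
#' @param root_prob root presence probability.
#' @param seed RNG seed.
#' @return binary matrix node x EC over all tree nodes.
#' @export
simulate_evolution <- function(tree, ecs, gain = 0.05, loss = 0.1,
                               root_prob = 0.7, seed = 1) {
  stopifnot(gain >= 0, gain <= 1, loss >= 0, loss <= 1)
  tree <- rooted_tree(tree)
  set.seed(seed)
  m <- matrix(0L, tree$n, length(ecs), dimnames = list(tree$names, ecs))
  for (v in rev(tree$postorder)) {
    if (v == tree$root) {
      m[v, ] <- stats::rbinom(length(ecs), 1, root_prob)
    } else {
      p <- ifelse(m[tree$parent[v], ] == 1, 1 - loss, gain)
      m[v, ] <- stats::rbinom(length(ecs), 1, p)
    }
  }
  m
}

#' Class-conditional score distributions
#'
#' Default samplers for the evidence channel: right-skewed gamma BLAST
#' scores and near-one beta GTG scores for present enzymes, mostly zero
#' ("no hit") for absent enzymes but with a sizeable spurious-hit rate
#' whose scores overlap the present class — single evidence channels are
#' deliberately imperfect classifiers, as real homology evidence is, so
#' that combining channels and borrowing strength across the phylogeny
#' both have room to help. The spurious-hit rate is high because a
#' permissive search (the usual E-value cutoff of 10) hands almost every
#' query some weak best hit. About half of the present BLAST scores exceed
#' 600 and a fair share of present GTG scores exceed 0.99, so the
#' distant-species capping perturbation has signal to destroy.
#'
#' @param blast_shape,blast_scale gamma parameters of present BLAST scores.
#' @param miss_present probability that a present enzyme has no hit.
#' @param hit_absent probability that an absent enzyme has a spurious hit.
#' @return list of samplers used by [simulate_scores()].
#' @export
score_profile <- function(blast_shape = 2.5, blast_scale = 280,
                          miss_present = 0.05, hit_absent = 0.8) {
  list(
    blast_present = function(n) stats::rgamma(n, blast_shape,
                                              scale = blast_scale),
    blast_absent = function(n) stats::rgamma(n, 1.2, scale = 180),
    gtg_present = function(n) stats::rbeta(n, 8, 0.7),
    gtg_absent = function(n) stats::rbeta(n, 1.2, 3),
    miss_present = miss_present, hit_absent = hit_absent)
}

#' Simulate evidence scores from leaf presence states
#'
#' Draws per (species, EC) BLAST and GTG scores from the class-conditional
#' distributions of `profile`; enzymes without a hit (all of the absent
#' ones with probability `1 - hit_absent`, present ones with probability
#' `miss_present`) receive no row, i.e. score (0, 0).
#'
#' @param leaf_presence binary matrix species x EC.
#' @param profile a [score_profile()].
#' @param seed RNG seed.
#' @return score table data.frame.
#' @export
simulate_scores <- function(leaf_presence, profile = score_profile(),
                            seed = 1) {
  set.seed(seed)
  cells <- expand.grid(species = rownames(leaf_presence),
                       ec = colnames(leaf_presence),
                       stringsAsFactors = FALSE)
  pres <- leaf_presence[cbind(cells$species, cells$ec)] == 1
  n <- nrow(cells)
  hit <- ifelse(pres, stats::runif(n) > profile$miss_present,
                stats::runif(n) < profile$hit_absent)
  blast <- numeric(n)
  gtg <- numeric(n)
  ip <- which(pres & hit)
  ia <- which(!pres & hit)
  blast[ip] <- profile$blast_present(length(ip))
  gtg[ip] <- profile$gtg_present(length(ip))
  blast[ia] <- profile$blast_absent(length(ia))
  gtg[ia] <- profile$gtg_absent(length(ia))
  out <- data.frame(species = cells$species, ec = cells$ec,
                    blast_score = blast, gtg_score = gtg,
                    stringsAsFactors = FALSE)[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic comparative-reconstruction study
#'
#' Draws every input the pipeline consumes: a universe, a random rooted
#' bifurcating tree, presence evolution, per-species gapless truth
#' networks (the gapless closure of the reactions whose EC evolved as
#' present, plus the spontaneous reactions), gold EC sets, a noisy
#' reference presence matrix (standing in for an independent
#' protein-signature detector: detection probability `ref_detect`, false
#' call probability `ref_false`), and evidence scores.
#'
#' @param n_species leaf count of the random tree.
#' @param n_molecules,n_reactions,n_ec,spont_frac passed to
#'   [generate_universe()].
#' @param gain,loss,root_prob passed to [simulate_evolution()].
#' @param profile a [score_profile()].
#' @param ref_detect,ref_false reference-call error rates.
#' @param seed RNG seed; every draw derives from it.
#' @return list of class `synthetic_study`.
#' @export
synthetic_study <- function(n_species = 12, n_molecules = 80,
                            n_reactions = 120, n_ec = 150,
                            spont_frac = 0.05, gain = 0.05, loss = 0.1,
                            root_prob = 0.5, profile = score_profile(),
                            ref_detect = 0.95, ref_false = 0.01, seed = 1) {
  universe <- generate_universe(n_molecules, n_reactions, n_ec,
                                spont_frac = spont_frac, seed = seed)
  set.seed(seed + 1L)
  phy <- ape::rtree(n_species, tip.label = sprintf("sp%02d",
                                                   seq_len(n_species)))
  tree <- rooted_tree(phy)
  ecs <- universe$ec_universe
  presence <- simulate_evolution(tree, ecs, gain, loss, root_prob,
                                 seed = seed + 2L)
  leaves <- tree$names[tree$is_leaf]
  leaf_presence <- presence[leaves, , drop = FALSE]
  db <- universe$db
  rxn_ecs <- lapply(db$reactions, `[[`, "ec")
  spont <- names(db$reactions)[lengths(rxn_ecs) == 0]
  truth_reactions <- lapply(leaves, function(sp) {
    present_ec <- ecs[leaf_presence[sp, ] == 1]
    seeds <- names(db$reactions)[vapply(rxn_ecs, function(e)
      any(e %in% present_ec), logical(1))]
    gapless_closure(universe, c(seeds, spont))
  })
  names(truth_reactions) <- leaves
  gold_ecs <- lapply(truth_reactions, function(rs)
    sort(unique(unlist(rxn_ecs[rs]))))
  set.seed(seed + 3L)
  ref <- leaf_presence
  ref[] <- stats::rbinom(length(ref), 1,
                         ifelse(ref == 1, ref_detect, ref_false))
  scores <- simulate_scores(leaf_presence, profile, seed = seed + 4L)
  structure(list(universe = universe, tree = tree, presence = presence,
                 leaf_presence = leaf_presence,
                 truth_reactions = truth_reactions, gold_ecs = gold_ecs,
                 reference = ref, scores = scores, profile = profile,
                 ec_universe = ecs, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d species, %d ECs, %d reactions (seed %d)\n",
              sum(x$tree$is_leaf), length(x$ec_universe),
              length(x$universe$db$reactions), x$seed))
  invisible(x)
}
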