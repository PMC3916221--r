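#' Estimate per-edge gain/stay probabilities
#'
#' For each edge of the tree, counts enzyme state transitions across all EC
#' columns of a full (leaves + ancestors) presence matrix and normalizes
#' with a pseudocount:
#' `p_gain = (#(0 -> 1) + pc) / (#(parent 0) + 2 pc)` and
#' `p_stay = (#(1 -> 1) + pc) / (#(parent 1) + 2 pc)`.
#' An edge with no observation of a given parent state falls back to the
#' globally pooled estimate for that probability (with a message);
#' `mode = "global"` pools all edges unconditionally.
#'
#' @param tree a [rooted_tree()].
#' @param full_states binary matrix node x EC covering every tree node
#'   (e.g. from [fitch_presence_matrix()]).
#' @param pseudocount non-negative smoothing count (default 1).
#' @param mode `"per_edge"` (default) or `"global"`.
#' @return data.frame with one row per edge: `parent`, `child` (node
#'   names), `p_gain`, `p_stay`, plus transition counts `n01`, `n0`,
#'   `n11`, `n1`.
#' @export
estimate_edge_cpds <- function(tree, full_states, pseudocount = 1,
                               mode = c("per_edge", "global")) {
  tree <- rooted_tree(tree)
  mode <- match.arg(mode)
  if (!all(tree$names %in% rownames(full_states))) {
    stop("full_states must cover every tree node", call. = FALSE)
  }
  edges <- tree_edges(tree)
  m <- full_states[tree$names, , drop = FALSE]
  ps <- m[edges$parent, , drop = FALSE]
  cs <- m[edges$child, , drop = FALSE]
  n0 <- rowSums(ps == 0)
  n1 <- rowSums(ps == 1)
  n01 <- rowSums(ps == 0 & cs == 1)
  n11 <- rowSums(ps == 1 & cs == 1)
  g0 <- sum(n0); g1 <- sum(n1); g01 <- sum(n01); g11 <- sum(n11)
  pc <- pseudocount
  global_gain <- (g01 + pc) / (g0 + 2 * pc)
  global_stay <- (g11 + pc) / (g1 + 2 * pc)
  if (mode == "global") {
    p_gain <- rep(global_gain, nrow(edges))
    p_stay <- rep(global_stay, nrow(edges))
  } else {
    p_gain <- (n01 + pc) / (n0 + 2 * pc)
    p_stay <- (n11 + pc) / (n1 + 2 * pc)
    starved0 <- n0 == 0
    starved1 <- n1 == 0
    if (any(starved0) || any(starved1)) {
      message(sprintf(
        "edge CPDs: %d edge(s) without parent-state observations use global counts",
        sum(starved0 | starved1)))
      p_gain[starved0] <- global_gain
      p_stay[starved1] <- global_stay
    }
  }
  data.frame(parent = tree$names[edges$parent], child = tree$names[edges$child],
             p_gain = p_gain, p_stay = p_stay,
             n01 = n01, n0 = n0, n11 = n11, n1 = n1,
             stringsAsFactors = FALSE)
}

#' Gaussian kernel density with regularization points
#'
#' Kernel density estimator used for the evidence distributions
#' (score given presence / absence). The bandwidth follows Silverman's
#' rule-of-thumb (`nrd0`): `0.9 min(sd, IQR/1.34) n^(-1/5)`. To keep the
#' density strictly positive over the observed score range and avoid
#' overfitting near zero density, `n_reg` extra points uniformly spaced on
#' `[0, reg_max]` are appended before fitting. Degenerate samples (zero
#' spread) receive a floor bandwidth of `bw_floor_frac * max(reg_max, 1)`.
#'
#' @param x numeric sample of scores.
#' @param n_reg number of regularization points (default 100).
#' @param reg_max upper end of the regularization range; defaults to
#'   `max(x)` and is shared across the four evidence densities when fit
#'   through [fit_evidence_cpds()].
#' @param bw_floor_frac floor bandwidth as a fraction of the score range.
#' @return object of class `score_kde` with `points`, `bw`.
#' @export
score_kde <- function(x, n_reg = 100, reg_max = max(x, 0),
                      bw_floor_frac = 1e-3) {
  if (n_reg > 0) {
    reg <- seq(0, max(reg_max, 0), length.out = n_reg)
    x <- c(x, reg)
  }
  if (length(x) < 1) {
    stop("cannot fit a density to an empty sample", call. = FALSE)
  }
  bw <- tryCatch(stats::bw.nrd0(x), error = function(e) 0)
  floor_bw <- bw_floor_frac * max(reg_max, 1)
  structure(list(points = x, bw = max(bw, floor_bw)),
            class = "score_kde")
}

#' Evaluate a kernel density estimate
#'
#' Exact evaluation as the mean of Gaussian kernels centred at the sample
#' points; no grid interpolation is involved.
#'
#' @param kde a [score_kde()].
#' @param q numeric query points.
#' @return density values at `q`.
#' @export
kde_density <- function(kde, q) {
  stopifnot(inherits(kde, "score_kde"))
  pts <- kde$points
  h <- kde$bw
  # chunked to bound memory on large query sets
  out <- numeric(length(q))
  chunk <- 2048L
  for (i in seq(1, length(q), by = chunk)) {
    j <- i:min(i + chunk - 1L, length(q))
    out[j] <- colMeans(stats::dnorm(outer(pts, q[j], "-") / h)) / h
  }
  out
}

#' @export
print.score_kde <- function(x, ...) {
  cat(sprintf("Gaussian KDE: %d points, bandwidth %.4g\n",
              length(x$points), x$bw))
  invisible(x)
}

#' Fit the four evidence densities
#'
#' Pools scores over all (leaf, EC) cells of the reference presence matrix
#' and fits the four class-conditional densities shared by every species
#' and enzyme: blast|present, blast|absent, gtg|present, gtg|absent.
#' Cells with no score row contribute score 0 (no hit). Each channel's
#' regularization range is `[0, max observed score]` for that channel.
#'
#' @param score_table score data.frame (`species`, `ec`, `blast_score`,
#'   `gtg_score`).
#' @param reference binary matrix leaf x EC of reference presence calls.
#' @param n_reg,bw_floor_frac see [score_kde()].
#' @return object of class `evidence_cpds`: list of four `score_kde`s
#'   (`blast_present`, `blast_absent`, `gtg_present`, `gtg_absent`).
#' @export
fit_evidence_cpds <- function(score_table, reference, n_reg = 100,
                              bw_floor_frac = 1e-3) {
  sp <- rownames(reference)
  ec <- colnames(reference)
  cells <- expand.grid(species = sp, ec = ec, stringsAsFactors = FALSE)
  sc <- score_lookup(score_table, cells$species, cells$ec)
  present <- reference[cbind(cells$species, cells$ec)] == 1
  bmax <- max(sc[, "blast_score"], 0)
  gmax <- max(sc[, "gtg_score"], 0)
  out <- list(
    blast_present = score_kde(sc[present, "blast_score"], n_reg, bmax,
                              bw_floor_frac),
    blast_absent = score_kde(sc[!present, "blast_score"], n_reg, bmax,
                             bw_floor_frac),
    gtg_present = score_kde(sc[present, "gtg_score"], n_reg, gmax,
                            bw_floor_frac),
    gtg_absent = score_kde(sc[!present, "gtg_score"], n_reg, gmax,
                           bw_floor_frac))
  class(out) <- "evidence_cpds"
  out
}

#' Evidence likelihoods for a set of (blast, gtg) observations
#'
#' @param cpds an [fit_evidence_cpds()] object.
#' @param blast,gtg numeric score vectors.
#' @return matrix with columns `absent`, `present`: the joint density of
#'   the observed score pair under each presence state.
#' @export
evidence_likelihood <- function(cpds, blast, gtg) {
  cbind(absent = kde_density(cpds$blast_absent, blast) *
          kde_density(cpds$gtg_absent, gtg),
        present = kde_density(cpds$blast_present, blast) *
          kde_density(cpds$gtg_present, gtg))
}
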