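# Evaluation machinery: EC-set confusion counts against a gold standard,
# ROC curves from threshold sweeps, and the two input-perturbation
# scenarios (poor sequencing, evolutionary distant species).

#' Compare a predicted EC set against a gold standard
#'
#' Standard confusion counts over a declared EC universe (true negatives
#' need a universe; whether that is all known ECs or the union of model
#' ECs is the caller's modelling choice). Only complete four-field EC
#' numbers are admitted. An empty prediction reports precision 0 with the
#' `precision_undefined` flag set.
#'
#' @param predicted,gold,universe character vectors of complete EC
#'   numbers; `predicted` and `gold` must be subsets of `universe`.
#' @return list of class `ec_comparison` with counts `tp`, `fp`, `tn`,
#'   `fn` and derived `tpr`, `fpr`, `precision`, `f1`,
#'   `precision_undefined`.
#' @export
compare_ec_sets <- function(predicted, gold, universe) {
  check_complete_ec(universe)
  if (length(predicted)) check_complete_ec(predicted)
  if (length(gold)) check_complete_ec(gold)
  if (!all(predicted %in% universe) || !all(gold %in% universe)) {
    stop("predicted and gold sets must be subsets of the universe",
         call. = FALSE)
  }
  predicted <- unique(predicted); gold <- unique(gold)
  universe <- unique(universe)
  tp <- length(intersect(predicted, gold))
  fp <- length(setdiff(predicted, gold))
  fn <- length(setdiff(gold, predicted))
  tn <- length(universe) - tp - fp - fn
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
  undef <- tp + fp == 0
  prec <- if (undef) 0 else tp / (tp + fp)
  f1 <- if (prec + tpr > 0) 2 * prec * tpr / (prec + tpr) else 0
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, tpr = tpr, fpr = fpr,
                 precision = prec, f1 = f1, precision_undefined = undef),
            class = "ec_comparison")
}

#' @export
print.ec_comparison <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d | TPR %.3f FPR %.3f prec %.3f F1 %.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$tpr, x$fpr, x$precision, x$f1))
  invisible(x)
}

#' ROC curve and AUC from per-EC scores
#'
#' Sweeps every distinct score as a threshold (ties grouped), computes
#' (FPR, TPR) against the gold set over the universe, and integrates by
#' the trapezoid rule. ECs of the universe without a score entry score 0.
#' Constant scores give the degenerate two-point curve with AUC 0.5.
#'
#' @param scores named numeric vector, EC -> score (higher = more likely
#'   present).
#' @param gold,universe EC sets.
#' @return list of class `roc_curve` with `points` (data.frame
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, gold, universe) {
  s <- stats::setNames(rep(0, length(universe)), universe)
  known <- intersect(names(scores), universe)
  s[known] <- scores[known]
  if (any(!is.finite(s))) stop("scores must be finite", call. = FALSE)
  label <- names(s) %in% gold
  thr <- sort(unique(s), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    pred <- s >= t
    c(fpr = sum(pred & !label) / max(sum(!label), 1),
      tpr = sum(pred & label) / max(sum(label), 1))
  }, c(fpr = 0, tpr = 0)))
  pts <- data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  structure(list(points = pts, auc = trapezoid_auc(pts$fpr, pts$tpr)),
            class = "roc_curve")
}

# trapezoid over (fpr, tpr) points with (0,0) and (1,1) anchors
trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  x <- c(0, fpr[o], 1)
  y <- c(0, tpr[o], 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' ROC curve from a family of predicted sets
#'
#' Builds an ROC curve for a predictor that yields whole EC sets at a
#' sweep of thresholds (the phase-two reconstructions under varying
#' acceptance threshold), rather than per-EC scores.
#'
#' @param sets list of predicted EC sets, one per threshold.
#' @param gold,universe EC sets.
#' @return a `roc_curve`.
#' @export
roc_from_sets <- function(sets, gold, universe) {
  pts <- do.call(rbind, lapply(sets, function(p) {
    cmp <- compare_ec_sets(intersect(p, universe), gold, universe)
    data.frame(threshold = NA_real_, fpr = cmp$fpr, tpr = cmp$tpr)
  }))
  structure(list(points = pts, auc = trapezoid_auc(pts$fpr, pts$tpr)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  o <- order(x$points$fpr, x$points$tpr)
  graphics::plot(c(0, x$points$fpr[o], 1), c(0, x$points$tpr[o], 1),
                 type = "l", xlab = "FPR", ylab = "TPR", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Emulate poor sequencing by removing query sequences
#'
#' Removes a uniform random fraction of the query sequences belonging to
#' the named species, together with every hit (row) they own:
#' `floor(fraction * n)` sequences per species, seeded and reproducible.
#'
#' @param hits data.frame with a `query` column (any hit or score table
#'   keyed by query sequence).
#' @param species_of named character vector query -> species.
#' @param species species whose sequences are dropped.
#' @param fraction fraction of sequences removed per species, in \[0, 1\].
#' @param seed RNG seed.
#' @return `hits` with the removed queries' rows dropped.
#' @export
simulate_poor_sequencing <- function(hits, species_of, species, fraction,
                                     seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  missing <- setdiff(species, unique(species_of))
  if (length(missing) > 0) {
    stop(sprintf("species not found: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  set.seed(seed)
  drop <- character(0)
  for (sp in species) {
    qs <- sort(unique(names(species_of)[species_of == sp]))
    n_drop <- floor(fraction * length(qs))
    if (n_drop > 0) drop <- c(drop, sample(qs, n_drop))
  }
  hits[!(hits$query %in% drop), , drop = FALSE]
}

#' Emulate an evolutionary distant species by capping high scores
#'
#' Replaces every BLAST score above `blast_cap` and every GTG score above
#' `gtg_cap` in the named species with a value drawn uniformly from the
#' donor values below the respective cap (the donor plays the role of a
#' poorly characterized organism). Other cells are untouched; seeded.
#'
#' @param score_table score data.frame.
#' @param species species whose scores are capped.
#' @param donor_scores data.frame with `blast_score` and `gtg_score`
#'   columns providing the replacement pools.
#' @param blast_cap,gtg_cap replacement thresholds (600 and 0.99).
#' @param seed RNG seed.
#' @return the perturbed score table.
#' @export
simulate_distant_species <- function(score_table, species, donor_scores,
                                     blast_cap = 600, gtg_cap = 0.99,
                                     seed = 1) {
  set.seed(seed)
  pool_b <- donor_scores$blast_score[donor_scores$blast_score < blast_cap]
  pool_g <- donor_scores$gtg_score[donor_scores$gtg_score < gtg_cap]
  tgt <- score_table$species %in% species
  hi_b <- which(tgt & score_table$blast_score > blast_cap)
  hi_g <- which(tgt & score_table$gtg_score > gtg_cap)
  if ((length(hi_b) > 0 && length(pool_b) == 0) ||
      (length(hi_g) > 0 && length(pool_g) == 0)) {
    stop("empty donor pool below cap", call. = FALSE)
  }
  if (length(hi_b) > 0) {
    score_table$blast_score[hi_b] <- sample(pool_b, length(hi_b),
                                            replace = TRUE)
  }
  if (length(hi_g) > 0) {
    score_table$gtg_score[hi_g] <- sample(pool_g, length(hi_g),
                                          replace = TRUE)
  }
  score_table
}
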