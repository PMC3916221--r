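#' Reciprocal homology score
#'
#' Combines the forward and reverse search p-values of a reciprocal sequence
#' search into a single score that is high only when both directions are
#' significant, the property that makes reciprocal searches useful for
#' flagging orthologous candidates. The default scoring function is
#' \eqn{-\log_{10} p_f - \log_{10} p_r}, with p-values floored at `eps` so
#' the score stays finite.
#'
#' The scoring function is pluggable: any function of the two p-value
#' vectors can be supplied, provided it is symmetric in its arguments and
#' non-increasing in each.
#'
#' @param p_forward,p_reverse numeric vectors of p-values in \[0, 1\].
#' @param eps floor applied to both p-values before taking logs.
#' @param score_fun optional replacement scoring function taking the two
#'   (floored) p-value vectors.
#' @return numeric vector of non-negative scores.
#' @examples
#' reciprocal_score(1e-5, 1e-3)
#' reciprocal_score(1, 1) # no evidence, zero score
#' @export
reciprocal_score <- function(p_forward, p_reverse, eps = 1e-300,
                             score_fun = NULL) {
  check_pvalue(p_forward, "p_forward")
  check_pvalue(p_reverse, "p_reverse")
  pf <- pmax(p_forward, eps)
  pr <- pmax(p_reverse, eps)
  if (!is.null(score_fun)) {
    return(score_fun(pf, pr))
  }
  -log10(pf) - log10(pr)
}

check_pvalue <- function(p, what) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop(sprintf("'%s' must be numeric in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}

#' Convert E-values to p-values
#'
#' Search tools commonly report E-values; under the Karlin-Altschul model
#' the corresponding p-value is `1 - exp(-E)`, capped at 1. Offered as an
#' input transform for hit tables that carry E-values.
#'
#' @param e numeric vector of non-negative E-values.
#' @return p-values in \[0, 1\].
#' @export
evalue_to_pvalue <- function(e) {
  if (!is.numeric(e) || anyNA(e) || any(e < 0)) {
    stop("E-values must be non-negative numbers", call. = FALSE)
  }
  pmin(1, -expm1(-e))
}

#' Per-(species, enzyme) evidence scores
#'
#' Aggregates raw homology hits into one row per (species, EC number):
#' the BLAST-style score is the maximum reciprocal score over hits whose
#' query belongs to the species and whose target carries the EC annotation;
#' the GTG-style score is the analogous maximum of the shared-feature
#' fraction. Combinations without any annotated hit score (0, 0) and are
#' omitted from the table (absence of a row means "no hit").
#'
#' @param blast_hits data.frame with columns `query`, `target`,
#'   `p_forward`, `p_reverse` (reciprocal-search p-values).
#' @param gtg_hits data.frame with columns `query`, `target`,
#'   `shared_fraction`.
#' @param annotation data.frame with columns `ec`, `target`: which target
#'   sequences are annotated with which complete EC number.
#' @param species_of named character vector mapping query sequence id to
#'   species id.
#' @param ... passed to [reciprocal_score()].
#' @return data.frame with columns `species`, `ec`, `blast_score`,
#'   `gtg_score`, one row per combination with at least one hit.
#' @export
enzyme_scores <- function(blast_hits, gtg_hits, annotation, species_of, ...) {
  check_complete_ec(annotation$ec)
  known_targets <- unique(c(blast_hits$target, gtg_hits$target))
  unknown <- setdiff(annotation$target, known_targets)
  if (length(unknown) > 0 && (nrow(blast_hits) > 0 || nrow(gtg_hits) > 0)) {
    warning(sprintf("%d annotated target(s) never hit; skipped", length(unknown)))
  }

  aggregate_channel <- function(hits, value) {
    if (nrow(hits) == 0) {
      return(data.frame(species = character(), ec = character(),
                        score = numeric()))
    }
    missing_sp <- setdiff(hits$query, names(species_of))
    if (length(missing_sp) > 0) {
      stop(sprintf("query sequence(s) without species assignment: %s",
                   paste(utils::head(missing_sp, 3), collapse = ", ")),
           call. = FALSE)
    }
    joined <- merge(hits, annotation, by = "target")
    if (nrow(joined) == 0) {
      return(data.frame(species = character(), ec = character(),
                        score = numeric()))
    }
    joined$species <- unname(species_of[joined$query])
    agg <- stats::aggregate(joined[[value]],
                            by = list(species = joined$species, ec = joined$ec),
                            FUN = max)
    names(agg)[3] <- "score"
    agg
  }

  bh <- blast_hits
  if (nrow(bh) > 0) {
    bh$score_value <- reciprocal_score(bh$p_forward, bh$p_reverse, ...)
  } else {
    bh$score_value <- numeric(0)
  }
  b <- aggregate_channel(bh, "score_value")
  g <- aggregate_channel(gtg_hits, "shared_fraction")
  names(b)[3] <- "blast_score"
  names(g)[3] <- "gtg_score"
  out <- merge(b, g, by = c("species", "ec"), all = TRUE)
  out$blast_score[is.na(out$blast_score)] <- 0
  out$gtg_score[is.na(out$gtg_score)] <- 0
  out <- out[order(out$species, out$ec), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname score_table_io
#' @export
score_lookup <- function(score_table, species, ec) {
  i <- match(paste(species, ec), paste(score_table$species, score_table$ec))
  blast <- ifelse(is.na(i), 0, score_table$blast_score[i])
  gtg <- ifelse(is.na(i), 0, score_table$gtg_score[i])
  cbind(blast_score = blast, gtg_score = gtg)
}

check_complete_ec <- function(ec) {
  bad <- !grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", ec)
  if (any(bad)) {
    stop(sprintf("incomplete or malformed EC number(s): %s",
                 paste(utils::head(unique(ec[bad]), 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(ec)
}
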