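# TSV plumbing for every tabular interface the pipeline consumes or emits.
# All readers insist on a header and report malformed rows with their line
# number; all writers round-trip through the matching reader.

read_tsv_checked <- function(path, required, numeric_cols = character()) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", colClasses = "character")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-numeric value in column '%s' at line %d",
                   path, col, bad[1] + 1L), call. = FALSE)
    }
    raw[[col]] <- v
  }
  raw
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and write evidence tables
#'
#' Hit tables, EC annotation tables, species maps and aggregated score
#' tables are all plain TSV files with declared headers. `read_blast_hits`
#' expects columns `query`, `target`, `p_forward`, `p_reverse`;
#' `read_gtg_hits` expects `query`, `target`, `shared_fraction`;
#' `read_ec_annotation` expects `ec`, `target`; `read_species_map` expects
#' `query`, `species`; score tables have `species`, `ec`, `blast_score`,
#' `gtg_score`. `score_lookup` retrieves (blast, gtg) pairs with the
#' no-hit-means-zero convention.
#'
#' @param path file path.
#' @param score_table,species,ec see `score_lookup`.
#' @param df table to write.
#' @name score_table_io
NULL

#' @rdname score_table_io
#' @export
read_blast_hits <- function(path) {
  df <- read_tsv_checked(path, c("query", "target", "p_forward", "p_reverse"),
                         c("p_forward", "p_reverse"))
  check_pvalue(df$p_forward, "p_forward")
  check_pvalue(df$p_reverse, "p_reverse")
  if (anyDuplicated(df[c("query", "target")])) {
    stop(sprintf("%s: duplicated (query, target) pair", path), call. = FALSE)
  }
  df
}

#' @rdname score_table_io
#' @export
read_gtg_hits <- function(path) {
  df <- read_tsv_checked(path, c("query", "target", "shared_fraction"),
                         "shared_fraction")
  if (any(df$shared_fraction < 0 | df$shared_fraction > 1)) {
    stop(sprintf("%s: shared_fraction outside [0, 1]", path), call. = FALSE)
  }
  df
}

#' @rdname score_table_io
#' @export
read_ec_annotation <- function(path) {
  df <- read_tsv_checked(path, c("ec", "target"))
  check_complete_ec(df$ec)
  df
}

#' @rdname score_table_io
#' @export
read_species_map <- function(path) {
  df <- read_tsv_checked(path, c("query", "species"))
  if (anyDuplicated(df$query)) {
    stop(sprintf("%s: a query maps to more than one species", path),
         call. = FALSE)
  }
  stats::setNames(df$species, df$query)
}

#' @rdname score_table_io
#' @export
read_score_table <- function(path) {
  df <- read_tsv_checked(path, c("species", "ec", "blast_score", "gtg_score"),
                         c("blast_score", "gtg_score"))
  if (anyDuplicated(df[c("species", "ec")])) {
    stop(sprintf("%s: duplicated (species, ec) row", path), call. = FALSE)
  }
  df
}

#' @rdname score_table_io
#' @export
write_score_table <- function(df, path) {
  write_tsv(df[c("species", "ec", "blast_score", "gtg_score")], path)
}

#' Read and write posterior tables
#'
#' Posterior tables carry one row per (node, ec) with the posterior
#' probability of enzyme presence.
#'
#' @param path file path.
#' @param df posterior table (`node`, `ec`, `posterior`).
#' @export
read_posteriors <- function(path) {
  df <- read_tsv_checked(path, c("node", "ec", "posterior"), "posterior")
  if (any(df$posterior < 0 | df$posterior > 1)) {
    stop(sprintf("%s: posterior outside [0, 1]", path), call. = FALSE)
  }
  df
}

#' @rdname read_posteriors
#' @export
write_posteriors <- function(df, path) {
  write_tsv(df[c("node", "ec", "posterior")], path)
}

#' Read a reference presence/absence matrix
#'
#' TSV with columns `species`, `ec`, `present` (0/1); returns a binary
#' matrix species x EC.
#'
#' @param path file path.
#' @export
read_reference_matrix <- function(path) {
  df <- read_tsv_checked(path, c("species", "ec", "present"), "present")
  if (!all(df$present %in% c(0, 1))) {
    stop(sprintf("%s: 'present' must be 0/1", path), call. = FALSE)
  }
  sp <- sort(unique(df$species))
  ec <- sort(unique(df$ec))
  m <- matrix(0L, length(sp), length(ec), dimnames = list(sp, ec))
  m[cbind(match(df$species, sp), match(df$ec, ec))] <- as.integer(df$present)
  m
}
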