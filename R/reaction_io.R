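# Flat-file formats for the reaction universe.
#
# reactions:  id <TAB> EC;EC <TAB> substrates <TAB> products <TAB> direction
#             with reactant terms "coef*molid" joined by " + "
# molecules:  id <TAB> formula <TAB> atom_elements_csv (csv may be empty)
# atom maps:  rxn sub_mol sub_occ sub_atom prod_mol prod_occ prod_atom (TSV)
# nutrients / blacklist: one id per line

parse_side <- function(s, path, line) {
  s <- trimws(s)
  if (s == "") return(stats::setNames(integer(0), character(0)))
  terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  coef <- integer(length(terms))
  mol <- character(length(terms))
  for (i in seq_along(terms)) {
    m <- regmatches(terms[i], regexec("^(?:([0-9]+)\\*)?(\\S+)$", terms[i]))[[1]]
    if (length(m) == 0) {
      stop(sprintf("%s: malformed reactant term '%s' at line %d", path,
                   terms[i], line), call. = FALSE)
    }
    coef[i] <- if (m[2] == "") 1L else as.integer(m[2])
    mol[i] <- m[3]
  }
  stats::setNames(coef, mol)
}

format_side <- function(v) {
  paste(sprintf("%d*%s", unname(v), names(v)), collapse = " + ")
}

#' Read and write reaction-universe flat files
#'
#' @param path file path.
#' @param reactions_path,molecules_path,mappings_path,nutrients_path
#'   component file paths; mappings and nutrients optional.
#' @param db a [reaction_db()].
#' @param dir output directory for [write_reaction_db()].
#' @name reaction_db_io
NULL

#' @rdname reaction_db_io
#' @export
read_molecules <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) {
      stop(sprintf("%s: malformed molecule row at line %d", path, i),
           call. = FALSE)
    }
    atoms <- if (length(f) >= 3 && nzchar(f[3])) {
      strsplit(f[3], ",", fixed = TRUE)[[1]]
    } else NULL
    molecule(f[1], f[2], atoms)
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' @rdname reaction_db_io
#' @export
read_reactions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 5) {
      stop(sprintf("%s: expected 5 tab-separated fields at line %d", path, i),
           call. = FALSE)
    }
    ec <- if (nzchar(trimws(f[2]))) {
      trimws(strsplit(f[2], ";", fixed = TRUE)[[1]])
    } else character()
    reaction(f[1], parse_side(f[3], path, i), parse_side(f[4], path, i),
             ec = ec, direction = f[5])
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' @rdname reaction_db_io
#' @export
read_atom_mappings <- function(path) {
  df <- read_tsv_checked(path, c("rxn", "sub_mol", "sub_occ", "sub_atom",
                                 "prod_mol", "prod_occ", "prod_atom"),
                         c("sub_occ", "sub_atom", "prod_occ", "prod_atom"))
  split(df[-1], df$rxn)
}

#' @rdname reaction_db_io
#' @export
read_id_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines)]
}

#' @rdname reaction_db_io
#' @export
read_reaction_db <- function(reactions_path, molecules_path,
                             mappings_path = NULL, nutrients_path = NULL) {
  reaction_db(
    molecules = read_molecules(molecules_path),
    reactions = read_reactions(reactions_path),
    mappings = if (is.null(mappings_path)) list() else
      read_atom_mappings(mappings_path),
    nutrients = if (is.null(nutrients_path)) character() else
      read_id_list(nutrients_path))
}

#' @rdname reaction_db_io
#' @export
write_reaction_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mol_lines <- vapply(db$molecules, function(m) {
    f <- paste0(names(m$counts), ifelse(m$counts > 1, m$counts, ""),
                collapse = "")
    paste(m$id, f, paste(m$atoms, collapse = ","), sep = "\t")
  }, "")
  writeLines(unname(mol_lines), file.path(dir, "molecules.tsv"))
  rxn_lines <- vapply(db$reactions, function(r) {
    paste(r$id, paste(r$ec, collapse = ";"), format_side(r$substrates),
          format_side(r$products), r$direction, sep = "\t")
  }, "")
  writeLines(unname(rxn_lines), file.path(dir, "reactions.tsv"))
  if (length(db$mappings) > 0) {
    maps <- do.call(rbind, lapply(names(db$mappings), function(id) {
      cbind(rxn = id, db$mappings[[id]])
    }))
    write_tsv(maps, file.path(dir, "atom_maps.tsv"))
  }
  writeLines(db$nutrients, file.path(dir, "nutrients.txt"))
  invisible(dir)
}
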