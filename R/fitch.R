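#' Fitch parsimony for binary presence states
#'
#' Reconstructs ancestral presence/absence states that minimize the number
#' of gain/loss events along the tree, using Fitch's two-pass algorithm.
#' The bottom-up pass builds state sets (counting one change per forced
#' union); the top-down pass resolves each node deterministically: a node
#' whose state set contains the parent's resolved state takes it, otherwise
#' (and at an ambiguous root) ties resolve toward absent. The resulting
#' full labeling attains the minimal change count.
#'
#' @param tree a [rooted_tree()].
#' @param leaf_states named 0/1 vector covering every leaf name.
#' @return list with `states` (named 0/1 vector over all nodes) and
#'   `changes` (the minimal number of state changes).
#' @export
fitch_parsimony <- function(tree, leaf_states) {
  tree <- rooted_tree(tree)
  leaves <- tree$names[tree$is_leaf]
  missing <- setdiff(leaves, names(leaf_states))
  if (length(missing) > 0) {
    stop(sprintf("leaf state missing for: %s",
                 paste(utils::head(missing, 3), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(leaf_states[leaves] %in% c(0, 1))) {
    stop("leaf states must be 0/1", call. = FALSE)
  }
  # state sets encoded as bitmasks: 1 = {absent}, 2 = {present}, 3 = both
  set <- integer(tree$n)
  changes <- 0L
  for (v in tree$postorder) {
    if (tree$is_leaf[v]) {
      set[v] <- if (leaf_states[[tree$names[v]]] == 1) 2L else 1L
    } else {
      inter <- 3L
      for (c in tree$children[[v]]) inter <- bitwAnd(inter, set[c])
      if (inter != 0L) {
        set[v] <- inter
      } else {
        uni <- 0L
        for (c in tree$children[[v]]) uni <- bitwOr(uni, set[c])
        set[v] <- uni
        changes <- changes + 1L
      }
    }
  }
  states <- integer(tree$n)
  for (v in rev(tree$postorder)) { # preorder: parents before children
    if (v == tree$root) {
      states[v] <- if (set[v] == 2L) 1L else 0L # ambiguity -> absent
    } else {
      ps <- states[tree$parent[v]]
      pbit <- if (ps == 1L) 2L else 1L
      states[v] <- if (bitwAnd(set[v], pbit) != 0L) ps else
        (if (set[v] == 2L) 1L else 0L)
    }
  }
  list(states = stats::setNames(states, tree$names), changes = changes)
}

#' Ancestral presence matrix over many enzymes
#'
#' Runs [fitch_parsimony()] for every EC column of a leaf presence matrix.
#'
#' @param tree a [rooted_tree()].
#' @param leaf_matrix binary matrix, rows named by leaf, columns by EC.
#' @return binary matrix with one row per tree node (leaves and ancestors),
#'   columns as in `leaf_matrix`.
#' @export
fitch_presence_matrix <- function(tree, leaf_matrix) {
  tree <- rooted_tree(tree)
  out <- matrix(0L, tree$n, ncol(leaf_matrix),
                dimnames = list(tree$names, colnames(leaf_matrix)))
  for (j in seq_len(ncol(leaf_matrix))) {
    out[, j] <- fitch_parsimony(tree, leaf_matrix[, j])$states[tree$names]
  }
  out
}
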