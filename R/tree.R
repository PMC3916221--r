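# Internal rooted-tree representation: integer parent pointers plus node
# names. Built from an ape "phylo" object so newick input goes through
# ape::read.tree; branch lengths are ignored (edge transition probabilities
# are estimated, not clock-derived).

#' Rooted phylogeny for presence inference
#'
#' Converts an `ape::phylo` tree (or a newick file/string) into the compact
#' rooted representation used throughout the package: integer parent
#' pointers, children lists and node names. Leaf labels must be unique; the
#' tree must be rooted. Internal nodes without labels are named
#' `anc1, anc2, ...` in `ape`'s internal-node order (root first).
#'
#' @param x an `ape::phylo` object, a newick string, or a path to a newick
#'   file.
#' @return an object of class `rooted_tree` with elements `n` (node count),
#'   `parent` (integer, 0 at the root), `children` (list), `root`, `names`,
#'   `is_leaf`, and `postorder` (children-before-parents node ordering).
#' @export
rooted_tree <- function(x) {
  if (inherits(x, "rooted_tree")) {
    return(x)
  }
  if (is.character(x)) {
    phy <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  } else {
    phy <- x
  }
  if (!inherits(phy, "phylo")) {
    stop("cannot interpret input as a phylogenetic tree", call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("leaf labels must be unique", call. = FALSE)
  }
  n_tip <- length(phy$tip.label)
  n <- n_tip + phy$Nnode
  parent <- integer(n)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- which(parent == 0L & seq_len(n) > n_tip)
  if (length(root) != 1L) {
    stop("tree must have exactly one root", call. = FALSE)
  }
  inner_names <- phy$node.label
  if (is.null(inner_names) || !length(inner_names) || any(inner_names == "")) {
    inner_names <- paste0("anc", seq_len(phy$Nnode))
  }
  nm <- c(phy$tip.label, inner_names)
  if (anyDuplicated(nm)) {
    stop("node names must be unique across leaves and ancestors",
         call. = FALSE)
  }
  children <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    children[[p]] <- c(children[[p]], phy$edge[i, 2])
  }
  out <- list(n = n, parent = parent, children = children, root = root,
              names = nm, is_leaf = seq_len(n) <= n_tip,
              postorder = postorder_nodes(parent, children, root))
  class(out) <- "rooted_tree"
  out
}

# iterative postorder (children before parents), deterministic child order
postorder_nodes <- function(parent, children, root) {
  n <- length(parent)
  order <- integer(0)
  stack <- root
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    stack <- c(stack, children[[v]])
  }
  rev(order)
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat(sprintf("rooted tree: %d leaves, %d internal nodes (root '%s')\n",
              sum(x$is_leaf), x$n - sum(x$is_leaf), x$names[x$root]))
  invisible(x)
}

#' Edges of a rooted tree
#'
#' @param tree a [rooted_tree()].
#' @return data.frame with integer columns `parent`, `child`, one row per
#'   edge, ordered by child index.
#' @export
tree_edges <- function(tree) {
  child <- which(tree$parent != 0L)
  data.frame(parent = tree$parent[child], child = child)
}

#' Serialize a rooted tree to newick
#'
#' @param tree a [rooted_tree()].
#' @param file optional path; when given the string is also written there.
#' @return the newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  tree <- rooted_tree(tree)
  fmt <- function(v) {
    if (tree$is_leaf[v]) return(tree$names[v])
    paste0("(", paste(vapply(tree$children[[v]], fmt, ""),
                      collapse = ","), ")", tree$names[v])
  }
  s <- paste0(fmt(tree$root), ";")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' A single-node tree (one species, no ancestors)
#'
#' Degenerate phylogeny used when inferring presence for one species in
#' isolation; also the backbone of the naive (no-phylogeny) classifier.
#'
#' @param name species name.
#' @export
single_node_tree <- function(name = "sp1") {
  out <- list(n = 1L, parent = 0L, children = list(integer(0)), root = 1L,
              names = name, is_leaf = TRUE, postorder = 1L)
  class(out) <- "rooted_tree"
  out
}
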