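#' Rooted patient phylogeny with per-edge mutation counts
#'
#' `evo_tree` is the package's central tree container: a rooted tree whose
#' leaves are tumor regions (plus, optionally, one matched-normal outgroup
#' leaf) and whose edges carry the somatic mutations assigned to them. The
#' length of an edge is the number of mutations on it, so branch lengths are
#' directly proportional to mutation counts.
#'
#' The tree is stored as a named parent vector: `parent[child]` gives the id
#' of the node above `child`, and the root maps to `NA`. Each non-root node
#' identifies the edge above it, so `lengths` and `mutations` are keyed by
#' child node id. Multifurcations and unifurcations (e.g. the trunk edge
#' between the root and the most recent common ancestor of the tumor
#' regions) are both allowed.
#'
#' @param parent Named character vector; `parent[node]` is the parent node id,
#'   `NA` for the single root. Names define the node set and the stored child
#'   order.
#' @param lengths Named numeric vector of edge lengths keyed by child node id.
#'   If `NULL`, lengths are taken as the number of mutations on each edge
#'   (zero when `mutations` is also `NULL`).
#' @param mutations Named list of character vectors keyed by child node id:
#'   the mutation ids assigned to the edge above that node. Optional.
#' @param outgroup Id of the normal outgroup leaf, or `NA` if the tree has
#'   none. The outgroup edge must have length 0 (the normal genome carries no
#'   somatic mutations).
#'
#' @return An object of class `evo_tree`.
#' @examples
#' tr <- evo_tree(
#'   parent  = c(root = NA, A = "root", R1 = "A", R2 = "A"),
#'   lengths = c(A = 5, R1 = 2, R2 = 3)
#' )
#' tree_leaves(tr)
#' @export
evo_tree <- function(parent, lengths = NULL, mutations = NULL,
                     outgroup = NA_character_) {
  if (!is.character(parent) || is.null(names(parent)))
    stop("`parent` must be a named character vector")
  nodes <- names(parent)
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  root <- nodes[is.na(parent)]
  if (length(root) != 1L) stop("tree must have exactly one root (one NA parent)")
  kids <- setdiff(nodes, root)
  if (!all(parent[kids] %in% nodes))
    stop("every parent id must itself be a node")

  if (is.null(mutations)) {
    mutations <- stats::setNames(rep(list(character()), length(kids)), kids)
  } else {
    miss <- setdiff(kids, names(mutations))
    mutations[miss] <- rep(list(character()), length(miss))
    mutations <- mutations[kids]
  }
  if (is.null(lengths)) {
    lengths <- vapply(mutations, length, integer(1))
  } else {
    if (is.null(names(lengths)) || !all(kids %in% names(lengths)))
      stop("`lengths` must be named by child node id and cover all edges")
    lengths <- lengths[kids]
    if (any(lengths < 0)) stop("edge lengths must be non-negative")
  }

  # acyclicity / connectivity: every node must reach the root
  for (v in kids) {
    seen <- character()
    w <- v
    while (!is.na(parent[[w]])) {
      if (w %in% seen) stop("cycle detected in parent map")
      seen <- c(seen, w)
      w <- parent[[w]]
    }
    if (w != root) stop("node ", v, " does not reach the root")
  }
  if (!is.na(outgroup)) {
    if (!outgroup %in% kids) stop("outgroup must be a non-root node")
    if (lengths[[outgroup]] != 0)
      stop("outgroup edge must have length 0")
  }

  structure(
    list(parent = parent, lengths = lengths, mutations = mutations,
         root = root, outgroup = outgroup),
    class = "evo_tree"
  )
}

#' @export
print.evo_tree <- function(x, ...) {
  lv <- tree_leaves(x)
  cat("<evo_tree> ", length(x$parent), " nodes, ", length(lv), " leaves",
      if (!is.na(x$outgroup)) " (incl. outgroup)",
      ", total length ", tree_total_length(x), "\n", sep = "")
  invisible(x)
}

#' Tree accessors
#'
#' Small helpers over [evo_tree()] objects: children of a node (in stored
#' order), leaf set, per-node depth in edges, per-node distance from the root
#' in mutation units, and the total tree length. The outgroup edge (length 0)
#' is excluded from `tree_total_length()`.
#'
#' @param tree An `evo_tree`.
#' @param node A node id.
#' @name tree-accessors
NULL

#' @rdname tree-accessors
#' @export
tree_children <- function(tree, node) {
  names(tree$parent)[!is.na(tree$parent) & tree$parent == node]
}

#' @rdname tree-accessors
#' @export
tree_leaves <- function(tree) {
  setdiff(names(tree$parent), unique(tree$parent[!is.na(tree$parent)]))
}

#' @rdname tree-accessors
#' @export
tree_depths <- function(tree) {
  d <- stats::setNames(rep(NA_real_, length(tree$parent)), names(tree$parent))
  d[tree$root] <- 0
  todo <- tree_children(tree, tree$root)
  while (length(todo)) {
    v <- todo[[1]]; todo <- todo[-1]
    d[v] <- d[[tree$parent[[v]]]] + 1
    todo <- c(todo, tree_children(tree, v))
  }
  d
}

#' @rdname tree-accessors
#' @export
tree_root_distances <- function(tree) {
  d <- stats::setNames(rep(NA_real_, length(tree$parent)), names(tree$parent))
  d[tree$root] <- 0
  todo <- tree_children(tree, tree$root)
  while (length(todo)) {
    v <- todo[[1]]; todo <- todo[-1]
    d[v] <- d[[tree$parent[[v]]]] + tree$lengths[[v]]
    todo <- c(todo, tree_children(tree, v))
  }
  d
}

#' @rdname tree-accessors
#' @export
tree_total_length <- function(tree) {
  keep <- names(tree$lengths)
  if (!is.na(tree$outgroup)) keep <- setdiff(keep, tree$outgroup)
  sum(tree$lengths[keep])
}

# leaves below each node, as a named list of character vectors
tree_leafsets <- function(tree) {
  nodes <- names(tree$parent)
  leaves <- tree_leaves(tree)
  sets <- stats::setNames(vector("list", length(nodes)), nodes)
  # postorder: repeatedly resolve nodes whose children are all resolved
  resolved <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  for (l in leaves) { sets[[l]] <- l; resolved[l] <- TRUE }
  while (!all(resolved)) {
    for (v in nodes[!resolved]) {
      ch <- tree_children(tree, v)
      if (all(resolved[ch])) {
        sets[[v]] <- sort(unique(unlist(sets[ch])))
        resolved[v] <- TRUE
      }
    }
  }
  sets
}

# most recent common ancestor of a set of leaves; unifurcations can make
# several nested nodes share a minimal leaf set, in which case the deepest
# (most recent) one is the MRCA
tree_mrca <- function(tree, leaves, leafsets = NULL) {
  if (is.null(leafsets)) leafsets <- tree_leafsets(tree)
  sz <- vapply(leafsets, length, integer(1))
  cand <- names(leafsets)[vapply(leafsets, function(s) all(leaves %in% s),
                                 logical(1))]
  cand <- cand[sz[cand] == min(sz[cand])]
  if (length(cand) > 1L) {
    d <- tree_depths(tree)
    cand <- cand[which.max(d[cand])]
  }
  cand
}

#' Canonical Newick string of a tree topology
#'
#' Serializes the tree with children ordered by their canonical subtree
#' string, so that two isomorphic trees (same topology, same leaf labels and
#' edge lengths) always produce the same string. Used as the deterministic
#' tie-break among equally parsimonious tree topologies.
#'
#' @param tree An `evo_tree`.
#' @param lengths Include branch lengths in the string?
#' @return A Newick string ending in `";"`.
#' @export
canonical_newick <- function(tree, lengths = TRUE) {
  fmt <- function(v) {
    ch <- tree_children(tree, v)
    lab <- v
    len <- if (lengths && !is.na(tree$parent[[v]]))
      paste0(":", format(tree$lengths[[v]], scientific = FALSE)) else ""
    if (!length(ch)) return(paste0(lab, len))
    sub <- sort(vapply(ch, fmt, character(1)))
    paste0("(", paste(sub, collapse = ","), ")", lab, len)
  }
  paste0(fmt(tree$root), ";")
}

# plain (stored child order) newick, used by write_tree_newick
stored_newick <- function(tree) {
  fmt <- function(v) {
    ch <- tree_children(tree, v)
    len <- if (!is.na(tree$parent[[v]]))
      paste0(":", format(tree$lengths[[v]], scientific = FALSE)) else ""
    if (!length(ch)) return(paste0(v, len))
    paste0("(", paste(vapply(ch, fmt, character(1)), collapse = ","), ")",
           v, len)
  }
  paste0(fmt(tree$root), ";")
}

#' Convert between `evo_tree` and `ape::phylo`
#'
#' `as_phylo()` builds an [ape][ape::read.tree] `phylo` object (internal node
#' ids become node labels); `evo_tree_from_phylo()` inverts it. Unifurcating
#' nodes such as the trunk below the root survive the round trip.
#'
#' @param tree An `evo_tree`.
#' @param phy An `ape` `phylo` object with unique tip labels.
#' @param outgroup Outgroup leaf id to flag, or `NA`.
#' @return `as_phylo()` a `phylo`; `evo_tree_from_phylo()` an `evo_tree`.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = stored_newick(tree))
}

#' @rdname as_phylo
#' @export
evo_tree_from_phylo <- function(phy, outgroup = NA_character_) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  node_lab <- phy$node.label
  if (is.null(node_lab) || any(!nzchar(node_lab)))
    node_lab <- paste0("N", seq_len(nnode))
  labs <- c(phy$tip.label, node_lab)
  if (anyDuplicated(labs)) stop("duplicate node labels in phylo object")
  parent <- stats::setNames(rep(NA_character_, ntip + nnode), labs)
  lens <- stats::setNames(numeric(0), character(0))
  el <- phy$edge.length
  if (is.null(el)) el <- rep(0, nrow(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    parent[labs[phy$edge[i, 2]]] <- labs[phy$edge[i, 1]]
    lens[labs[phy$edge[i, 2]]] <- el[i]
  }
  evo_tree(parent, lengths = lens, outgroup = outgroup)
}

#' The running 4-region example tree
#'
#' A small rooted tree used throughout the documentation and tests: a trunk
#' of 3 mutations from the root to the common ancestor of all regions, an
#' intermediate shared edge of 2 mutations leading to regions R1 (3), R2 (1)
#' and R3 (3), and a fourth region R4 on its own branch of 2 mutations. The
#' total tree length is 14 and the edge-length multiset is {3, 2, 3, 1, 3, 2}.
#'
#' @return An `evo_tree` with leaves R1--R4.
#' @examples
#' tr <- demo_tree()
#' tree_total_length(tr)  # 14
#' @export
demo_tree <- function() {
  evo_tree(
    parent  = c(root = NA, A = "root", B = "A", R4 = "A",
                R1 = "B", R2 = "B", R3 = "B"),
    lengths = c(A = 3, B = 2, R4 = 2, R1 = 3, R2 = 1, R3 = 3)
  )
}
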