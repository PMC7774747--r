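#' Bifurcate a phylogeny and pad it onto a reference binary tree
#'
#' Maps an observed phylogeny onto a reference bifurcated tree so that trees
#' of different shapes become comparable. Internal nodes with more than two
#' children are made binary by inserting zero-length virtual edges: the two
#' children with the largest total (real) subtree length descend together
#' through one virtual node, the remaining children through a second virtual
#' node (recursively, if more than two remain). Every node above the target
#' depth is then completed to exactly two children with zero-length virtual
#' edges, so the result is a complete binary tree of depth `target_depth`
#' whose real edges carry the original lengths. The sum of real edge lengths
#' is unchanged.
#'
#' The matched-normal outgroup leaf, if present, is dropped before mapping:
#' the reference tree describes the tumor clade hanging from the trunk.
#'
#' @param tree An `evo_tree`.
#' @param target_depth Depth of the reference tree; must be at least the
#'   tree's own post-bifurcation depth (the default).
#' @return An `evo_tree` of subclass `bifurcated_tree` with attributes
#'   `depth` (the reference depth) and `virtual` (ids of inserted nodes).
#'   Children are stored in canonical traversal order: at each node the
#'   child whose subtree carries the larger total real length comes first
#'   (ties: real before virtual, then lexicographically smallest contained
#'   node id).
#' @examples
#' b <- bifurcate_and_pad(demo_tree())
#' attr(b, "depth")          # 4
#' tree_depths(b)[c("R1", "R2", "R3")]  # all 4 after bifurcation
#' @export
bifurcate_and_pad <- function(tree, target_depth = NULL) {
  stopifnot(inherits(tree, "evo_tree"))
  st <- slot_tree(tree)
  md <- slot_depth(st)
  D <- if (is.null(target_depth)) md else target_depth
  if (D < md)
    stop("target_depth ", D, " is smaller than the bifurcated depth ", md)

  parent <- c(stats::setNames(NA_character_, st$id))
  lens <- numeric(0)
  virt <- character(0)
  vctr <- 0L
  new_virtual_id <- function() {
    vctr <<- vctr + 1L
    paste0(".v", vctr)
  }
  emit <- function(slot, depth) {
    kids <- slot$children
    if (depth >= D) {
      if (length(kids)) stop("internal error: node below reference depth")
      return(invisible())
    }
    while (length(kids) < 2L) {
      kids <- c(kids, list(list(id = new_virtual_id(), len = 0,
                                virtual = TRUE, children = list(), tot = 0)))
    }
    for (k in kids) {
      parent[k$id] <<- slot$id
      lens[k$id] <<- k$len
      if (isTRUE(k$virtual)) virt <<- c(virt, k$id)
      emit(k, depth + 1L)
    }
  }
  emit(st, 0L)
  out <- evo_tree(parent, lengths = lens)
  attr(out, "depth") <- D
  attr(out, "virtual") <- virt
  class(out) <- c("bifurcated_tree", class(out))
  out
}

#' Normalize edge lengths of a bifurcated tree
#'
#' Divides every real edge length by the total tree length, so that real
#' edge lengths sum to 1; virtual edges stay at 0. Errors when the total
#' length is 0 (a tree with no mutations has no evolutionary pattern to
#' normalize).
#'
#' @param tree A `bifurcated_tree` from [bifurcate_and_pad()].
#' @return The tree with normalized lengths.
#' @export
normalize_lengths <- function(tree) {
  stopifnot(inherits(tree, "bifurcated_tree"))
  tot <- sum(tree$lengths)
  if (tot == 0) stop("total edge length is 0; nothing to normalize")
  tree$lengths <- tree$lengths / tot
  tree
}

#' Standardized edge-length vector of a bifurcated tree
#'
#' Reads the reference tree's edges in canonical order -- from the root
#' down, visiting at each internal node the child with the larger total real
#' subtree length first -- and records each edge's normalized length. The
#' result has one entry per reference-tree edge, `2^(depth+1) - 2` in total;
#' virtual edges contribute 0 and real entries sum to 1.
#'
#' @param tree A normalized `bifurcated_tree` (see [normalize_lengths()]).
#' @return Numeric vector of length `2^(depth+1) - 2` with attribute
#'   `depth`.
#' @examples
#' z <- vectorize(normalize_lengths(bifurcate_and_pad(demo_tree())))
#' round(z[1:10], 3)
#' @export
vectorize <- function(tree) {
  stopifnot(inherits(tree, "bifurcated_tree"))
  D <- attr(tree, "depth")
  z <- numeric(0)
  walk <- function(v) {
    for (ch in tree_children(tree, v)) {
      z[length(z) + 1L] <<- tree$lengths[[ch]]
      walk(ch)
    }
  }
  walk(tree$root)
  stopifnot(length(z) == 2^(D + 1) - 2)
  attr(z, "depth") <- D
  z
}

#' Standardized vectors for a cohort of trees
#'
#' Computes one standardized edge-length vector per patient on a shared
#' reference tree, whose depth is the maximum post-bifurcation depth over
#' the cohort. All vectors therefore have the same length
#' `2^(D+1) - 2`; patients with shallower trees are padded with trailing
#' structural zeros, so adding a deeper patient to a cohort only extends the
#' existing vectors with zeros.
#'
#' @param trees Named list of `evo_tree` objects (names are patient ids).
#' @return Numeric matrix, one row per patient, with attribute `depth`.
#' @export
cohort_vectors <- function(trees) {
  stopifnot(length(trees) >= 1L)
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    stop("`trees` must be a named list (patient ids)")
  depths <- vapply(trees, function(t) slot_depth(slot_tree(t)), numeric(1))
  D <- max(depths)
  vs <- lapply(trees, function(t)
    vectorize(normalize_lengths(bifurcate_and_pad(t, D))))
  m <- do.call(rbind, vs)
  rownames(m) <- names(trees)
  attr(m, "depth") <- D
  m
}

## ---- internal: slot-tree construction ---------------------------------
## A "slot" is one mapped node: list(id, len (edge above), virtual flag,
## children (list of <= 2 slots, emission-ordered), tot (len + real length
## below), key (smallest contained real id, for deterministic tie-breaks)).

slot_tree <- function(tree) {
  vctr <- 0L
  new_vid <- function() { vctr <<- vctr + 1L; paste0(".g", vctr) }
  build <- function(v, len) {
    ch <- tree_children(tree, v)
    if (!is.na(tree$outgroup)) ch <- setdiff(ch, tree$outgroup)
    kids <- lapply(ch, function(c) build(c, tree$lengths[[c]]))
    slots <- group_slots(kids, new_vid)
    list(id = v, len = len, virtual = FALSE, children = slots,
         tot = len + sum(vapply(slots, function(s) s$tot, numeric(1))),
         key = v)
  }
  build(tree$root, 0)
}

order_slots <- function(slots) {
  tot <- vapply(slots, function(s) s$tot, numeric(1))
  virt <- vapply(slots, function(s) isTRUE(s$virtual), logical(1))
  key <- vapply(slots, function(s) s$key, character(1))
  slots[order(-tot, virt, key)]
}

group_slots <- function(kids, new_vid) {
  if (length(kids) <= 1L) return(kids)
  kids <- order_slots(kids)
  if (length(kids) == 2L) return(kids)
  make_virtual <- function(members) {
    members <- order_slots(members)
    inner <- if (length(members) <= 2L) members else {
      # more than two members: regroup under further virtual nodes
      group_slots(members, new_vid)
    }
    list(id = new_vid(), len = 0, virtual = TRUE, children = inner,
         tot = sum(vapply(inner, function(s) s$tot, numeric(1))),
         key = min(vapply(inner, function(s) s$key, character(1))))
  }
  vA <- make_virtual(kids[1:2])
  vB <- make_virtual(kids[-(1:2)])
  order_slots(list(vA, vB))
}

slot_depth <- function(slot, depth = 0L) {
  if (!length(slot$children)) return(depth)
  max(vapply(slot$children, slot_depth, numeric(1), depth = depth + 1L))
}
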