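#' Build a per-patient binary mutation presence matrix
#'
#' Collapses a patient's mutation calls into a regions-by-mutations binary
#' matrix. A mutation is scored present in a region when its variant allele
#' frequency there reaches `vaf_threshold` (default 0.1); calls below the
#' threshold are treated as absent, so low-level sequencing noise does not
#' create spurious branches. Multiple mutations of the same gene are kept as
#' distinct characters keyed by gene and protein change. Mutations absent
#' from every region after thresholding are dropped.
#'
#' @param calls `data.frame` of mutation calls for a single patient, as read
#'   by [read_mutation_table()].
#' @param vaf_threshold Presence threshold on VAF; calls with
#'   `vaf >= vaf_threshold` count as present.
#' @return An object of class `region_matrix`: a list with `patient_id`,
#'   `region_ids`, `mutation_ids`, the binary `presence` matrix
#'   (regions x mutations), a named logical `drivers` vector, and a `ccf`
#'   matrix (NA where the mutation was not observed in the region).
#' @export
build_presence_matrix <- function(calls, vaf_threshold = 0.1) {
  pid <- unique(calls$patient_id)
  if (length(pid) != 1L) stop("calls must come from exactly one patient")
  regions <- sort(unique(calls$region_id))
  if (length(regions) < 2L)
    stop("multi-region method requires at least 2 regions; got ",
         length(regions))
  mut_id <- ifelse(nzchar(calls$protein_change),
                   paste0(calls$gene, ":", calls$protein_change), calls$gene)
  muts <- sort(unique(mut_id))
  pres <- matrix(0L, length(regions), length(muts),
                 dimnames = list(regions, muts))
  ccf <- matrix(NA_real_, length(regions), length(muts),
                dimnames = list(regions, muts))
  ok <- calls$vaf >= vaf_threshold
  for (i in which(ok)) pres[calls$region_id[i], mut_id[i]] <- 1L
  for (i in seq_len(nrow(calls)))
    ccf[calls$region_id[i], mut_id[i]] <- calls$ccf[i]
  drv <- tapply(calls$is_driver, mut_id, function(x) any(x, na.rm = TRUE))
  drv <- stats::setNames(as.logical(drv[muts]), muts)

  keep <- colSums(pres) > 0L
  structure(
    list(patient_id = pid, region_ids = regions,
         mutation_ids = muts[keep],
         presence = pres[, keep, drop = FALSE],
         drivers = drv[keep],
         ccf = ccf[, keep, drop = FALSE],
         genes = stats::setNames(calls$gene[match(muts[keep], mut_id)],
                                 muts[keep])),
    class = "region_matrix"
  )
}

#' @export
print.region_matrix <- function(x, ...) {
  cat("<region_matrix> patient ", x$patient_id, ": ",
      length(x$region_ids), " regions x ", length(x$mutation_ids),
      " mutations\n", sep = "")
  invisible(x)
}

#' Classify mutation tree locations (ubiquitous / shared / private)
#'
#' Labels each mutation by how many tumor regions carry it: present in all
#' regions is ubiquitous (location A, the trunk), present in exactly one is
#' private (location C), anything in between is shared (location B).
#'
#' @param matrix A `region_matrix` from [build_presence_matrix()].
#' @return `data.frame` with columns `mutation_id`, `location` (one of
#'   `"A_ubiquitous"`, `"B_shared"`, `"C_private"`), `n_regions_present`.
#' @export
classify_locations <- function(matrix) {
  stopifnot(inherits(matrix, "region_matrix"))
  nr <- length(matrix$region_ids)
  if (nr < 2L) stop("need at least 2 regions")
  cs <- colSums(matrix$presence)
  loc <- ifelse(cs == nr, "A_ubiquitous",
                ifelse(cs == 1L, "C_private", "B_shared"))
  data.frame(mutation_id = matrix$mutation_ids,
             location = unname(loc),
             n_regions_present = as.integer(unname(cs)),
             row.names = NULL)
}

#' Dollo parsimony score of a tree for a presence matrix
#'
#' Under Dollo parsimony each mutation is gained exactly once -- on the edge
#' above the most recent common ancestor (MRCA) of the regions that carry it
#' -- and may subsequently be lost any number of times. The score of a tree
#' is the total number of events: one gain per mutation plus the implied
#' losses (edges inside the MRCA clade leading to carrier-free subtrees).
#'
#' @param tree An `evo_tree` whose non-outgroup leaves include all regions of
#'   `matrix`.
#' @param matrix A `region_matrix`.
#' @return Integer Dollo score.
#' @export
dollo_score <- function(tree, matrix) {
  stopifnot(inherits(tree, "evo_tree"), inherits(matrix, "region_matrix"))
  sets <- tree_leafsets(tree)
  if (!is.na(tree$outgroup))
    sets <- lapply(sets, function(s) setdiff(s, tree$outgroup))
  score <- 0L
  for (m in matrix$mutation_ids) {
    S <- matrix$region_ids[matrix$presence[, m] == 1L]
    mrca <- tree_mrca(tree, S, sets)
    msize <- length(sets[[mrca]])
    losses <- 0L
    for (v in names(tree$parent)) {
      p <- tree$parent[[v]]
      if (is.na(p)) next
      if (identical(v, tree$outgroup)) next
      if (length(intersect(sets[[v]], S)) == 0L &&
          length(intersect(sets[[p]], S)) > 0L &&
          length(sets[[p]]) <= msize)
        losses <- losses + 1L
    }
    score <- score + 1L + losses
  }
  score
}

#' Reconstruct a patient phylogeny by Dollo parsimony
#'
#' Searches rooted binary topologies over the tumor regions for the tree
#' minimizing the Dollo score (see [dollo_score()]). The matched normal is
#' attached as an all-zero outgroup leaf at the root, so the edge from the
#' root to the common ancestor of the regions is the trunk. For small region
#' counts all rooted topologies are enumerated; above that, seeded
#' hill-climbing over nearest-neighbor-interchange (NNI) moves with random
#' restarts is used. Ties among equally parsimonious topologies are broken
#' deterministically by the lexicographically smallest canonical Newick
#' string.
#'
#' Mutations are then assigned to edges with [assign_mutations_to_edges()],
#' so the returned tree has edge lengths equal to mutation counts.
#'
#' @param matrix A `region_matrix` with 2--12 regions.
#' @param search `"auto"` (exhaustive up to `exhaustive_max` regions, NNI
#'   above), `"exhaustive"` (allowed up to 7 regions), or `"nni"`.
#' @param n_restarts Random restarts for the NNI search. Uses R's global
#'   random number generator; set a seed for reproducibility.
#' @param exhaustive_max Region count up to which `"auto"` enumerates.
#' @return An `evo_tree` with outgroup leaf `"normal"`, mutations assigned to
#'   edges, and attributes `dollo_score` and `search`.
#' @export
dollo_tree <- function(matrix, search = c("auto", "exhaustive", "nni"),
                       n_restarts = 10, exhaustive_max = 6) {
  stopifnot(inherits(matrix, "region_matrix"))
  search <- match.arg(search)
  n <- length(matrix$region_ids)
  if (length(matrix$mutation_ids) == 0L) stop("empty presence matrix")
  if (n < 2L || n > 12L) stop("supported region counts are 2..12")
  if (search == "exhaustive" && n > 7L)
    stop("exhaustive search supported only for <= 7 regions")
  if (search == "auto") search <- if (n <= exhaustive_max) "exhaustive" else "nni"

  pat <- pattern_masks(matrix)
  if (search == "exhaustive") {
    tops <- all_rooted_topologies(n)
    scores <- vapply(tops, score_nested, numeric(1),
                     patterns = pat$masks, weights = pat$weights, n = n)
    best <- min(scores)
    cand <- tops[scores == best]
    strs <- vapply(cand, nested_canonical, character(1),
                   labels = matrix$region_ids)
    top <- cand[[order(strs)[1L]]]
  } else {
    best <- Inf; best_tops <- list()
    for (r in seq_len(max(1, n_restarts))) {
      cur <- random_topology(n)
      cur_s <- score_nested(cur, pat$masks, pat$weights, n)
      repeat {
        nb <- nni_neighbors(cur)
        ns <- vapply(nb, score_nested, numeric(1),
                     patterns = pat$masks, weights = pat$weights, n = n)
        if (!length(ns) || min(ns) >= cur_s) break
        cur <- nb[[which.min(ns)]]
        cur_s <- min(ns)
      }
      if (cur_s < best) { best <- cur_s; best_tops <- list(cur) }
      else if (cur_s == best) best_tops <- c(best_tops, list(cur))
    }
    strs <- vapply(best_tops, nested_canonical, character(1),
                   labels = matrix$region_ids)
    top <- best_tops[[order(strs)[1L]]]
  }
  pat_mut <- length(matrix$mutation_ids)
  tree <- nested_to_tree(top, matrix$region_ids)
  tree <- assign_mutations_to_edges(tree, matrix)
  attr(tree, "dollo_score") <- as.integer(best + pat_mut)
  attr(tree, "search") <- search
  tree
}

#' Assign mutations to tree edges
#'
#' Attaches each mutation to the edge above the MRCA of the regions carrying
#' it and sets edge lengths to mutation counts. A mutation present in every
#' region lands on the trunk (the edge from the root to the tumor clade);
#' a mutation private to one region lands on that region's pendant edge.
#' Every mutation is assigned to exactly one edge, so edge lengths sum to
#' the number of mutations.
#'
#' @param tree An `evo_tree` whose non-outgroup leaves are the regions of
#'   `matrix`.
#' @param matrix A `region_matrix`.
#' @return The tree with `mutations` and `lengths` replaced by the
#'   assignment.
#' @export
assign_mutations_to_edges <- function(tree, matrix) {
  stopifnot(inherits(tree, "evo_tree"), inherits(matrix, "region_matrix"))
  regions <- setdiff(tree_leaves(tree),
                     if (is.na(tree$outgroup)) character() else tree$outgroup)
  if (!setequal(regions, matrix$region_ids))
    stop("tree leaves do not match matrix regions")
  sets <- tree_leafsets(tree)
  if (!is.na(tree$outgroup))
    sets <- lapply(sets, function(s) setdiff(s, tree$outgroup))
  kids <- setdiff(names(tree$parent), tree$root)
  mut <- stats::setNames(rep(list(character()), length(kids)), kids)
  for (m in matrix$mutation_ids) {
    S <- matrix$region_ids[matrix$presence[, m] == 1L]
    if (!length(S)) stop("mutation ", m, " has an empty carrier set")
    node <- tree_mrca(tree, S, sets)
    if (identical(node, tree$root))
      stop("MRCA is the root; the tree needs a trunk edge above the regions")
    mut[[node]] <- c(mut[[node]], m)
  }
  evo_tree(tree$parent, mutations = mut, outgroup = tree$outgroup)
}

## ---- internal: nested topology machinery ------------------------------
## A rooted binary topology over regions 1..n is a nested list; a leaf is an
## integer. Scoring uses per-node carrier bitmasks, so n <= 12 leaves.

pattern_masks <- function(matrix) {
  masks <- apply(matrix$presence, 2L,
                 function(col) sum(2^(which(col == 1L) - 1L)))
  tab <- table(masks)
  list(masks = as.numeric(names(tab)), weights = as.numeric(tab))
}

# postorder arrays: node masks and parent indices
nested_arrays <- function(t, n) {
  masks <- numeric(0); parent <- integer(0)
  walk <- function(x) {  # returns index of the node just added
    if (!is.list(x)) {
      masks[length(masks) + 1L] <<- 2^(x - 1L)
      parent[length(parent) + 1L] <<- NA_integer_
      return(length(masks))
    }
    a <- walk(x[[1]]); b <- walk(x[[2]])
    masks[length(masks) + 1L] <<- masks[a] + masks[b]
    parent[length(parent) + 1L] <<- NA_integer_
    idx <- length(masks)
    parent[a] <<- idx; parent[b] <<- idx
    idx
  }
  walk(t)
  list(masks = masks, parent = parent)
}

# Dollo losses only (gains are constant across topologies); weighted sum
score_nested <- function(t, patterns, weights, n) {
  ar <- nested_arrays(t, n)
  masks <- as.integer(ar$masks)
  parent <- ar$parent
  sizes <- popcount(masks)
  vs <- which(!is.na(parent))   # all non-root nodes of the region clade
  pidx <- parent[vs]
  total <- 0
  for (i in seq_along(patterns)) {
    S <- as.integer(patterns[i])
    inter <- bitwAnd(masks, S)
    carr <- inter != 0L
    mrca_size <- min(sizes[inter == S])
    losses <- sum(!carr[vs] & carr[pidx] & sizes[pidx] <= mrca_size)
    total <- total + weights[i] * losses
  }
  total
}

popcount <- function(x) {
  r <- integer(length(x))
  while (any(x > 0)) { r <- r + x %% 2L; x <- x %/% 2L }
  r
}

all_rooted_topologies <- function(n) {
  if (n == 1L) return(list(1L))
  smaller <- all_rooted_topologies(n - 1L)
  out <- list()
  for (t in smaller) out <- c(out, insert_leaf(t, n))
  out
}

insert_leaf <- function(t, leaf) {
  out <- list(list(t, leaf))
  if (is.list(t)) {
    for (v in insert_leaf(t[[1]], leaf)) out <- c(out, list(list(v, t[[2]])))
    for (v in insert_leaf(t[[2]], leaf)) out <- c(out, list(list(t[[1]], v)))
  }
  out
}

nni_neighbors <- function(t) {
  if (!is.list(t)) return(list())
  res <- list()
  A <- t[[1]]; B <- t[[2]]
  if (is.list(A))
    res <- c(res, list(list(list(B, A[[2]]), A[[1]])),
             list(list(list(A[[1]], B), A[[2]])))
  if (is.list(B))
    res <- c(res, list(list(B[[1]], list(A, B[[2]]))),
             list(list(B[[2]], list(A, B[[1]]))))
  for (v in nni_neighbors(A)) res <- c(res, list(list(v, B)))
  for (v in nni_neighbors(B)) res <- c(res, list(list(A, v)))
  res
}

random_topology <- function(n) {
  pool <- as.list(seq_len(n))
  while (length(pool) > 1L) {
    ij <- sample.int(length(pool), 2L)
    merged <- list(pool[[ij[1]]], pool[[ij[2]]])
    pool <- c(pool[-ij], list(merged))
  }
  pool[[1]]
}

nested_canonical <- function(t, labels) {
  fmt <- function(x) {
    if (!is.list(x)) return(labels[x])
    sub <- sort(c(fmt(x[[1]]), fmt(x[[2]])))
    paste0("(", paste(sub, collapse = ","), ")")
  }
  paste0(fmt(t), ";")
}

# nested topology -> evo_tree with root, trunk, and "normal" outgroup.
# Children are canonically ordered and internal nodes named N1, N2, ... in
# preorder, so identical topologies always yield identical trees.
nested_to_tree <- function(t, labels) {
  cano <- function(x) {
    if (!is.list(x)) return(list(key = labels[x], node = x))
    a <- cano(x[[1]]); b <- cano(x[[2]])
    kids <- if (a$key <= b$key) list(a, b) else list(b, a)
    list(key = paste0("(", kids[[1]]$key, ",", kids[[2]]$key, ")"),
         node = kids)
  }
  ct <- cano(t)
  parent <- c(root = NA_character_, normal = "root")
  counter <- 0L
  emit <- function(x, par) {
    if (!is.list(x$node)) {
      parent[labels[x$node]] <<- par
      return(invisible())
    }
    counter <<- counter + 1L
    id <- paste0("N", counter)
    parent[id] <<- par
    emit(x$node[[1]], id)
    emit(x$node[[2]], id)
  }
  emit(ct, "root")
  evo_tree(parent, lengths = stats::setNames(rep(0, length(parent) - 1L),
                                             setdiff(names(parent), "root")),
           outgroup = "normal")
}
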