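# Independent oracles and small generators used across the test files.
# These deliberately avoid the package's internal machinery: leaf sets,
# Dollo scores, hypergeometric tails etc. are recomputed from first
# principles so implementation and check stay on separate routes.

# ---- random trees ------------------------------------------------------

# random rooted tree over n regions with a trunk; 2-4 children per internal
# node (multifurcating), integer edge lengths in 1..max_len
random_mtree <- function(n_leaves = 5, max_len = 9) {
  counter <- 0L
  parent <- c(root = NA_character_)
  lens <- numeric(0)
  grow <- function(leaves, par) {
    if (length(leaves) == 1L) {
      parent[leaves] <<- par
      lens[leaves] <<- sample.int(max_len, 1L)
      return(invisible())
    }
    counter <<- counter + 1L
    id <- paste0("M", counter)
    parent[id] <<- par
    lens[id] <<- sample.int(max_len, 1L)
    k <- min(length(leaves), sample(2:4, 1L))
    grp <- sample(rep(seq_len(k), length.out = length(leaves)))
    for (g in seq_len(k)) grow(leaves[grp == g], id)
  }
  grow(paste0("R", seq_len(n_leaves)), "root")
  evo_tree(parent, lengths = lens)
}

# random binary region tree with normal outgroup and mutations on edges
random_patient_tree <- function(n_regions = 4, n_mut = 30) {
  rm <- random_region_matrix(n_regions, n_mut)
  dollo_tree(rm, search = "exhaustive")
}

# ---- presence matrices -------------------------------------------------

# region_matrix object built directly from a binary matrix
make_rm <- function(presence, patient_id = "P1") {
  if (is.null(rownames(presence)))
    rownames(presence) <- paste0("R", seq_len(nrow(presence)))
  if (is.null(colnames(presence)))
    colnames(presence) <- paste0("m", seq_len(ncol(presence)))
  keep <- colSums(presence) > 0
  presence <- presence[, keep, drop = FALSE]
  structure(
    list(patient_id = patient_id, region_ids = rownames(presence),
         mutation_ids = colnames(presence),
         presence = presence,
         drivers = stats::setNames(rep(FALSE, ncol(presence)),
                                   colnames(presence)),
         ccf = matrix(NA_real_, nrow(presence), ncol(presence),
                      dimnames = dimnames(presence)),
         genes = stats::setNames(colnames(presence), colnames(presence))),
    class = "region_matrix")
}

random_region_matrix <- function(n_regions, n_mut, p = 0.5) {
  m <- matrix(rbinom(n_regions * n_mut, 1L, p), n_regions, n_mut)
  empty <- colSums(m) == 0
  for (j in which(empty)) m[sample.int(n_regions, 1L), j] <- 1L
  make_rm(m)
}

# ---- Dollo oracle ------------------------------------------------------

# leaf regions below each node, recomputed from the parent map alone
oracle_leaves_below <- function(tree) {
  nodes <- names(tree$parent)
  is_parent <- nodes %in% tree$parent
  leaves <- nodes[!is_parent]
  leaves <- setdiff(leaves, tree$outgroup)
  below <- stats::setNames(vector("list", length(nodes)), nodes)
  for (l in leaves) {
    w <- l
    repeat {
      below[[w]] <- c(below[[w]], l)
      w <- tree$parent[[w]]
      if (is.na(w)) break
    }
  }
  below
}

# minimal Dollo events for one carrier set by enumerating every possible
# gain edge and every subset of loss edges beneath it (subset ORs built by
# dynamic programming over the lowest set bit)
oracle_dollo_one <- function(tree, carriers) {
  below <- oracle_leaves_below(tree)
  edges <- setdiff(names(tree$parent), c(tree$root, tree$outgroup))
  regions <- sort(unique(unlist(below[edges])))
  bit <- function(set) sum(2^(match(set, regions) - 1L))
  target <- as.integer(bit(carriers))
  best <- Inf
  for (g in edges) {
    gmask <- as.integer(bit(below[[g]]))
    if (bitwAnd(gmask, target) != target) next
    sub <- edges[vapply(edges, function(e)
      all(below[[e]] %in% below[[g]]) && e != g, logical(1))]
    k <- length(sub)
    masks <- vapply(sub, function(e) as.integer(bit(below[[e]])),
                    integer(1))
    ns <- 2L^k
    orr <- integer(ns); pc <- integer(ns)
    if (k > 0L) for (s in seq_len(ns - 1L)) {
      low <- bitwAnd(s, -s)
      idx <- as.integer(round(log2(low))) + 1L
      rest <- s - low
      orr[s + 1L] <- bitwOr(orr[rest + 1L], masks[idx])
      pc[s + 1L] <- pc[rest + 1L] + 1L
    }
    ok <- bitwAnd(gmask, bitwNot(orr)) == target
    if (any(ok)) best <- min(best, 1L + min(pc[ok]))
  }
  best
}

oracle_dollo_score <- function(tree, rm) {
  sum(vapply(rm$mutation_ids, function(m) {
    oracle_dollo_one(tree, rm$region_ids[rm$presence[, m] == 1L])
  }, numeric(1)))
}

# all rooted binary topologies over the regions, via phangorn, each wrapped
# with a trunk and a "normal" outgroup like the package's trees
oracle_all_topologies <- function(regions) {
  phys <- phangorn::allTrees(length(regions), rooted = TRUE,
                             tip.label = regions)
  lapply(phys, function(phy) {
    ntip <- length(phy$tip.label)
    labs <- c(phy$tip.label, paste0("O", seq_len(phy$Nnode)))
    parent <- stats::setNames(rep(NA_character_, length(labs)), labs)
    for (i in seq_len(nrow(phy$edge)))
      parent[labs[phy$edge[i, 2]]] <- labs[phy$edge[i, 1]]
    clade_root <- labs[ntip + 1L]
    parent[clade_root] <- "root"
    parent <- c(root = NA_character_, normal = "root", parent)
    lens <- stats::setNames(rep(0, length(parent) - 1L),
                            setdiff(names(parent), "root"))
    evo_tree(parent, lengths = lens, outgroup = "normal")
  })
}

# ---- misc oracles ------------------------------------------------------

# two-sided Fisher p by direct hypergeometric tail enumeration
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# per-basepair CNA ITH on a toy genome (0-based half-open segments)
oracle_cna_ith <- function(segments, n_regions, genome_length = 10000L) {
  alt <- segments[segments$cn_state != 2L, , drop = FALSE]
  if (!nrow(alt)) return(0)
  regions <- paste0("R", seq_len(n_regions))
  count <- matrix(FALSE, genome_length, n_regions,
                  dimnames = list(NULL, regions))
  for (i in seq_len(nrow(alt))) {
    pos <- (alt$start[i] + 1L):alt$end[i]
    count[pos, alt$region_id[i]] <- TRUE
  }
  per_bp <- rowSums(count)
  any_bp <- sum(per_bp > 0)
  all_bp <- sum(per_bp == n_regions)
  if (any_bp == 0) return(0)
  (any_bp - all_bp) / any_bp
}

# textbook two-group log-rank statistic (observed minus expected)
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2L)
  g1 <- sort(unique(group))[1]
  U <- 0; V <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & group == g1)
    dj <- sum(time == t & event)
    d1j <- sum(time == t & event & group == g1)
    U <- U + d1j - n1j * dj / nj
    if (nj > 1)
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  U^2 / V
}
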