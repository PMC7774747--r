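#' Timing pairs of driver mutations on a phylogeny
#'
#' Orders pairs of driver mutations by their position on the tree. Trunk
#' (ubiquitous, A) mutations precede everything; shared (B) mutations
#' precede private (C) mutations. A pair is emitted when the two locations
#' differ in the A < B < C hierarchy, with one phylogenetic restriction: a
#' B -> C pair is only emitted when the shared mutation's edge is ancestral
#' to the private mutation's edge (shared and private mutations on disjoint
#' branches are not temporally ordered by the tree). A -> B and A -> C pairs
#' always hold because the trunk is ancestral to every branch.
#'
#' @param tree An `evo_tree` with mutations assigned to edges (see
#'   [assign_mutations_to_edges()]).
#' @param locations `data.frame` from [classify_locations()].
#' @param drivers Character vector of driver mutation ids, or a named
#'   logical vector over mutation ids (as in `region_matrix$drivers`).
#' @param genes Optional named character vector mapping mutation id to gene
#'   symbol (`region_matrix$genes`); defaults to the text before the first
#'   `":"` of the mutation id.
#' @param patient_id Patient id stamped on the output rows.
#' @return `data.frame` with columns `patient_id`, `earlier_mutation`,
#'   `later_mutation`, `earlier_gene`, `later_gene`, `relation` (one of
#'   `"A->B"`, `"A->C"`, `"B->C"`).
#' @export
timing_pairs <- function(tree, locations, drivers, genes = NULL,
                         patient_id = NA_character_) {
  stopifnot(inherits(tree, "evo_tree"))
  if (is.logical(drivers)) drivers <- names(drivers)[drivers]
  drv <- intersect(drivers, locations$mutation_id)
  empty <- data.frame(patient_id = character(), earlier_mutation = character(),
                      later_mutation = character(), earlier_gene = character(),
                      later_gene = character(), relation = character())
  if (length(drv) < 2L) return(empty)
  loc <- stats::setNames(locations$location, locations$mutation_id)
  rank <- c(A_ubiquitous = 1L, B_shared = 2L, C_private = 3L)
  edge_of <- mutation_edges(tree)
  anc <- edge_ancestry(tree)
  if (is.null(genes))
    genes <- stats::setNames(sub(":.*$", "", drv), drv)

  rows <- list()
  for (i in seq_along(drv)) for (j in seq_along(drv)) {
    if (i == j) next
    m1 <- drv[i]; m2 <- drv[j]
    r1 <- rank[[loc[[m1]]]]; r2 <- rank[[loc[[m2]]]]
    if (r1 >= r2) next
    if (r1 == 2L && r2 == 3L) {  # B -> C needs edge ancestry
      e1 <- edge_of[[m1]]; e2 <- edge_of[[m2]]
      if (is.na(e1) || is.na(e2)) next
      if (!(e1 %in% anc[[e2]]) || e1 == e2) next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = patient_id, earlier_mutation = m1, later_mutation = m2,
      earlier_gene = unname(genes[[m1]]), later_gene = unname(genes[[m2]]),
      relation = paste0(substr(loc[[m1]], 1, 1), "->", substr(loc[[m2]], 1, 1)))
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# edge (child-node id) carrying each mutation; NA when unassigned
mutation_edges <- function(tree) {
  out <- character(0)
  for (v in names(tree$mutations))
    for (m in tree$mutations[[v]]) out[m] <- v
  out
}

# for each edge (child id): the set of edges on the path root -> that edge,
# inclusive
edge_ancestry <- function(tree) {
  kids <- setdiff(names(tree$parent), tree$root)
  anc <- stats::setNames(vector("list", length(kids)), kids)
  for (v in kids) {
    path <- character(0)
    w <- v
    while (!is.na(tree$parent[[w]])) { path <- c(path, w); w <- tree$parent[[w]] }
    anc[[v]] <- path
  }
  anc
}

#' Early driver feature (EDF) genes across a cohort
#'
#' A driver gene is *early* in a patient when one of its mutations sits at
#' the trunk (location A), or at a shared branch (B) with another driver
#' mutation downstream of it on the same root-to-leaf path (i.e. it appears
#' as the earlier member of a B -> C timing pair). A gene qualifies as an
#' EDF gene when it is early in at least `min_patients` patients. When
#' subtype labels are supplied, per-subtype early-carrier counts are
#' attached and the gene is assigned to a subtype that holds at least
#' `specificity` of its early carriers.
#'
#' @param early_by_patient `data.frame` with columns `patient_id`, `gene`
#'   listing per-patient early driver genes; build it with
#'   [early_driver_calls()].
#' @param min_patients Minimum early-carrier count (default 3).
#' @param subtypes Optional named vector of subtype labels by patient id.
#' @param specificity Fraction of early carriers required for subtype
#'   assignment (default 0.7).
#' @return `data.frame` with `gene`, `n_patients_early`, per-subtype counts
#'   (columns `subtype_<label>`), and `assigned_subtype` (`"none"` when no
#'   subtype reaches `specificity`).
#' @export
edf_genes <- function(early_by_patient, min_patients = 3, subtypes = NULL,
                      specificity = 0.7) {
  stopifnot(all(c("patient_id", "gene") %in% names(early_by_patient)))
  e <- unique(early_by_patient[c("patient_id", "gene")])
  counts <- table(e$gene)
  keep <- names(counts)[counts >= min_patients]
  out <- data.frame(gene = keep,
                    n_patients_early = as.integer(counts[keep]))
  out <- out[order(-out$n_patients_early, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(subtypes)) {
    labs <- sort(unique(subtypes))
    for (l in labs) out[[paste0("subtype_", l)]] <- 0L
    out$assigned_subtype <- "none"
    for (i in seq_len(nrow(out))) {
      carriers <- e$patient_id[e$gene == out$gene[i]]
      st <- subtypes[carriers]
      st <- st[!is.na(st)]
      for (l in labs)
        out[[paste0("subtype_", l)]][i] <- sum(st == l)
      if (length(st)) {
        frac <- table(factor(st, levels = labs)) / length(st)
        top <- names(frac)[which.max(frac)]
        if (max(frac) >= specificity) out$assigned_subtype[i] <- top
      }
    }
  }
  out
}

#' Per-patient early driver gene calls
#'
#' Flags, for one patient, the driver genes with an early mutation: any
#' driver mutation at the trunk (A), or at a shared branch (B) appearing as
#' the earlier member of a B -> C timing pair.
#'
#' @inheritParams timing_pairs
#' @return `data.frame` with columns `patient_id`, `gene`.
#' @export
early_driver_calls <- function(tree, locations, drivers, genes = NULL,
                               patient_id = NA_character_) {
  if (is.logical(drivers)) drivers <- names(drivers)[drivers]
  drv <- intersect(drivers, locations$mutation_id)
  if (is.null(genes))
    genes <- stats::setNames(sub(":.*$", "", drv), drv)
  loc <- stats::setNames(locations$location, locations$mutation_id)
  early_mut <- drv[loc[drv] == "A_ubiquitous"]
  tp <- timing_pairs(tree, locations, drv, genes = genes,
                     patient_id = patient_id)
  early_mut <- union(early_mut,
                     tp$earlier_mutation[tp$relation == "B->C"])
  g <- unique(unname(genes[early_mut]))
  data.frame(patient_id = rep(patient_id, length(g)), gene = g)
}

#' Bradley-Terry win matrix from cohort timing pairs
#'
#' Aggregates timing pairs across patients into a gene-by-gene win matrix:
#' `wins[i, j]` counts how often gene i's mutation preceded gene j's on a
#' patient tree. Pairs within the same gene are dropped. Optionally, when
#' two driver mutations of different genes share one edge (and are therefore
#' not ordered by tree position), the one with the higher mean CCF across
#' regions is credited as earlier.
#'
#' @param pairs `data.frame` of timing pairs (rows from [timing_pairs()],
#'   possibly many patients).
#' @param same_edge_ccf Optional `data.frame` with columns `earlier_gene`,
#'   `later_gene` of CCF-resolved same-edge pairs, as produced by
#'   [same_edge_ccf_pairs()]; appended as additional wins.
#' @return Square numeric matrix of win counts with gene dimnames.
#' @export
bt_wins <- function(pairs, same_edge_ccf = NULL) {
  p <- pairs[pairs$earlier_gene != pairs$later_gene,
             c("earlier_gene", "later_gene")]
  if (!is.null(same_edge_ccf))
    p <- rbind(p, same_edge_ccf[c("earlier_gene", "later_gene")])
  genes <- sort(unique(c(p$earlier_gene, p$later_gene)))
  w <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (i in seq_len(nrow(p)))
    w[p$earlier_gene[i], p$later_gene[i]] <-
      w[p$earlier_gene[i], p$later_gene[i]] + 1
  w
}

#' CCF-resolved ordering of same-edge driver pairs
#'
#' Driver mutations sharing one tree edge are topologically unordered; when
#' per-region CCFs are available the mutation with the higher mean CCF is
#' deemed earlier (a higher cancer cell fraction indicates an older
#' mutation). Pairs whose mean CCFs are missing or tied are skipped.
#'
#' @param tree An `evo_tree` with mutations assigned to edges.
#' @param matrix The patient's `region_matrix` (for `ccf`, `drivers`,
#'   `genes`).
#' @return `data.frame` with columns `earlier_gene`, `later_gene`.
#' @export
same_edge_ccf_pairs <- function(tree, matrix) {
  stopifnot(inherits(matrix, "region_matrix"))
  drv <- names(matrix$drivers)[matrix$drivers]
  out <- data.frame(earlier_gene = character(), later_gene = character())
  if (length(drv) < 2L) return(out)
  edge_of <- mutation_edges(tree)
  mean_ccf <- colMeans(matrix$ccf, na.rm = TRUE)
  for (e in unique(edge_of[drv])) {
    ms <- drv[edge_of[drv] == e]
    if (length(ms) < 2L) next
    for (i in seq_along(ms)) for (j in seq_along(ms)) {
      if (i == j) next
      gi <- matrix$genes[[ms[i]]]; gj <- matrix$genes[[ms[j]]]
      if (gi == gj) next
      ci <- mean_ccf[[ms[i]]]; cj <- mean_ccf[[ms[j]]]
      if (is.na(ci) || is.na(cj) || ci <= cj) next
      out <- rbind(out, data.frame(earlier_gene = gi, later_gene = gj))
    }
  }
  out
}

#' Bradley-Terry temporal ordering of driver genes
#'
#' Fits the Bradley-Terry model to a win matrix of pairwise temporal
#' precedences by the standard minorization-maximization (MM) iteration:
#' each gene receives a positive ability score, and
#' `P(i precedes j) = ability_i / (ability_i + ability_j)`. Higher ability
#' means earlier in tumor evolution. For regularization, `pseudo` wins are
#' added in both directions for every gene pair that was compared at least
#' once, keeping abilities finite for undefeated genes. Genes with no
#' comparisons at all are excluded with a message. Abilities are normalized
#' to sum to 1; the MM log-likelihood is non-decreasing over iterations.
#'
#' @param wins Square numeric win matrix (dimnames are gene names), e.g.
#'   from [bt_wins()].
#' @param pseudo Pseudo-win added both ways per compared pair (default 0.5;
#'   0 gives the raw maximum-likelihood fit).
#' @param tol Relative convergence tolerance on abilities (default 1e-8).
#' @param max_iter Iteration cap (default 10000).
#' @return An object of class `bt_ordering`: list with `genes`, `ability`
#'   (named, positive, sums to 1), `ranking` (genes, earliest first),
#'   `logLik` trace, and `converged`.
#' @examples
#' w <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE,
#'             dimnames = list(c("TP53", "KRAS"), c("TP53", "KRAS")))
#' fit <- bradley_terry(w, pseudo = 0)
#' fit$ability["TP53"] / fit$ability["KRAS"]  # 3
#' @export
bradley_terry <- function(wins, pseudo = 0.5, tol = 1e-8, max_iter = 10000) {
  stopifnot(is.matrix(wins), nrow(wins) == ncol(wins))
  genes <- rownames(wins)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(wins)))
  dimnames(wins) <- list(genes, genes)
  compared <- wins + t(wins) > 0
  diag(compared) <- FALSE
  no_comp <- rowSums(compared) == 0
  if (any(no_comp)) {
    message("excluding gene(s) with no comparisons: ",
            paste(genes[no_comp], collapse = ", "))
    wins <- wins[!no_comp, !no_comp, drop = FALSE]
    genes <- genes[!no_comp]
    compared <- compared[!no_comp, !no_comp, drop = FALSE]
  }
  k <- length(genes)
  if (k < 2L) stop("need at least two genes with comparisons")
  w <- wins + pseudo * compared
  n <- w + t(w)                       # comparisons per pair
  W <- rowSums(w)                     # total wins per gene
  p <- rep(1 / k, k)
  ll <- function(p) {
    pm <- outer(p, p, "+")
    sum(w[n > 0] * log(outer(p, p, function(a, b) a)[n > 0] / pm[n > 0]))
  }
  trace <- ll(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- rowSums(n / outer(p, p, "+") * compared)
    p_new <- W / denom
    p_new <- p_new / sum(p_new)
    delta <- max(abs(p_new - p) / pmax(p, .Machine$double.eps))
    p <- p_new
    trace <- c(trace, ll(p))
    if (delta < tol) { converged <- TRUE; break }
  }
  names(p) <- genes
  structure(
    list(genes = genes, ability = p,
         ranking = genes[order(-p)],
         logLik = trace, converged = converged),
    class = "bt_ordering"
  )
}

#' @export
print.bt_ordering <- function(x, ...) {
  cat("<bt_ordering> ", length(x$genes), " genes",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(round(sort(x$ability, decreasing = TRUE), 4))
  invisible(x)
}
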