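#' Tree-to-tree distance matrix
#'
#' Euclidean distance between the standardized edge-length vectors of every
#' pair of patients. (The squared form `(zi - zj)'(zi - zj)` is a monotone
#' transform of this distance; clustering cuts under single, complete or
#' average linkage are identical either way, and the unsquared form is the
#' Euclidean distance proper.)
#'
#' @param vectors Numeric matrix of standardized vectors, one row per
#'   patient, as returned by [cohort_vectors()].
#' @return A symmetric matrix of distances with zero diagonal.
#' @export
distance_matrix <- function(vectors) {
  stopifnot(is.matrix(vectors))
  d <- as.matrix(stats::dist(vectors, method = "euclidean"))
  dimnames(d) <- list(rownames(vectors), rownames(vectors))
  d
}

#' Cluster patients into evolutionary subtypes
#'
#' Agglomerative hierarchical clustering on a precomputed tree-to-tree
#' distance matrix. For every candidate number of subtypes k the dendrogram
#' is cut and the average silhouette coefficient computed from the same
#' distances; the chosen k maximizes the average silhouette (smallest k wins
#' ties). The silhouette of patient i is
#' `(b(i) - a(i)) / max(a(i), b(i))`, with `a(i)` the mean distance to the
#' other members of its cluster and `b(i)` the smallest mean distance to any
#' other cluster; singletons score 0. k = 1 is excluded from the scan: the
#' silhouette is undefined without a second cluster.
#'
#' @param distances Symmetric distance matrix from [distance_matrix()].
#' @param k_range Candidate cluster counts (default 2..10); values exceeding
#'   the number of patients are skipped with a message.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An object of class `subtype_assignment`: list with `patient_ids`,
#'   `labels` (subtype per patient for the chosen k), `silhouette_by_k`
#'   (named numeric), `chosen_k`, `linkage`, and the `hclust` object.
#' @export
cluster_trees <- function(distances, k_range = 2:10, linkage = "complete") {
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances))
  n <- nrow(distances)
  if (n < 3L) stop("need at least 3 patients to cluster")
  ids <- rownames(distances)
  if (is.null(ids)) ids <- paste0("P", seq_len(n))
  hc <- stats::hclust(stats::as.dist(distances), method = linkage)
  ks <- sort(unique(as.integer(k_range)))
  if (any(ks < 2L)) stop("k_range must start at 2 or above")
  drop_k <- ks[ks > n]
  if (length(drop_k)) {
    message("skipping k > n patients: ", paste(drop_k, collapse = ", "))
    ks <- ks[ks <= n]
  }
  sil <- stats::setNames(rep(NA_real_, length(ks)), ks)
  cuts <- list()
  for (i in seq_along(ks)) {
    lab <- stats::cutree(hc, k = ks[i])
    cuts[[i]] <- lab
    sil[i] <- mean(silhouette_widths(distances, lab))
  }
  best <- which.max(sil)
  structure(
    list(patient_ids = ids,
         labels = stats::setNames(unname(cuts[[best]]), ids),
         silhouette_by_k = sil,
         chosen_k = ks[best],
         linkage = linkage,
         hclust = hc),
    class = "subtype_assignment"
  )
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat("<subtype_assignment> ", length(x$patient_ids), " patients, k = ",
      x$chosen_k, " (", x$linkage, " linkage)\n", sep = "")
  print(table(subtype = x$labels))
  cat("average silhouette by k:\n")
  print(round(x$silhouette_by_k, 3))
  invisible(x)
}

#' Per-patient silhouette widths
#'
#' @param distances Symmetric distance matrix.
#' @param labels Integer cluster label per patient.
#' @return Numeric vector of silhouette widths in \[-1, 1\].
#' @export
silhouette_widths <- function(distances, labels) {
  n <- length(labels)
  stopifnot(nrow(distances) == n)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- own[own != i]
    if (!length(own)) { s[i] <- 0; next }   # singleton cluster
    a <- mean(distances[i, own])
    b <- Inf
    for (g in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(distances[i, labels == g]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Project trees into two dimensions by SVD
#'
#' Rank-2 singular value decomposition of the column-centered vector matrix;
#' the scores place every patient's phylogeny in a 2D Euclidean space for
#' display, with tighter subtypes appearing as more compact point clouds.
#'
#' @param vectors Standardized vector matrix from [cohort_vectors()].
#' @return Numeric matrix (patients x 2) of projection coordinates.
#' @export
project_2d <- function(vectors) {
  stopifnot(is.matrix(vectors), nrow(vectors) >= 2L)
  x <- scale(vectors, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = 2, nv = 0)
  out <- sv$u %*% diag(sv$d[1:2], 2, 2)
  rownames(out) <- rownames(vectors)
  colnames(out) <- c("dim1", "dim2")
  out
}
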