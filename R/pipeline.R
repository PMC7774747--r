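#' End-to-end evolutionary subtyping pipeline
#'
#' Runs the full analysis on a cohort mutation table: per patient, builds
#' the binary presence matrix (VAF threshold), reconstructs the Dollo
#' parsimony tree with the normal outgroup, and classifies mutation
#' locations; then encodes all trees as standardized edge-length vectors on
#' a shared reference tree, computes the Euclidean distance matrix, and
#' clusters patients into evolutionary subtypes with silhouette-selected k.
#'
#' Patients with fewer than two regions after thresholding are skipped with
#' a message (the method is multi-region by construction).
#'
#' @param calls Cohort mutation calls (see [read_mutation_table()]).
#' @param vaf_threshold Presence threshold on VAF (default 0.1).
#' @param k_range Candidate subtype counts (default 2..10).
#' @param linkage Hierarchical clustering linkage (default `"complete"`).
#' @param search Tree search mode passed to [dollo_tree()].
#' @return List of class `evo_pipeline`: `matrices`, `trees`, `locations`
#'   (named lists by patient), `vectors` (matrix), `distances` (matrix),
#'   and `assignment` (a `subtype_assignment`).
#' @export
evo_subtype_pipeline <- function(calls, vaf_threshold = 0.1,
                                 k_range = 2:10, linkage = "complete",
                                 search = "auto") {
  pids <- unique(calls$patient_id)
  matrices <- list(); trees <- list(); locations <- list()
  for (p in pids) {
    pc <- calls[calls$patient_id == p, , drop = FALSE]
    m <- tryCatch(build_presence_matrix(pc, vaf_threshold = vaf_threshold),
                  error = function(e) {
                    message("skipping ", p, ": ", conditionMessage(e))
                    NULL
                  })
    if (is.null(m) || length(m$mutation_ids) == 0L) next
    matrices[[p]] <- m
    trees[[p]] <- dollo_tree(m, search = search)
    locations[[p]] <- classify_locations(m)
  }
  if (length(trees) < 3L) stop("fewer than 3 usable patients")
  vectors <- cohort_vectors(trees)
  distances <- distance_matrix(vectors)
  assignment <- cluster_trees(distances, k_range = k_range,
                              linkage = linkage)
  structure(
    list(matrices = matrices, trees = trees, locations = locations,
         vectors = vectors, distances = distances,
         assignment = assignment),
    class = "evo_pipeline"
  )
}

#' @export
print.evo_pipeline <- function(x, ...) {
  cat("<evo_pipeline> ", length(x$trees), " patients, reference depth ",
      attr(x$vectors, "depth"), "\n", sep = "")
  print(x$assignment)
  invisible(x)
}
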