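#' Branched diversity of a patient's mutations
#'
#' The ratio `(#private + #shared) / #ubiquitous`: how much of the mutation
#' burden sits on branches rather than on the trunk. Patients whose tumors
#' diversified after a short common history score high; tumors that
#' accumulated most mutations before regional divergence score near 0. When
#' the patient has no ubiquitous mutations the ratio is undefined and `NA`
#' is returned with a message (no pseudocount is invented).
#'
#' @param locations `data.frame` from [classify_locations()].
#' @return A single ratio, or `NA_real_` when there are no ubiquitous
#'   mutations.
#' @export
branched_diversity <- function(locations) {
  if (!nrow(locations)) stop("no mutations; branched diversity undefined")
  n_u <- sum(locations$location == "A_ubiquitous")
  n_bs <- sum(locations$location %in% c("B_shared", "C_private"))
  if (n_u == 0L) {
    message("no ubiquitous mutations; branched diversity is NA")
    return(NA_real_)
  }
  n_bs / n_u
}

#' Intra-tumor heterogeneity (ITH) index
#'
#' The ratio of subclonal to clonal mutation counts for one patient. When
#' the calls carry clonality labels (e.g. from an upstream subclonal
#' deconvolution) those are used directly. Otherwise a transparent fallback
#' derives clonality from the data: a mutation is clonal iff it is present
#' in every region (VAF at or above `vaf_threshold`) and its minimum
#' per-region CCF is at least `ccf_clonal_threshold`; all other mutations
#' are subclonal.
#'
#' @param calls Mutation calls for one patient.
#' @param ccf_clonal_threshold Minimum per-region CCF for the fallback
#'   clonal call (default 0.9).
#' @param vaf_threshold Presence threshold used by the fallback (default
#'   0.1).
#' @return `#subclonal / #clonal`, or `NA_real_` (with a message) when there
#'   are no clonal mutations.
#' @export
ith_index <- function(calls, ccf_clonal_threshold = 0.9, vaf_threshold = 0.1) {
  if (length(unique(calls$patient_id)) != 1L)
    stop("calls must come from exactly one patient")
  mut_id <- ifelse(nzchar(calls$protein_change),
                   paste0(calls$gene, ":", calls$protein_change), calls$gene)
  have_labels <- !all(is.na(calls$clonality))
  if (have_labels) {
    lab <- tapply(calls$clonality, mut_id, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) NA_character_ else x[[1]]
    })
    lab <- lab[!is.na(lab)]
  } else {
    if (all(is.na(calls$ccf)))
      stop("neither clonality labels nor CCF available")
    m <- build_presence_matrix(calls, vaf_threshold = vaf_threshold)
    ubiq <- colSums(m$presence) == length(m$region_ids)
    min_ccf <- apply(m$ccf, 2L, function(x) {
      if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
    })
    clonal <- ubiq & !is.na(min_ccf) & min_ccf >= ccf_clonal_threshold
    lab <- ifelse(clonal, "clonal", "subclonal")
    names(lab) <- m$mutation_ids
  }
  n_clonal <- sum(lab == "clonal")
  n_sub <- sum(lab == "subclonal")
  if (n_clonal == 0L) {
    message("no clonal mutations; ITH index is NA")
    return(NA_real_)
  }
  n_sub / n_clonal
}

#' Copy-number alteration ITH
#'
#' The fraction of the altered genome that is subclonally altered: base
#' pairs copy-number altered in some but not all regions, divided by base
#' pairs altered in any region. Computed by exact interval arithmetic
#' (union across regions vs. intersection across all `n_regions` regions),
#' per chromosome, on 0-based half-open segments. Segments with
#' `cn_state == 2` are treated as unaltered. Returns 0 when no base pair is
#' altered anywhere.
#'
#' @param segments CNA segments for one patient (see [read_cna_table()]).
#' @param n_regions Number of regions sampled for the patient; regions with
#'   no altered segment still count against the "altered in all regions"
#'   intersection.
#' @return Fraction in \[0, 1\].
#' @export
cna_ith <- function(segments, n_regions) {
  stopifnot(n_regions >= 1L)
  if (length(unique(segments$patient_id)) > 1L)
    stop("segments must come from exactly one patient")
  check_conflicting_overlaps(segments)
  alt <- segments[segments$cn_state != 2L, , drop = FALSE]
  if (!nrow(alt)) return(0)
  regions <- unique(alt$region_id)
  any_bp <- 0; all_bp <- 0
  for (chr in unique(alt$chrom)) {
    per_region <- lapply(regions, function(r) {
      s <- alt[alt$region_id == r & alt$chrom == chr, , drop = FALSE]
      IRanges::reduce(IRanges::IRanges(start = s$start + 1L, end = s$end))
    })
    union_r <- IRanges::reduce(do.call(c, per_region))
    any_bp <- any_bp + sum(IRanges::width(union_r))
    if (length(regions) == n_regions) {
      inter <- per_region[[1]]
      for (r in per_region[-1]) inter <- IRanges::intersect(inter, r)
      all_bp <- all_bp + sum(IRanges::width(inter))
    }
    # else: some region has no altered bp on any chromosome -> the
    # all-region intersection is empty by definition
  }
  if (any_bp == 0) return(0)
  (any_bp - all_bp) / any_bp
}

check_conflicting_overlaps <- function(segments) {
  key <- paste(segments$region_id, segments$chrom)
  for (k in unique(key)) {
    s <- segments[key == k, , drop = FALSE]
    if (nrow(s) < 2L) next
    ir <- IRanges::IRanges(start = s$start + 1L, end = s$end)
    ov <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    bad <- qh < sh & s$cn_state[qh] != s$cn_state[sh]
    if (any(bad))
      stop("overlapping segments with conflicting copy-number states in ",
           k)
  }
  invisible(segments)
}

#' Subclonal diversity curve and its AUC
#'
#' Characterizes how mutations accumulate along a patient's phylogeny. The
#' x axis is the fraction of accumulated mutations, subdivided into steps of
#' `step` and normalized to 0--1. For each grid fraction f, y(f) is the
#' proportion of non-root tree nodes whose distance from the root (the
#' cumulative mutation count along the path, normalized by the total tree
#' mutation count) is strictly less than f. The area under this curve
#' (trapezoid rule) summarizes subclonal diversity: trees whose nodes sit
#' close to the root -- many subclones diverging early -- have larger AUC.
#' The outgroup leaf, if present, is not counted (it is not a tumor
#' subclone). The curve is invariant to uniform scaling of edge lengths.
#'
#' @param tree An `evo_tree` with at least one mutation.
#' @param step Grid step on the accumulated-mutation axis (default 0.01).
#' @return List with `fraction` (grid), `proportion` (y values), and `auc`.
#' @export
subclonal_diversity_curve <- function(tree, step = 0.01) {
  stopifnot(inherits(tree, "evo_tree"))
  tot <- tree_total_length(tree)
  if (tot == 0) stop("tree has zero total mutations")
  d <- tree_root_distances(tree)
  keep <- setdiff(names(d), c(tree$root,
                              if (is.na(tree$outgroup)) character()
                              else tree$outgroup))
  if (!length(keep)) stop("tree has no non-root nodes")
  nd <- d[keep] / tot
  f <- seq(0, 1, by = step)
  y <- vapply(f, function(fi) mean(nd < fi), numeric(1))
  auc <- sum((y[-1] + y[-length(y)]) / 2 * diff(f))
  list(fraction = f, proportion = y, auc = auc)
}

#' Corrected tumor size
#'
#' Adjusts a tumor's size for the number of regions sampled, approximating
#' the tumor mass as a sphere: dividing the volume equally among the `ss`
#' sampled regions divides the diameter by the cube root of `ss`, giving
#' `ts / ss^(1/3)`. With one sample the size is unchanged, and the
#' correction is strictly decreasing in the sample count. Any constant
#' factor cancels in between-group comparisons.
#'
#' @param ts Tumor size in mm (> 0).
#' @param ss Number of samples (>= 1).
#' @return Corrected size in mm.
#' @export
corrected_tumor_size <- function(ts, ss) {
  if (any(ts <= 0)) stop("tumor size must be positive")
  if (any(ss < 1)) stop("sample size must be >= 1")
  ts / ss^(1 / 3)
}

#' Per-patient heterogeneity profile
#'
#' Convenience wrapper assembling [branched_diversity()], [ith_index()],
#' [cna_ith()], [subclonal_diversity_curve()] and [corrected_tumor_size()]
#' into one row per patient.
#'
#' @param calls Mutation calls (may span patients).
#' @param trees Named list of `evo_tree` per patient.
#' @param segments Optional CNA segments (may span patients).
#' @param clinical Optional clinical table (for tumor size and region
#'   counts).
#' @param vaf_threshold Presence threshold (default 0.1).
#' @return `data.frame` with one row per patient.
#' @export
heterogeneity_profile <- function(calls, trees, segments = NULL,
                                  clinical = NULL, vaf_threshold = 0.1) {
  pids <- names(trees)
  out <- data.frame(patient_id = pids, branched_diversity = NA_real_,
                    ith_index = NA_real_, cna_ith = NA_real_,
                    subclonal_diversity_auc = NA_real_,
                    corrected_tumor_size = NA_real_)
  for (i in seq_along(pids)) {
    pc <- calls[calls$patient_id == pids[i], , drop = FALSE]
    m <- build_presence_matrix(pc, vaf_threshold = vaf_threshold)
    out$branched_diversity[i] <-
      suppressMessages(branched_diversity(classify_locations(m)))
    out$ith_index[i] <- suppressMessages(ith_index(pc,
                                                   vaf_threshold = vaf_threshold))
    out$subclonal_diversity_auc[i] <-
      subclonal_diversity_curve(trees[[pids[i]]])$auc
    if (!is.null(segments)) {
      ps <- segments[segments$patient_id == pids[i], , drop = FALSE]
      out$cna_ith[i] <- cna_ith(ps, n_regions = length(m$region_ids))
    }
    if (!is.null(clinical)) {
      cr <- clinical[clinical$patient_id == pids[i], , drop = FALSE]
      if (nrow(cr) == 1L && !is.na(cr$tumor_size))
        out$corrected_tumor_size[i] <-
          corrected_tumor_size(cr$tumor_size, cr$n_regions_sampled)
    }
  }
  out
}
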