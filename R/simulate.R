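#' Configuration for the synthetic multi-region cohort generator
#'
#' Bundles the generative model parameters for [simulate_cohort()]. The
#' three archetypes emulate the branch-length profiles of the three
#' evolutionary subtypes: archetype 1 has a short trunk with branch lengths
#' comparable to it (branched evolution, high heterogeneity); archetype 2
#' has a long trunk and short branches (early accumulation of variation,
#' trunk fraction 0.75); archetype 3 has a short trunk with long,
#' asymmetric shared branches (subclonal replacement). Profiles are the
#' expected fraction of a patient's mutations on trunk / shared / private
#' edges; per-patient fractions are drawn from a Dirichlet centered on the
#' profile.
#'
#' @param n_patients Named integer vector: patients per archetype.
#' @param regions_range Min/max tumor regions per patient (default 2--8).
#' @param region_count_probs Sampling weights for the region counts in
#'   `regions_range`; the default decreasing weights mimic multi-region
#'   cohorts, where most tumors are sampled at 2--4 regions and few at 7--8.
#' @param mutations_range Min/max non-synonymous mutations per patient.
#' @param profiles List of trunk/shared/private fraction triplets per
#'   archetype.
#' @param profile_concentration Dirichlet concentration around the profile;
#'   larger values give tighter, better-separated archetypes.
#' @param shared_size_power Per-archetype exponent weighting shared
#'   (internal) edges by the number of regions they subtend: mutations
#'   accumulate along a lineage over time, so edges ancestral to more
#'   regions are older and longer. A high exponent (archetype 3)
#'   concentrates mass on one long shared branch near the trunk, giving
#'   the asymmetric branching of that archetype.
#' @param within_concentration Dirichlet concentration for the noise around
#'   the size-weighted within-category split.
#' @param private_alpha Per-pendant Dirichlet parameter for splitting
#'   private mass across regions: large values (archetype 1) give branches
#'   of similar length, small values (archetype 3) give the strongly
#'   asymmetric branch lengths of that archetype.
#' @param topology_shape Region topology sampler per archetype:
#'   `"balanced"` (divergent coexisting lineages: random joins preferring
#'   the smallest clades, archetype 1), `"caterpillar"` (sequential
#'   subclonal replacement: a chain of nested clades, archetype 3), or
#'   `"random"` (uniform random joins).
#' @param drivers Driver gene lists per archetype.
#' @param driver_placement Trunk/shared/private placement probabilities for
#'   driver mutations per archetype.
#' @param n_drivers_range Min/max driver mutations per patient.
#' @param vaf_shape Beta shape parameters for carrier VAFs (mean 0.4).
#' @param vaf_threshold Detection threshold used downstream (default 0.1).
#' @param dropout_rate Probability that a true presence is observed below
#'   the detection threshold.
#' @param background_rate Probability that a non-carrier region reports a
#'   sub-threshold noise VAF.
#' @param ccf_clonal_range,ccf_subclonal_range Uniform CCF ranges for
#'   clonal (trunk) and subclonal mutations.
#' @param cna_segments_range Min/max copy-number segments per patient.
#' @param cna_subclonal_frac Fraction of CNA segments that are subclonal,
#'   per archetype.
#' @param median_dfs Baseline median disease-free survival in days.
#' @param hazard_multiplier Per-archetype hazard multiplier (archetype 1
#'   progresses fastest).
#' @param censor_time Administrative censoring time in days.
#' @param tumor_size_meanlog,tumor_size_sdlog Log-normal tumor size (mm)
#'   parameters per archetype.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    n_patients = c(arch1 = 20L, arch2 = 20L, arch3 = 20L),
    regions_range = c(2L, 8L),
    region_count_probs = c(0.04, 0.18, 0.30, 0.24, 0.14, 0.07, 0.03),
    mutations_range = c(50L, 150L),
    profiles = list(
      arch1 = c(trunk = 0.07, shared = 0.31, private = 0.62),
      arch2 = c(trunk = 0.75, shared = 0.10, private = 0.15),
      arch3 = c(trunk = 0.42, shared = 0.45, private = 0.13)),
    profile_concentration = 150,
    shared_size_power = c(arch1 = 0.5, arch2 = 1, arch3 = 4),
    within_concentration = c(arch1 = 50, arch2 = 50, arch3 = 50),
    private_alpha = c(arch1 = 12, arch2 = 4, arch3 = 0.6),
    topology_shape = c(arch1 = "balanced", arch2 = "random",
                       arch3 = "caterpillar"),
    drivers = list(
      arch1 = c("PIK3CA", "NOTCH1", "EGFR", "TSHR", "TP53"),
      arch2 = c("KRAS", "PTEN", "COL5A2", "CMTR2", "WT1", "WRN", "STK11",
                "FBXW7"),
      arch3 = c("NFE2L2", "KEAP1", "NIN", "ARID1A", "TSC2")),
    driver_placement = list(
      arch1 = c(trunk = 0.40, shared = 0.30, private = 0.30),
      arch2 = c(trunk = 0.85, shared = 0.10, private = 0.05),
      arch3 = c(trunk = 0.15, shared = 0.70, private = 0.15)),
    n_drivers_range = c(3L, 5L),
    vaf_shape = c(8, 12),
    vaf_threshold = 0.1,
    dropout_rate = 0.02,
    background_rate = 0.05,
    ccf_clonal_range = c(0.92, 1),
    ccf_subclonal_range = c(0.2, 0.85),
    cna_segments_range = c(8L, 12L),
    cna_subclonal_frac = c(arch1 = 0.55, arch2 = 0.10, arch3 = 0.35),
    median_dfs = 1000,
    hazard_multiplier = c(arch1 = 3, arch2 = 1, arch3 = 1.2),
    censor_time = 1825,
    tumor_size_meanlog = c(arch1 = log(45), arch2 = log(30),
                           arch3 = log(30)),
    tumor_size_sdlog = 0.3,
    seed = 1L) {
  for (p in profiles) {
    stopifnot(abs(sum(p) - 1) < 1e-8)
    if (any(p <= 0) || any(p >= 1))
      stop("profile fractions must lie strictly in (0, 1)")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-region tumor cohort with known ground truth
#'
#' Draws, for each patient: a random rooted binary region topology with a
#' normal outgroup; mutation counts allocated to edges from the archetype's
#' Dirichlet branch-length profile; per-region VAFs (Beta for carriers,
#' with configurable detection dropout and sub-threshold background noise);
#' CCFs near 1 for trunk mutations and lower for subclonal ones; driver
#' mutations from the archetype's gene list with archetype-biased edge
#' placement; non-overlapping clonal and subclonal copy-number segments;
#' and clinical records with exponential disease-free survival under the
#' archetype's hazard, administrative censoring, and archetype-shifted
#' tumor size, stage and invasion phenotypes. With two sampled regions no
#' shared (internal) edge exists, so the shared mass is folded into trunk
#' and private in proportion to their sampled fractions.
#'
#' The same configuration (including its seed) always reproduces the same
#' cohort byte for byte.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort` with elements `mutations`, `cna`,
#'   `clinical` (data frames in the [read_mutation_table()] dialects) and
#'   `truth`: per patient the archetype, the true `evo_tree`, true mutation
#'   locations and clonality, driver genes and their edge categories, and
#'   the survival parameters.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  archs <- names(config$n_patients)
  mut_rows <- list(); cna_rows <- list(); clin_rows <- list()
  truth <- list()
  pnum <- 0L
  for (a in archs) {
    for (k in seq_len(config$n_patients[[a]])) {
      pnum <- pnum + 1L
      pid <- sprintf("SIM%03d", pnum)
      sim <- simulate_patient(pid, a, config)
      mut_rows[[pid]] <- sim$mutations
      cna_rows[[pid]] <- sim$cna
      clin_rows[[pid]] <- sim$clinical
      truth[[pid]] <- sim$truth
    }
  }
  structure(
    list(mutations = do.call(rbind, c(mut_rows, make.row.names = FALSE)),
         cna = do.call(rbind, c(cna_rows, make.row.names = FALSE)),
         clinical = do.call(rbind, c(clin_rows, make.row.names = FALSE)),
         truth = truth),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", length(x$truth), " patients, ",
      nrow(x$mutations), " mutation calls\n", sep = "")
  print(table(archetype = vapply(x$truth, `[[`, "", "archetype")))
  invisible(x)
}

#' Write a simulated cohort to a directory of TSV tables
#'
#' Writes `mutations.tsv`, `cna.tsv` and `clinical.tsv` in the dialects the
#' package readers accept; reading them back reproduces the simulated
#' records exactly.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_mutation_table(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_cna_table(cohort$cna, file.path(dir, "cna.tsv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  invisible(dir)
}

## ---- internal ---------------------------------------------------------

# Rooted binary region topology with an archetype-specific shape.
# "balanced": join the two smallest clades (random tie-break) -> divergent
# coexisting lineages. "caterpillar": a chain of nested clades (leaf order
# randomized) -> sequential subclonal replacement. "random": uniform joins.
shaped_topology <- function(n, shape = c("random", "balanced",
                                         "caterpillar")) {
  shape <- match.arg(shape)
  if (n == 1L) return(1L)
  if (shape == "random") return(random_topology(n))
  ord <- sample.int(n)
  if (shape == "caterpillar") {
    t <- ord[1L]
    for (i in seq(2L, n)) t <- list(t, ord[i])
    return(t)
  }
  # balanced: repeatedly merge the two clades with the fewest leaves
  pool <- as.list(ord)
  sizes <- rep(1L, n)
  while (length(pool) > 1L) {
    o <- order(sizes + stats::runif(length(sizes)))  # random tie-break
    ij <- o[1:2]
    merged <- list(pool[[ij[1]]], pool[[ij[2]]])
    msize <- sizes[ij[1]] + sizes[ij[2]]
    pool <- c(pool[-ij], list(merged))
    sizes <- c(sizes[-ij], msize)
  }
  pool[[1]]
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

simulate_patient <- function(pid, arch, cfg) {
  counts <- seq(cfg$regions_range[1], cfg$regions_range[2])
  probs <- cfg$region_count_probs
  if (length(probs) != length(counts)) probs <- rep(1, length(counts))
  nr <- sample(counts, 1L, prob = probs)
  regions <- paste0("R", seq_len(nr))
  top <- shaped_topology(nr, cfg$topology_shape[[arch]])
  tree0 <- nested_to_tree(top, regions)
  sets <- tree_leafsets(tree0)
  sets <- lapply(sets, function(s) setdiff(s, "normal"))

  internal <- setdiff(grep("^N", names(tree0$parent), value = TRUE), "N1")
  trunk_edge <- "N1"
  pendant <- regions
  m_total <- sample(seq(cfg$mutations_range[1], cfg$mutations_range[2]), 1L)

  frac <- rdirichlet1(cfg$profile_concentration * cfg$profiles[[arch]])
  names(frac) <- names(cfg$profiles[[arch]])
  if (!length(internal)) {
    # With two regions there is no internal (shared) edge: a lineage is
    # either ancestral to both samples (trunk) or to one (branch). Long
    # shared lineages then surface as long branches, so the shared mass
    # goes to the private category.
    frac <- c(trunk = unname(frac["trunk"]), shared = 0,
              private = unname(frac["private"] + frac["shared"]))
  }
  cat_of <- sample(c("trunk", "shared", "private"), m_total, replace = TRUE,
                   prob = frac)
  conc <- cfg$within_concentration[[arch]]
  shared_w <- if (length(internal)) {
    sz <- lengths(sets[internal])  # regions subtended by each shared edge
    base <- sz^cfg$shared_size_power[[arch]]
    rdirichlet1(conc * base / sum(base))
  }
  private_w <- rdirichlet1(rep(cfg$private_alpha[[arch]], length(pendant)))
  edge_of <- character(m_total)
  for (i in seq_len(m_total)) {
    edge_of[i] <- switch(cat_of[i],
      trunk = trunk_edge,
      shared = if (length(internal))
        sample(internal, 1L, prob = shared_w) else trunk_edge,
      private = sample(pendant, 1L, prob = private_w))
  }

  # driver mutations: extra, archetype-biased placement
  n_drv <- sample(seq(cfg$n_drivers_range[1], cfg$n_drivers_range[2]), 1L)
  n_drv <- min(n_drv, length(cfg$drivers[[arch]]))
  drv_genes <- sample(cfg$drivers[[arch]], n_drv)
  pl <- cfg$driver_placement[[arch]]
  avail <- c(trunk = TRUE, shared = length(internal) > 0, private = TRUE)
  pl <- pl[avail] / sum(pl[avail])
  drv_edge <- character(n_drv)
  for (i in seq_len(n_drv)) {
    catg <- sample(names(pl), 1L, prob = pl)
    drv_edge[i] <- switch(catg,
      trunk = trunk_edge,
      shared = sample(internal, 1L, prob = shared_w),
      private = sample(pendant, 1L, prob = private_w))
  }

  genes <- c(sprintf("PSG%04d", sample.int(5000, m_total)), drv_genes)
  prot <- sprintf("p.%s%d%s", sample(LETTERS, m_total + n_drv, TRUE),
                  sample.int(999, m_total + n_drv, TRUE),
                  sample(LETTERS, m_total + n_drv, TRUE))
  edge_all <- c(edge_of, drv_edge)
  is_drv <- c(rep(FALSE, m_total), rep(TRUE, n_drv))
  mut_ids <- paste0(genes, ":", prot)

  # true tree with mutations on edges
  kids <- setdiff(names(tree0$parent), tree0$root)
  mut_list <- stats::setNames(rep(list(character()), length(kids)), kids)
  for (i in seq_along(mut_ids))
    mut_list[[edge_all[i]]] <- c(mut_list[[edge_all[i]]], mut_ids[i])
  tree <- evo_tree(tree0$parent, mutations = mut_list, outgroup = "normal")

  # true locations from carrier counts
  carriers <- sets[edge_all]
  n_carr <- lengths(carriers)
  true_loc <- ifelse(n_carr == nr, "A_ubiquitous",
                     ifelse(n_carr == 1L, "C_private", "B_shared"))
  clonality <- ifelse(edge_all == trunk_edge, "clonal", "subclonal")

  # per-region calls
  rows <- list()
  for (i in seq_along(mut_ids)) {
    carr <- carriers[[i]]
    ccf_rng <- if (clonality[i] == "clonal") cfg$ccf_clonal_range
               else cfg$ccf_subclonal_range
    for (r in regions) {
      if (r %in% carr) {
        vaf <- if (stats::runif(1) < cfg$dropout_rate)
          stats::runif(1, 0.01, cfg$vaf_threshold - 0.01)
        else stats::rbeta(1, cfg$vaf_shape[1], cfg$vaf_shape[2])
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, region_id = r, gene = genes[i],
          protein_change = prot[i], vaf = round(vaf, 4),
          ccf = round(stats::runif(1, ccf_rng[1], ccf_rng[2]), 4),
          is_driver = is_drv[i], clonality = clonality[i])
      } else if (stats::runif(1) < cfg$background_rate) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, region_id = r, gene = genes[i],
          protein_change = prot[i],
          vaf = round(stats::runif(1, 0.002, 0.08), 4),
          ccf = NA_real_, is_driver = is_drv[i], clonality = NA_character_)
      }
    }
  }
  mutations <- do.call(rbind, c(rows, make.row.names = FALSE))

  # copy-number segments on non-overlapping slots of a 100 Mb toy genome
  n_seg <- sample(seq(cfg$cna_segments_range[1], cfg$cna_segments_range[2]),
                  1L)
  n_sub <- round(cfg$cna_subclonal_frac[[arch]] * n_seg)
  slot_w <- floor(1e8 / n_seg)
  cna <- list()
  for (s in seq_len(n_seg)) {
    len <- sample.int(floor(slot_w / 2), 1L) + 1e5
    start <- (s - 1L) * slot_w + sample.int(slot_w - len - 1L, 1L)
    state <- sample(c(1L, 3L, 4L), 1L)
    in_regions <- if (s <= n_sub) {
      sz <- sample.int(nr - 1L, 1L)
      sample(regions, sz)
    } else regions
    for (r in in_regions)
      cna[[length(cna) + 1L]] <- data.frame(
        patient_id = pid, region_id = r, chrom = "1",
        start = start, end = start + len, cn_state = state)
  }
  cna <- do.call(rbind, c(cna, make.row.names = FALSE))

  # clinical record
  rate <- log(2) / cfg$median_dfs * cfg$hazard_multiplier[[arch]]
  raw <- stats::rexp(1, rate)
  stage_probs <- switch(arch,
    arch1 = c(IA = 0.10, IB = 0.16, II = 0.28, IIIA = 0.28, IIIB = 0.18),
    arch2 = c(IA = 0.30, IB = 0.28, II = 0.24, IIIA = 0.12, IIIB = 0.06),
    arch3 = c(IA = 0.26, IB = 0.26, II = 0.26, IIIA = 0.14, IIIB = 0.08))
  inv_p <- switch(arch, arch1 = 0.5, arch2 = 0.2, arch3 = 0.25)
  clinical <- data.frame(
    patient_id = pid,
    dfs_time = round(min(raw, cfg$censor_time), 1),
    dfs_event = raw <= cfg$censor_time,
    tumor_size = round(stats::rlnorm(1, cfg$tumor_size_meanlog[[arch]],
                                     cfg$tumor_size_sdlog), 1),
    n_regions_sampled = nr,
    stage = sample(names(stage_probs), 1L, prob = stage_probs),
    pleural_invasion = stats::runif(1) < inv_p,
    vascular_invasion = stats::runif(1) < inv_p,
    adjuvant_therapy = stats::runif(1) < if (arch == "arch1") 0.42 else 0.2,
    histology = sample(c("LUAD", "LUSC"), 1L,
                       prob = if (arch == "arch3") c(0.4, 0.6)
                       else c(0.65, 0.35)))

  list(mutations = mutations, cna = cna, clinical = clinical,
       truth = list(archetype = arch, tree = tree,
                    locations = stats::setNames(true_loc, mut_ids),
                    clonality = stats::setNames(clonality, mut_ids),
                    drivers = stats::setNames(drv_edge, drv_genes),
                    trunk_fraction = unname(frac["trunk"]),
                    survival_rate = rate))
}

#' Simulate a timing tournament with a planted gene order
#'
#' Generates pairwise temporal-precedence outcomes for a known ordering of
#' driver genes, for validating [bradley_terry()] recovery: each patient
#' carries a random subset of genes whose latent evolutionary stage is the
#' gene's true rank plus Gaussian noise, and every within-patient pair is
#' ordered by latent stage.
#'
#' @param n_patients Number of patients (default 50).
#' @param genes Gene names, earliest first; their order is the planted
#'   truth.
#' @param genes_per_patient Drivers carried per patient.
#' @param noise_sd Standard deviation of the stage noise, in rank units.
#' @return List with `wins` (matrix for [bradley_terry()]) and
#'   `true_order` (the `genes` argument).
#' @export
simulate_timing_tournament <- function(n_patients = 50,
                                       genes = sprintf("G%02d", 1:10),
                                       genes_per_patient = 4,
                                       noise_sd = 1) {
  k <- length(genes)
  w <- matrix(0, k, k, dimnames = list(genes, genes))
  for (p in seq_len(n_patients)) {
    idx <- sort(sample.int(k, genes_per_patient))
    stage <- idx + stats::rnorm(length(idx), 0, noise_sd)
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (i == j) next
      if (stage[i] < stage[j]) w[idx[i], idx[j]] <- w[idx[i], idx[j]] + 1
    }
  }
  list(wins = w, true_order = genes)
}
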