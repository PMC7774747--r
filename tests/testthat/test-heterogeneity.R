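loc_df <- function(u, s, p) {
  data.frame(
    mutation_id = sprintf("m%d", seq_len(u + s + p)),
    location = c(rep("A_ubiquitous", u), rep("B_shared", s),
                 rep("C_private", p)),
    n_regions_present = rep(1L, u + s + p))
}

test_that("branched diversity is (private + shared) over ubiquitous", {
  expect_equal(branched_diversity(loc_df(5, 2, 3)), 1)
  expect_equal(branched_diversity(loc_df(4, 0, 0)), 0)
  expect_message(bd <- branched_diversity(loc_df(0, 2, 3)), "NA")
  expect_true(is.na(bd))
  expect_error(branched_diversity(loc_df(0, 0, 0)), "no mutations")
})

test_that("ITH index uses labels when present and the CCF fallback
           otherwise", {
  calls <- data.frame(
    patient_id = "P1", region_id = "R1",
    gene = paste0("G", 1:12), protein_change = "",
    vaf = 0.4, ccf = NA_real_, is_driver = FALSE,
    clonality = c(rep("subclonal", 4), rep("clonal", 8)))
  expect_equal(ith_index(calls), 0.5)
  calls$clonality <- "clonal"
  expect_equal(ith_index(calls), 0)
  # fallback: clonal iff ubiquitous and min CCF >= 0.9
  fb <- data.frame(
    patient_id = "P1",
    region_id = rep(c("R1", "R2"), times = 3),
    gene = rep(c("A", "B", "C"), each = 2), protein_change = "",
    vaf = c(0.4, 0.4, 0.4, 0.05, 0.4, 0.4),
    ccf = c(0.95, 0.97, 0.9, 0.9, 0.95, 0.6),
    is_driver = FALSE, clonality = NA_character_)
  # A ubiquitous high CCF -> clonal; B not ubiquitous; C low min CCF
  expect_equal(ith_index(fb), 2)
  fb$ccf <- NA_real_
  expect_error(ith_index(fb), "neither clonality labels nor CCF")
})

test_that("fallback clonality labels match a threshold recount on
           synthetic data", {
  sim <- simulate_cohort(sim_config(
    n_patients = c(arch1 = 2L, arch2 = 2L, arch3 = 2L),
    dropout_rate = 0, background_rate = 0, seed = 6L))
  for (p in unique(sim$mutations$patient_id)) {
    pc <- sim$mutations[sim$mutations$patient_id == p, ]
    labelled <- ith_index(pc)
    pc2 <- pc
    pc2$clonality <- NA_character_
    fallback <- ith_index(pc2)
    # noiseless trunk mutations have CCF >= 0.92 in all regions, so the
    # fallback reproduces the label-based index exactly
    expect_equal(fallback, labelled)
  }
})

test_that("cna_ith equals the per-basepair oracle on toy genomes", {
  seg <- function(r, s, e, cn) data.frame(
    patient_id = "P1", region_id = r, chrom = "1",
    start = s, end = e, cn_state = cn)
  # identical alteration everywhere -> 0
  s1 <- rbind(seg("R1", 0, 100, 3), seg("R2", 0, 100, 3))
  expect_equal(cna_ith(s1, 2), 0)
  # altered in one of three regions -> 1
  s2 <- seg("R1", 50, 150, 1)
  expect_equal(cna_ith(s2, 3), 1)
  # diploid-only segments -> 0
  expect_equal(cna_ith(seg("R1", 0, 99, 2), 2), 0)
  # conflicting overlap is an error
  s3 <- rbind(seg("R1", 0, 100, 3), seg("R1", 50, 150, 1))
  expect_error(cna_ith(s3, 2), "conflicting")
  set.seed(61)
  for (i in 1:20) {
    n_regions <- sample(2:4, 1)
    rows <- list()
    for (r in paste0("R", seq_len(n_regions))) {
      n_seg <- sample(1:4, 1)
      starts <- sort(sample.int(9000, n_seg))
      for (s in starts)
        rows[[length(rows) + 1L]] <- seg(r, s, s + sample.int(800, 1),
                                         sample(c(2L, 3L, 1L), 1))
    }
    segs <- do.call(rbind, rows)
    segs <- segs[!duplicated(segs[c("region_id", "start")]), ]
    ok <- try(cna_ith(segs, n_regions), silent = TRUE)
    if (inherits(ok, "try-error")) next  # conflicting overlap drawn
    expect_equal(ok, oracle_cna_ith(segs, n_regions))
  }
})

test_that("subclonal diversity curve matches closed forms and scaling
           invariance", {
  # trunk-only tree: one non-root node at normalized distance 1
  star <- evo_tree(c(root = NA, A = "root", R1 = "A", R2 = "A"),
                   lengths = c(A = 10, R1 = 0, R2 = 0))
  sc <- subclonal_diversity_curve(star)
  # nodes A, R1, R2 all at distance 1; y(f) = 0 for all f <= 1
  expect_equal(sc$auc, 0)
  # chain tree with k equally spaced nodes: AUC -> 1/2 from below
  chain_auc <- function(k) {
    par <- c(root = NA, stats::setNames(c("root", paste0("n", seq_len(k - 1))),
                                        paste0("n", seq_len(k))))
    lens <- stats::setNames(rep(1, k), paste0("n", seq_len(k)))
    subclonal_diversity_curve(evo_tree(par, lengths = lens))$auc
  }
  expect_equal(chain_auc(4), 3 / 8, tolerance = 0.02)
  expect_equal(chain_auc(50), 49 / 100, tolerance = 0.01)
  expect_lt(abs(chain_auc(100) - 0.5), 0.01)
  # invariance to uniform edge scaling
  tr <- random_mtree(5)
  tr2 <- tr; tr2$lengths <- tr$lengths * 7
  expect_equal(subclonal_diversity_curve(tr)$auc,
               subclonal_diversity_curve(tr2)$auc)
  zero <- evo_tree(c(root = NA, R1 = "root"), lengths = c(R1 = 0))
  expect_error(subclonal_diversity_curve(zero), "zero")
})

test_that("corrected tumor size follows the cube-root law", {
  expect_equal(corrected_tumor_size(30, 1), 30)
  expect_equal(corrected_tumor_size(30, 8), 15)
  ss <- 1:10
  cs <- corrected_tumor_size(40, ss)
  expect_true(all(diff(cs) < 0))
  expect_error(corrected_tumor_size(-1, 2), "positive")
  expect_error(corrected_tumor_size(30, 0), ">= 1")
})

test_that("heterogeneity profile assembles one row per patient", {
  sim <- simulate_cohort(sim_config(
    n_patients = c(arch1 = 1L, arch2 = 1L, arch3 = 1L), seed = 8L))
  pipe <- suppressMessages(evo_subtype_pipeline(sim$mutations))
  prof <- heterogeneity_profile(sim$mutations, pipe$trees,
                                segments = sim$cna,
                                clinical = sim$clinical)
  expect_equal(nrow(prof), 3L)
  expect_true(all(prof$cna_ith >= 0 & prof$cna_ith <= 1))
  expect_true(all(prof$subclonal_diversity_auc >= 0 &
                    prof$subclonal_diversity_auc <= 1))
  expect_true(all(is.finite(prof$corrected_tumor_size)))
})
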