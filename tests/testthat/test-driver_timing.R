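# A hand-built patient: trunk driver (TP53), shared driver (NSD1) above
# regions R1/R2, private driver (PLXNB2) on R1, private driver (EGFR) on R3
# (not below NSD1's branch).
timing_fixture <- function() {
  pres <- rbind(R1 = c(1, 1, 1, 0, 1), R2 = c(1, 1, 0, 0, 1),
                R3 = c(1, 0, 0, 1, 1))
  colnames(pres) <- c("TP53:p.R175H", "NSD1:p.A100T", "PLXNB2:p.G5R",
                      "EGFR:p.L858R", "PSG1:p.K9N")
  rm <- make_rm(pres)
  rm$drivers[] <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  rm$genes[] <- c("TP53", "NSD1", "PLXNB2", "EGFR", "PSG1")
  tree <- dollo_tree(rm, search = "exhaustive")
  loc <- classify_locations(rm)
  list(rm = rm, tree = tree, loc = loc)
}

test_that("timing pairs follow the A < B < C hierarchy with ancestry for
           B -> C", {
  fx <- timing_fixture()
  tp <- timing_pairs(fx$tree, fx$loc, fx$rm$drivers, genes = fx$rm$genes,
                     patient_id = "P1")
  # trunk TP53 precedes every non-trunk driver
  expect_setequal(tp$later_gene[tp$earlier_gene == "TP53"],
                  c("NSD1", "PLXNB2", "EGFR"))
  # shared NSD1 precedes PLXNB2 (same lineage) but not EGFR (disjoint)
  expect_true(any(tp$earlier_gene == "NSD1" & tp$later_gene == "PLXNB2" &
                    tp$relation == "B->C"))
  expect_false(any(tp$earlier_gene == "NSD1" & tp$later_gene == "EGFR"))
  # no pair joins two mutations with the same location label
  loc_of <- stats::setNames(fx$loc$location, fx$loc$mutation_id)
  expect_true(all(loc_of[tp$earlier_mutation] != loc_of[tp$later_mutation]))
  # all drivers on the trunk -> no pairs
  pres <- rbind(R1 = c(1, 1), R2 = c(1, 1))
  colnames(pres) <- c("TP53:a", "KRAS:b")
  rm2 <- make_rm(pres); rm2$drivers[] <- TRUE
  rm2$genes[] <- c("TP53", "KRAS")
  tr2 <- dollo_tree(rm2)
  expect_equal(nrow(timing_pairs(tr2, classify_locations(rm2),
                                 rm2$drivers, genes = rm2$genes)), 0L)
})

test_that("pair counts equal a brute-force enumeration with a leaf-set
           path check", {
  set.seed(71)
  for (i in 1:8) {
    rm <- random_region_matrix(4, 12)
    rm$drivers[] <- seq_along(rm$drivers) <= 6
    tree <- dollo_tree(rm, search = "exhaustive")
    loc <- classify_locations(rm)
    tp <- timing_pairs(tree, loc, rm$drivers, genes = rm$genes)
    # oracle: leaf sets of the carrying edges decide ancestry
    below <- oracle_leaves_below(tree)
    edge_of <- character()
    for (v in names(tree$mutations))
      for (m in tree$mutations[[v]]) edge_of[m] <- v
    rank <- c(A_ubiquitous = 1, B_shared = 2, C_private = 3)
    lr <- stats::setNames(rank[loc$location], loc$mutation_id)
    drv <- names(rm$drivers)[rm$drivers]
    n_expected <- 0L
    for (m1 in drv) for (m2 in drv) {
      if (m1 == m2 || lr[m1] >= lr[m2]) next
      if (lr[m1] == 2 && lr[m2] == 3) {
        e1 <- edge_of[m1]; e2 <- edge_of[m2]
        ok <- e1 != e2 && all(below[[e2]] %in% below[[e1]]) &&
          length(below[[e1]]) > length(below[[e2]])
        if (!ok) next
      }
      n_expected <- n_expected + 1L
    }
    expect_equal(nrow(tp), n_expected)
  }
})

test_that("early driver calls and EDF qualification follow the
           three-patient rule", {
  fx <- timing_fixture()
  early <- early_driver_calls(fx$tree, fx$loc, fx$rm$drivers,
                              genes = fx$rm$genes, patient_id = "P1")
  expect_setequal(early$gene, c("TP53", "NSD1"))  # A, and B with C below
  cohort <- rbind(
    data.frame(patient_id = c("P1", "P2", "P3", "P4"), gene = "TP53"),
    data.frame(patient_id = c("P1", "P2"), gene = "NSD1"),
    data.frame(patient_id = c("P2", "P3", "P4"), gene = "KRAS"))
  edf <- edf_genes(cohort, min_patients = 3)
  expect_setequal(edf$gene, c("TP53", "KRAS"))   # NSD1 early in only 2
  expect_equal(edf$n_patients_early[edf$gene == "TP53"], 4L)
  # qualification is monotone in added patients
  edf2 <- edf_genes(rbind(cohort,
                          data.frame(patient_id = "P5", gene = "NSD1"),
                          data.frame(patient_id = "P6", gene = "NSD1")),
                    min_patients = 3)
  expect_true(all(edf$gene %in% edf2$gene))
  expect_true("NSD1" %in% edf2$gene)
})

test_that("EDF subtype assignment needs 70% of early carriers", {
  cohort <- data.frame(
    patient_id = paste0("P", 1:10),
    gene = "TSHR")
  subtypes <- stats::setNames(c(rep(1, 10)), paste0("P", 1:10))
  edf <- edf_genes(cohort, subtypes = subtypes)
  expect_equal(edf$assigned_subtype, "1")       # 10/10 in one subtype
  expect_equal(edf$subtype_1, 10L)
  mixed <- stats::setNames(c(rep(1, 6), rep(2, 4)), paste0("P", 1:10))
  edf2 <- edf_genes(cohort, subtypes = mixed)
  expect_equal(edf2$assigned_subtype, "none")   # 60% < 70%
  mostly <- stats::setNames(c(rep(1, 7), rep(2, 3)), paste0("P", 1:10))
  edf3 <- edf_genes(cohort, subtypes = mostly)
  expect_equal(edf3$assigned_subtype, "1")      # 7/10 reaches 70%
})

test_that("Bradley-Terry reproduces the 2-item closed form and excludes
           uncompared genes", {
  w <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  fit <- bradley_terry(w, pseudo = 0)
  expect_equal(unname(fit$ability["A"] / fit$ability["B"]), 3,
               tolerance = 1e-6)
  expect_equal(sum(fit$ability), 1)
  # regularized fit keeps the ordering but shrinks the ratio
  fit2 <- bradley_terry(w, pseudo = 0.5)
  expect_equal(unname(fit2$ability["A"] / fit2$ability["B"]), 7 / 3,
               tolerance = 1e-6)
  w3 <- rbind(w, C = 0); w3 <- cbind(w3, C = 0)
  expect_message(fit3 <- bradley_terry(w3), "no comparisons: C")
  expect_setequal(fit3$genes, c("A", "B"))
})

test_that("a transitive tournament is ranked in topological order and
           matches a likelihood grid on 3 genes", {
  w <- matrix(0, 3, 3, dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  w["X", "Y"] <- 5; w["X", "Z"] <- 5; w["Y", "Z"] <- 5
  w["Y", "X"] <- 1; w["Z", "X"] <- 1; w["Z", "Y"] <- 1
  fit <- bradley_terry(w, pseudo = 0)
  expect_equal(fit$ranking, c("X", "Y", "Z"))
  # brute-force likelihood over a simplex grid
  grid <- seq(0.02, 0.96, by = 0.02)
  best <- -Inf; best_p <- NULL
  for (p1 in grid) for (p2 in grid) {
    p3 <- 1 - p1 - p2
    if (p3 <= 0) next
    p <- c(p1, p2, p3)
    ll <- 0
    for (i in 1:3) for (j in 1:3)
      if (i != j) ll <- ll + w[i, j] * log(p[i] / (p[i] + p[j]))
    if (ll > best) { best <- ll; best_p <- p }
  }
  expect_lt(max(abs(unname(fit$ability) - best_p)), 0.03)
  # the MM log-likelihood trace never decreases
  expect_true(all(diff(fit$logLik) >= -1e-9))
})

test_that("maximum-likelihood abilities are invariant to duplicating the
           whole tournament", {
  set.seed(72)
  k <- 5
  w <- matrix(sample(1:6, k * k, replace = TRUE), k, k,
              dimnames = list(paste0("G", 1:k), paste0("G", 1:k)))
  diag(w) <- 0
  f1 <- bradley_terry(w, pseudo = 0)
  f2 <- bradley_terry(2 * w, pseudo = 0)
  expect_equal(f1$ability, f2$ability, tolerance = 1e-5)
})

test_that("planted orderings are recovered from synthetic tournaments", {
  set.seed(73)
  sim <- simulate_timing_tournament(n_patients = 50)
  fit <- bradley_terry(sim$wins)
  tau <- stats::cor(seq_along(sim$true_order),
                    match(sim$true_order, fit$ranking),
                    method = "kendall")
  expect_gte(tau, 0.8)
})

test_that("same-edge driver pairs are ordered by mean CCF", {
  pres <- rbind(R1 = c(1, 1), R2 = c(1, 1))
  colnames(pres) <- c("TP53:a", "KRAS:b")
  rm <- make_rm(pres)
  rm$drivers[] <- TRUE
  rm$genes[] <- c("TP53", "KRAS")
  rm$ccf[] <- c(0.99, 0.98, 0.61, 0.60)  # TP53 higher in both regions
  tr <- dollo_tree(rm)
  pairs <- same_edge_ccf_pairs(tr, rm)
  expect_equal(pairs,
               data.frame(earlier_gene = "TP53", later_gene = "KRAS"))
  w <- bt_wins(timing_pairs(tr, classify_locations(rm), rm$drivers,
                            genes = rm$genes), same_edge_ccf = pairs)
  expect_equal(unname(w["TP53", "KRAS"]), 1)
})
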