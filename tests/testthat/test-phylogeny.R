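test_that("presence matrix applies the VAF detection threshold", {
  calls <- data.frame(
    patient_id = "P1",
    region_id = c("R1", "R2", "R1", "R2"),
    gene = c("TP53", "TP53", "KRAS", "KRAS"),
    protein_change = c("p.R175H", "p.R175H", "p.G12C", "p.G12C"),
    vaf = c(0.09, 0.5, 0.3, 0.4),
    ccf = NA_real_, is_driver = TRUE, clonality = NA_character_)
  m <- build_presence_matrix(calls, vaf_threshold = 0.1)
  expect_equal(unname(m$presence[, "TP53:p.R175H"]), c(0L, 1L))
  expect_equal(unname(m$presence[, "KRAS:p.G12C"]), c(1L, 1L))
  expect_error(build_presence_matrix(calls[calls$region_id == "R1", ]),
               "2 regions")
})

test_that("presence column sums match an independent recount of calls", {
  sim <- simulate_cohort(sim_config(
    n_patients = c(arch1 = 2L, arch2 = 2L, arch3 = 2L), seed = 3L))
  for (p in unique(sim$mutations$patient_id)) {
    pc <- sim$mutations[sim$mutations$patient_id == p, ]
    m <- build_presence_matrix(pc)
    id <- ifelse(nzchar(pc$protein_change),
                 paste0(pc$gene, ":", pc$protein_change), pc$gene)
    recount <- table(id[pc$vaf >= 0.1])
    expect_equal(unname(colSums(m$presence)[names(recount)]),
                 as.integer(recount))
    # mutations below threshold everywhere are dropped
    expect_true(all(colSums(m$presence) > 0))
  }
})

test_that("location labels follow the ubiquitous/shared/private rule", {
  pres <- rbind(R1 = c(1, 1, 0), R2 = c(1, 1, 1), R3 = c(1, 0, 0))
  colnames(pres) <- c("a", "b", "c")
  loc <- classify_locations(make_rm(pres))
  expect_equal(loc$location, c("A_ubiquitous", "B_shared", "C_private"))
  set.seed(4)
  rm <- random_region_matrix(5, 40)
  loc <- classify_locations(rm)
  cs <- colSums(rm$presence)
  expect_equal(sum(loc$location == "A_ubiquitous"), sum(cs == 5))
  expect_equal(sum(loc$location == "C_private"), sum(cs == 1))
  expect_equal(sum(loc$location == "B_shared"), sum(cs > 1 & cs < 5))
})

test_that("dollo_score equals the gain/loss-subset enumeration oracle", {
  set.seed(31)
  for (i in 1:8) {
    rm <- random_region_matrix(4, 12)
    tr <- dollo_tree(rm, search = "exhaustive")
    expect_equal(dollo_score(tr, rm), oracle_dollo_score(tr, rm))
  }
})

test_that("two regions give the unique topology; nested sets give a
           perfect phylogeny with zero losses", {
  pres <- rbind(R1 = c(1, 1, 0), R2 = c(1, 0, 1))
  colnames(pres) <- c("u", "p1", "p2")
  tr <- dollo_tree(make_rm(pres))
  expect_equal(attr(tr, "dollo_score"), 3L)   # 1 gain each, no losses
  expect_setequal(tree_leaves(tr), c("R1", "R2", "normal"))
  # nested carrier sets on 4 regions: score equals the mutation count
  pres <- rbind(R1 = c(1, 1, 1, 0), R2 = c(1, 1, 1, 0),
                R3 = c(1, 1, 0, 0), R4 = c(1, 0, 0, 1))
  colnames(pres) <- paste0("m", 1:4)
  tr <- dollo_tree(make_rm(pres), search = "exhaustive")
  expect_equal(attr(tr, "dollo_score"), 4L)
})

test_that("exhaustive search attains the oracle optimum over all rooted
           topologies", {
  set.seed(32)
  for (i in 1:4) {
    rm <- random_region_matrix(4, 10)
    tr <- dollo_tree(rm, search = "exhaustive")
    oracle_best <- min(vapply(oracle_all_topologies(rm$region_ids),
                              oracle_dollo_score, numeric(1), rm = rm))
    expect_equal(attr(tr, "dollo_score"), oracle_best)
  }
})

test_that("NNI search never beats exhaustive and usually matches it", {
  set.seed(33)
  n_match <- 0L
  for (i in 1:10) {
    rm <- random_region_matrix(5, 15)
    ex <- attr(dollo_tree(rm, search = "exhaustive"), "dollo_score")
    nn <- attr(dollo_tree(rm, search = "nni", n_restarts = 5),
               "dollo_score")
    expect_gte(nn, ex)
    n_match <- n_match + (nn == ex)
  }
  expect_gte(n_match, 9L)
})

test_that("edge assignment conserves mutations and places them at MRCAs", {
  pres <- rbind(R1 = c(1, 0, 1), R2 = c(1, 0, 1), R3 = c(1, 1, 0))
  colnames(pres) <- c("ubi", "priv", "sh")
  rm <- make_rm(pres)
  tr <- dollo_tree(rm, search = "exhaustive")
  # ubiquitous mutation sits on the trunk (edge below the root)
  trunk <- setdiff(tree_children(tr, tr$root), "normal")
  expect_true("ubi" %in% tr$mutations[[trunk]])
  # private mutation sits on R3's pendant edge
  expect_true("priv" %in% tr$mutations[["R3"]])
  expect_equal(tree_total_length(tr), 3)
  set.seed(34)
  for (i in 1:10) {
    rm <- random_region_matrix(sample(3:6, 1), 25)
    tr <- dollo_tree(rm)
    expect_equal(tree_total_length(tr), length(rm$mutation_ids))
    expect_setequal(unlist(tr$mutations), rm$mutation_ids)
  }
})

test_that("region relabeling leaves the Dollo score invariant", {
  set.seed(35)
  for (i in 1:5) {
    rm <- random_region_matrix(5, 20)
    perm <- sample(seq_along(rm$region_ids))
    pres2 <- rm$presence[perm, , drop = FALSE]
    rownames(pres2) <- rm$region_ids
    tr1 <- dollo_tree(rm, search = "exhaustive")
    tr2 <- dollo_tree(make_rm(pres2), search = "exhaustive")
    expect_equal(attr(tr1, "dollo_score"), attr(tr2, "dollo_score"))
  }
})

test_that("degenerate matrices are refused", {
  expect_error(dollo_tree(make_rm(matrix(0L, 2, 2))), "empty")
  rm <- random_region_matrix(8, 5)
  expect_error(dollo_tree(rm, search = "exhaustive"), "7 regions")
})
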