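test_that("the 4-region example maps, normalizes and vectorizes as
           published", {
  tr <- demo_tree()
  d0 <- tree_depths(tr)
  expect_equal(unname(d0[c("R1", "R2", "R3")]), c(3, 3, 3))
  expect_equal(unname(d0["R4"]), 2)
  b <- bifurcate_and_pad(tr)
  expect_equal(attr(b, "depth"), 4)
  expect_equal(unname(tree_depths(b)[c("R1", "R2", "R3")]), c(4, 4, 4))
  nb <- normalize_lengths(b)
  expect_equal(unname(nb$lengths["A"]), 3 / 14)   # trunk
  expect_equal(unname(nb$lengths["B"]), 2 / 14)   # intermediate edge
  z <- vectorize(nb)
  expect_length(z, 30)                            # 2^(4+1) - 2
  expect_equal(round(z[1:10], 3),
               c(0.214, 0.143, 0, 0.214, 0.214, 0, 0.071, 0, 0.143, 0))
  expect_true(all(z[11:30] == 0))
  expect_equal(sum(z), 1)
})

test_that("an already-binary balanced tree at target depth is unchanged", {
  tr <- evo_tree(c(root = NA, A = "root", B = "root",
                   R1 = "A", R2 = "A", R3 = "B", R4 = "B"),
                 lengths = c(A = 2, B = 2, R1 = 1, R2 = 1, R3 = 1, R4 = 1))
  b <- bifurcate_and_pad(tr)
  expect_equal(attr(b, "depth"), 2)
  expect_length(attr(b, "virtual"), 0)
  expect_equal(sort(names(b$parent)), sort(names(tr$parent)))
  z <- vectorize(normalize_lengths(b))
  expect_length(z, 6)
  # equal edge lengths in a symmetric tree give equal real entries
  expect_equal(unname(z), c(0.25, 0.125, 0.125, 0.25, 0.125, 0.125),
               ignore_attr = TRUE)
})

test_that("bifurcation preserves total length and pads all leaves to the
           target depth", {
  set.seed(41)
  for (i in 1:30) {
    tr <- random_mtree(sample(2:7, 1))
    b <- bifurcate_and_pad(tr)
    expect_equal(sum(b$lengths), tree_total_length(tr))
    d <- tree_depths(b)
    leaves <- tree_leaves(b)
    expect_true(all(d[leaves] == attr(b, "depth")))
    virt <- attr(b, "virtual")
    expect_true(all(b$lengths[virt] == 0))
  }
})

test_that("normalization requires positive total length and divides by it", {
  one <- evo_tree(c(root = NA, R1 = "root"), lengths = c(R1 = 7))
  z <- vectorize(normalize_lengths(bifurcate_and_pad(one)))
  expect_equal(unname(z[1]), 1)
  zero <- evo_tree(c(root = NA, R1 = "root"), lengths = c(R1 = 0))
  expect_error(normalize_lengths(bifurcate_and_pad(zero)), "0")
})

test_that("vectors conserve mass and count of positive entries on random
           trees", {
  set.seed(42)
  for (i in 1:30) {
    tr <- random_mtree(sample(2:7, 1))
    z <- vectorize(normalize_lengths(bifurcate_and_pad(tr)))
    expect_equal(sum(z), 1)
    n_real_pos <- sum(tr$lengths > 0)
    expect_equal(sum(z > 0), n_real_pos)
  }
})

test_that("the vector is invariant to node enumeration order", {
  set.seed(43)
  for (i in 1:15) {
    tr <- random_mtree(sample(3:6, 1))
    perm <- sample(seq_along(tr$parent))
    tr2 <- evo_tree(tr$parent[perm], lengths = tr$lengths)
    z1 <- vectorize(normalize_lengths(bifurcate_and_pad(tr)))
    z2 <- vectorize(normalize_lengths(bifurcate_and_pad(tr2)))
    expect_equal(unname(z1), unname(z2))
  }
})

test_that("cohort vectors share the global reference depth", {
  trees <- list(P1 = demo_tree(), P2 = demo_tree())
  m <- cohort_vectors(trees)
  expect_equal(dim(m), c(2, 30))
  expect_equal(m["P1", ], m["P2", ])

  # a deeper patient extends everyone to the new reference depth; the
  # shallow tree keeps its positive entries and gains structural zeros only
  deep <- evo_tree(c(root = NA, A = "root", B = "A", C = "B", D = "C",
                     R1 = "D", R2 = "D", R3 = "C", R4 = "B", R5 = "A"),
                   lengths = c(A = 4, B = 3, C = 2, D = 2, R1 = 1, R2 = 2,
                               R3 = 1, R4 = 2, R5 = 3))
  m2 <- cohort_vectors(list(P1 = demo_tree(), P3 = deep))
  expect_gt(attr(m2, "depth"), attr(m, "depth"))
  expect_equal(ncol(m2), 2^(attr(m2, "depth") + 1) - 2)
  expect_equal(sort(m2["P1", m2["P1", ] > 0]),
               sort(m["P1", m["P1", ] > 0]))
  expect_equal(sum(m2["P1", ]), 1)
})

test_that("trees reconstructed with an outgroup vectorize on the tumor
           clade only", {
  pres <- rbind(R1 = c(1, 1, 0), R2 = c(1, 1, 1), R3 = c(1, 0, 1))
  colnames(pres) <- paste0("m", 1:3)
  tr <- dollo_tree(make_rm(pres), search = "exhaustive")
  z <- vectorize(normalize_lengths(bifurcate_and_pad(tr)))
  expect_equal(sum(z), 1)
  b <- bifurcate_and_pad(tr)
  expect_false("normal" %in% names(b$parent))
})
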