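# Distances, neighbor joining, bootstrap, monophyly.

test_that("distance closed forms", {
  expect_equal(compute_distances(c(a = "MKLV", b = "MKLV"))["a", "b"], 0)
  expect_equal(compute_distances(c(a = "MKLV", b = "MKIV"), "p")["a", "b"],
               0.25)
  expect_equal(compute_distances(c(a = "MKLV", b = "MKIV"),
                                 "poisson")["a", "b"],
               -log(0.75), tolerance = 1e-10)
  expect_equal(compute_distances(c(a = "ACGT", b = "GCGT"),
                                 "k2p_nt")["a", "b"],
               -0.5 * log(0.5), tolerance = 1e-10)
  # pairwise deletion skips gap columns per pair
  d <- compute_distances(c(a = "MK-V", b = "MKIV", c = "MKIV"), "p")
  expect_equal(d["a", "b"], 0)
  expect_equal(d["b", "c"], 0)
  # saturation errors name the pair
  expect_error(compute_distances(c(a = "AAAA", b = "CCCC"), "poisson"),
               "a, b")
})

test_that("NJ resolves the quartet with exact branch lengths", {
  d <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  expect_true(test_monophyly(tr, c("A", "B")))
  co <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(unname(co), unname(d), tolerance = 1e-9)
  # 3-taxon star closed form
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- nj_tree(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 1, c = 2))
  expect_error(nj_tree(matrix(c(0, 1, 1, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "3 taxa")
})

test_that("NJ recovers random additive matrices and matches ape", {
  set.seed(53)
  for (i in 1:30) {
    D <- random_additive_matrix(sample(4:12, 1))
    tr <- nj_tree(D)
    co <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(co - D)), 1e-6)
    # independent oracle: ape's NJ gives the same unrooted topology
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ape::nj(D))),
                 structure(0, names = "PH85"), ignore_attr = TRUE)
  }
})

test_that("label permutation leaves the unrooted topology unchanged", {
  set.seed(59)
  D <- random_additive_matrix(8)
  p <- sample(8)
  t1 <- nj_tree(D)
  t2 <- nj_tree(D[p, p])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))),
               0)
})

test_that("bootstrap is seed-reproducible and saturates on congruent signal", {
  aln <- c(A = paste0(strrep("A", 100), strrep("C", 100)),
           B = paste0(strrep("A", 100), strrep("C", 100)),
           C = paste0(strrep("G", 100), strrep("T", 100)),
           D = paste0(strrep("G", 100), strrep("T", 100)))
  b1 <- bootstrap_support(aln, "p", replicates = 100, seed = 17)
  b2 <- bootstrap_support(aln, "p", replicates = 100, seed = 17)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  supp <- suppressWarnings(as.numeric(b1$node.label))
  expect_equal(max(supp, na.rm = TRUE), 100)
  # a single replicate can only give 0 or 100
  b3 <- bootstrap_support(aln, "p", replicates = 1, seed = 2)
  s3 <- suppressWarnings(as.numeric(b3$node.label))
  expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
  expect_error(bootstrap_support(aln, "p", replicates = 0, seed = 1),
               "replicates")
})

test_that("monophyly is a bipartition test on the unrooted tree", {
  tr <- ape::read.tree(text = "((T1:1,T2:1):1,(N1:1,N2:1):1);")
  expect_true(test_monophyly(tr, c("T1", "T2")))
  expect_false(test_monophyly(tr, c("T1", "N1")))
  expect_true(test_monophyly(tr, "T1"))
  expect_error(test_monophyly(tr, "nope"), "unknown tip")
})

test_that("a TIR-labeled clade simulated down a tree is recovered", {
  tir_tips <- paste0("tir", 1:5)
  cc_tips <- paste0("cc", 1:8)
  nwk <- paste0("((", paste0(tir_tips, ":0.1", collapse = ","), "):0.6,",
                paste0(cc_tips, ":0.15", collapse = ","), ");")
  tree <- ape::read.tree(text = nwk)
  aln <- simulate_alignment(tree, 400, seed = 61)
  est <- nj_tree(compute_distances(aln, "poisson"))
  expect_true(test_monophyly(est, tir_tips))
  expect_false(test_monophyly(est, c(tir_tips[1], cc_tips[1])))
})
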