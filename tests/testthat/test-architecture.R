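# Clusters, duplication events, families, per-location summaries.

mk_loci <- function(starts, seq_id = "chr1", width = 1000,
                    ids = sprintf("g%02d", seq_along(starts))) {
  data.frame(gene_id = ids, seq_id = seq_id, start = starts,
             end = starts + width - 1, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("200-kb rule with transitive chaining", {
  # 95-kb gap -> one cluster of two
  cl <- detect_clusters(mk_loci(c(1e5, 1e5 + 1000 + 95000)))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 2L)
  # 250-kb gap -> none
  cl2 <- detect_clusters(mk_loci(c(1e5, 1e5 + 1000 + 250000)))
  expect_equal(nrow(cl2), 0L)
  # successive 150-kb gaps chain into one cluster of three
  s <- c(1e5, 1e5 + 1000 + 150000, 1e5 + 2 * (1000 + 150000))
  cl3 <- detect_clusters(mk_loci(s))
  expect_equal(cl3$n_members, 3L)
  # overlap counts as zero gap
  cl4 <- detect_clusters(mk_loci(c(1000, 1500)))
  expect_equal(cl4$n_members, 2L)
  expect_error(detect_clusters(mk_loci(c(1, 2), ids = c("a", "a"))),
               "duplicate")
})

test_that("clusters are permutation-invariant and partition their members", {
  set.seed(41)
  loci <- rbind(mk_loci(c(1e5, 1.5e5, 2e5, 9e5, 9.6e5), "chr1",
                        ids = paste0("a", 1:5)),
                mk_loci(c(5e5, 5.4e5, 2e6), "chr2", ids = paste0("b", 1:3)))
  c1 <- detect_clusters(loci)
  c2 <- detect_clusters(loci[sample(nrow(loci)), ])
  expect_equal(c1$members, c2$members)
  mem <- cluster_membership(c1)
  expect_false(anyDuplicated(mem$gene_id) > 0)
  for (k in seq_len(nrow(c1)))
    expect_true(all(loci$seq_id[match(c1$members[[k]], loci$gene_id)] ==
                      c1$seq_id[k]))
})

test_that("70/70 decision rule on constructed pairs", {
  set.seed(43)
  base <- generate_gene("CNL", "regular")$sequence
  ident <- detect_duplications(setNames(c(base, base), c("a", "b")))
  expect_equal(nrow(ident), 1L)
  expect_equal(ident$coverage, 1.0)
  expect_equal(ident$identity, 1.0)
  # 60% identity, full coverage -> no event
  pair60 <- setNames(c(base, mutate_to_identity(base, 0.60)), c("a", "b"))
  expect_equal(nrow(detect_duplications(pair60)), 0L)
  # 85% identity -> event
  pair85 <- setNames(c(base, mutate_to_identity(base, 0.85)), c("a", "b"))
  ev <- detect_duplications(pair85)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$identity, 0.85, tolerance = 0.02)
  # truncated copy at 50% length -> coverage fails
  half <- substr(base, 1, floor(nchar(base) / 2))
  expect_equal(nrow(detect_duplications(setNames(c(base, half),
                                                 c("a", "b")))), 0L)
})

test_that("alignment decisions match the dynamic-programming oracle", {
  set.seed(47)
  params <- duplication_params()
  for (i in 1:50) {
    len <- sample(60:120, 1)
    a <- random_protein(len)
    b <- switch(1 + (i %% 4),
                mutate_to_identity(a, runif(1, 0.85, 0.98)),
                mutate_to_identity(a, runif(1, 0.40, 0.60)),
                random_protein(sample(60:120, 1)),
                substr(mutate_to_identity(a, 0.9), 1,
                       floor(len * runif(1, 0.4, 0.6))))
    got <- align_pair(a, b)
    want <- oracle_align(a, b)
    expect_equal(got$score, want$score, tolerance = 1e-6,
                 info = paste("instance", i))
    # identity is only defined up to co-optimality; compare it where it is
    # decision-relevant (far-below-threshold pairs admit many tracebacks)
    if (max(got$identity, want$identity) >= 0.4)
      expect_equal(got$identity, want$identity, tolerance = 0.05,
                   info = paste("instance", i))
    expect_equal(got$coverage, want$coverage, tolerance = 0.02,
                 info = paste("instance", i))
    decision_got <- got$coverage > params$min_coverage &&
      got$identity > params$min_identity
    decision_want <- want$coverage > params$min_coverage &&
      want$identity > params$min_identity
    expect_equal(decision_got, decision_want, info = paste("instance", i))
  }
})

test_that("families are single-linkage components", {
  ev <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                   coverage = 1, identity = 0.9, linked = FALSE)
  fam <- build_families(ev)
  expect_equal(sort(fam$gene_id[fam$family_id == "family1"]),
               c("A", "B", "C"))
  ev2 <- data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
                    coverage = 1, identity = 0.9, linked = FALSE)
  expect_equal(length(unique(build_families(ev2)$family_id)), 2L)
})

test_that("16 pair families plus 7 larger components give 23 families", {
  pairs <- data.frame(gene_a = sprintf("p%02da", 1:16),
                      gene_b = sprintf("p%02db", 1:16))
  bigger <- do.call(rbind, lapply(1:7, function(k) {
    ids <- sprintf("f%d_%d", k, 1:3)
    data.frame(gene_a = ids[c(1, 2)], gene_b = ids[c(2, 3)])
  }))
  ev <- rbind(pairs, bigger)
  ev$coverage <- 1; ev$identity <- 0.9; ev$linked <- FALSE
  fam <- build_families(ev)
  expect_equal(length(unique(fam$family_id)), 23L)
  sizes <- table(table(fam$family_id))
  expect_equal(unname(sizes[["2"]]), 16L)
  expect_equal(unname(sizes[["3"]]), 7L)
})

test_that("linked events collapse to one per adjacent run", {
  loci <- mk_loci(c(1e5, 1.2e5, 1.4e5), ids = c("A", "B", "C"))
  clusters <- detect_clusters(loci)
  prot <- generate_gene("CNL", "regular")$sequence
  prots <- setNames(c(prot, mutate_to_identity(prot, 0.95),
                      mutate_to_identity(prot, 0.9)), c("A", "B", "C"))
  ev <- detect_duplications(prots, loci = loci, clusters = clusters)
  expect_true(any(ev$linked))
  collapsed <- collapse_linked_events(ev)
  expect_lt(nrow(collapsed), nrow(ev))
})

test_that("architecture summary applies the exclusion convention", {
  # 3 genes clustered on chr1, singleton on chr2 excluded from denominator
  loci <- rbind(mk_loci(c(1e5, 1.5e5, 2e5), "chr1", ids = c("a", "b", "c")),
                mk_loci(5e5, "chr2", ids = "d"))
  cl <- detect_clusters(loci)
  s <- summarize_architecture(loci, cl, data.frame(gene_a = "a",
                                                   gene_b = "b",
                                                   coverage = 1,
                                                   identity = 1,
                                                   linked = TRUE))
  expect_equal(s$totals$n_excluded, 1L)
  expect_equal(s$totals$clustered_pct, 100)
  expect_equal(s$totals$dup_in_cluster_pct, 100)
  expect_equal(sum(s$per_location$n_genes), 4L)
  # empty genome
  s0 <- summarize_architecture(loci[0, ], detect_clusters(loci[0, ]),
                               data.frame(gene_a = character(),
                                          gene_b = character(),
                                          coverage = numeric(),
                                          identity = numeric(),
                                          linked = logical()))
  expect_equal(s0$totals$n_genes, 0L)
})

test_that("GFF3 round trip preserves loci", {
  loci <- mk_loci(c(1e5, 3e5), ids = c("gA", "gB"))
  f <- tempfile(fileext = ".gff3")
  gr <- GenomicRanges::GRanges(loci$seq_id,
                               IRanges::IRanges(loci$start, loci$end),
                               strand = loci$strand, type = "gene",
                               ID = loci$gene_id)
  rtracklayer::export(gr, f, format = "gff3")
  back <- read_gene_loci(f)
  expect_equal(back$gene_id, loci$gene_id)
  expect_equal(back$start, loci$start)
  expect_equal(back$end, loci$end)
})
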