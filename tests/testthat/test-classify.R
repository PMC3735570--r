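# Regularity, terminal codes, letter-code composition, class summaries.

test_that("regularity requires all five motifs and a complete ORF", {
  cons <- nbsatlas:::nbs_motif_consensus()
  full <- paste0("M", strrep("SGT", 10),
                 paste(cons, collapse = strrep("GST", 4)), strrep("TGS", 10))
  h <- scan_nbs_motifs(full)
  r <- assess_regularity(h, full)
  expect_equal(r$regularity, "regular")
  expect_true(r$subset_contiguous)
  # same motifs but no initial Met -> non-regular
  broken <- sub("^M", "G", full)
  r2 <- assess_regularity(scan_nbs_motifs(broken), broken)
  expect_equal(r2$regularity, "non-regular")
  # contiguous subset
  part <- paste0("M", strrep("SGT", 10), cons["Kinase3a"], strrep("GST", 4),
                 cons["GLPL"], strrep("GST", 4), cons["MHDL"], strrep("TGS", 10))
  r3 <- assess_regularity(scan_nbs_motifs(part), part)
  expect_equal(r3$regularity, "non-regular")
  expect_equal(r3$motif_subset, c("Kinase3a", "GLPL", "MHDL"))
  expect_true(r3$subset_contiguous)
  # non-contiguous subset flagged
  gap <- paste0("M", strrep("SGT", 10), cons["P-loop"], strrep("GST", 4),
                cons["GLPL"], strrep("TGS", 10))
  r4 <- assess_regularity(scan_nbs_motifs(gap), gap)
  expect_equal(r4$motif_subset, c("P-loop", "GLPL"))
  expect_false(r4$subset_contiguous)
})

test_that("N-terminal code follows the T > C > c > X > none priority", {
  ev_tir <- data.frame(gene_id = "g", domain_type = "TIR",
                       start = 5, end = 140, score = 1)
  expect_equal(assign_nterm_code(200, ev_tir), "T")
  ev0 <- data.frame(gene_id = character(), domain_type = character(),
                    start = integer(), end = integer(), score = numeric())
  prof <- structure(list(gene_id = "g", prob = c(rep(0.6, 150), rep(0, 100)),
                         window = 21, thresholds = c(0.02, 0.1, 0.5, 0.9)),
                    class = "cc_profile")
  expect_equal(assign_nterm_code(200, ev0, prof), "c")
  prof$prob[10] <- 0.95
  expect_equal(assign_nterm_code(200, ev0, prof), "C")
  # long undescribed flank -> X; short -> none
  zero <- prof; zero$prob[] <- 0
  expect_equal(assign_nterm_code(121, ev0, zero), "X")
  expect_equal(assign_nterm_code(81, ev0, zero), "")
  expect_equal(assign_nterm_code(101, ev0, zero), "")  # rule is strict > 100
  expect_error(assign_nterm_code(NA, ev0), "classification error")
})

test_that("C-terminal code is L over X over none", {
  ev_lrr <- data.frame(gene_id = "g", domain_type = "LRR",
                       start = 450, end = 680, score = 1)
  expect_equal(assign_cterm_code(420, 700, ev_lrr), "L")
  ev0 <- ev_lrr[0, ]
  expect_equal(assign_cterm_code(420, 570, ev0), "X")
  expect_equal(assign_cterm_code(420, 460, ev0), "")
  expect_equal(assign_cterm_code(420, 520, ev0), "")  # exactly 100 residues
})

test_that("whole-gene classification composes the expected codes", {
  set.seed(31)
  cases <- list(c("CNL", "regular"), c("cNL", "non-regular"),
                c("XNX", "non-regular"), c("TN", "non-regular"),
                c("N", "regular"))
  for (cs in cases) {
    g <- generate_gene(cs[1], cs[2])
    cl <- classify_genes(setNames(g$sequence, "g"))
    expect_equal(cl$letter_code, cs[1])
    expect_equal(cl$regularity, cs[2])
  }
})

test_that("every qualified gene gets exactly one code and counts conserve", {
  set.seed(33)
  prots <- setNames(c(generate_gene("CNL", "regular")$sequence,
                      generate_gene("TNL", "regular")$sequence,
                      generate_gene("NL", "non-regular")$sequence,
                      generate_gene("cNX", "regular")$sequence),
                    paste0("g", 1:4))
  cl <- classify_genes(prots)
  expect_equal(nrow(cl), 4L)
  expect_true(all(grepl("^[CcTX]?N[LX]?$", cl$letter_code)))
  s <- summarize_classes(cl)
  expect_equal(sum(s$subgroups$n), 4L)
  # permutation invariance
  s2 <- summarize_classes(cl[sample(nrow(cl)), ])
  expect_equal(s$subgroups, s2$subgroups)
})

test_that("class summary reproduces printed-count arithmetic", {
  cl <- data.frame(gene_id = paste0("g", 1:355),
                   regularity = rep(c("regular", "non-regular"), c(163, 192)),
                   letter_code = c(rep("CNL", 24), rep("cNL", 57),
                                   rep("TNL", 19), rep("NL", 63),
                                   rep("XNX", 2), rep("NX", 190)))
  s <- summarize_classes(cl)
  sg <- s$subgroups
  expect_equal(sg$pct[sg$letter_code == "CNL" & sg$regularity == "regular"],
               6.76)
  expect_equal(s$totals$pct[s$totals$regularity == "regular"], 45.92)
  expect_equal(s$totals$pct[s$totals$regularity == "non-regular"], 54.08)
  # small worked example
  s2 <- summarize_classes(data.frame(gene_id = paste0("g", 1:4),
                                     regularity = "regular",
                                     letter_code = rep(c("CN", "TN"),
                                                       c(1, 3))))
  expect_equal(sort(s2$subgroups$pct), c(25, 75))
  # degenerate inputs
  expect_error(summarize_classes(cl[0, ], total = 0), "zero")
  s0 <- summarize_classes(cl[0, ], total = 10)
  expect_equal(nrow(s0$subgroups), 0L)
})
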