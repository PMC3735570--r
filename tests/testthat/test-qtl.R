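# Electronic PCR and marker co-localization.

plant_product <- function(len = 10000, at = 2000, size = 300,
                          primer_len = 20) {
  g <- random_dna_seq(len)
  fwd <- substr(g, at, at + primer_len - 1)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(g, at + size - primer_len, at + size - 1))))
  list(genome = c(chr1 = g), fwd = fwd, rev = rev,
       start = at, end = at + size - 1)
}

test_that("planted perfect sites give one product of the planted size", {
  set.seed(71)
  pl <- plant_product(size = 300)
  hits <- epcr(pl$genome, pl$fwd, pl$rev)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$size, 300L)
  expect_equal(hits$start, pl$start)
  expect_equal(hits$end, pl$end)
  expect_equal(hits$fwd_mismatches + hits$rev_mismatches, 0L)
})

test_that("products outside the size window are rejected", {
  set.seed(73)
  too_big <- plant_product(size = 750)
  expect_equal(nrow(epcr(too_big$genome, too_big$fwd, too_big$rev)), 0L)
  too_small <- plant_product(size = 60)
  expect_equal(nrow(epcr(too_small$genome, too_small$fwd, too_small$rev)), 0L)
})

test_that("primer validation errors", {
  g <- c(chr1 = random_dna_seq(1000))
  expect_error(epcr(g, "ACGTACGTACGT", strrep("ACGT", 5)), "15 bases")
  expect_error(epcr(g, strrep("ACGT", 5), "AC",
                    params = epcr_params(anchor3 = 3)), "anchor")
})

test_that("e-PCR equals the all-position-pairs oracle", {
  set.seed(79)
  for (i in 1:50) {
    pl <- plant_product(len = 2500, at = sample(200:800, 1),
                        size = sample(100:600, 1))
    fwd <- pl$fwd; rev <- pl$rev
    # degrade primers with up to 3 substitutions (some exceed the limit)
    degrade <- function(p, k) {
      s <- strsplit(p, "")[[1]]
      for (j in sample(length(s) - 3, k)) # 3' anchor left intact
        s[j] <- sample(setdiff(c("A", "C", "G", "T"), s[j]), 1)
      paste(s, collapse = "")
    }
    fwd <- degrade(fwd, sample(0:3, 1))
    rev <- degrade(rev, sample(0:3, 1))
    got <- epcr(pl$genome, fwd, rev)
    want <- oracle_epcr(pl$genome, fwd, rev)
    key <- function(d) sort(paste(d$seq_id, d$start, d$end))
    expect_equal(key(got), key(want), info = paste("instance", i))
  }
})

test_that("reverse-complementing the genome mirrors the placements", {
  set.seed(83)
  pl <- plant_product(len = 5000, at = 1500, size = 250)
  rc_genome <- c(chr1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pl$genome[["chr1"]]))))
  fwdhits <- epcr(pl$genome, pl$fwd, pl$rev)
  rchits <- epcr(rc_genome, pl$fwd, pl$rev)
  expect_equal(nrow(rchits), nrow(fwdhits))
  L <- nchar(pl$genome[["chr1"]])
  expect_equal(sort(L - fwdhits$end + 1), sort(rchits$start))
  expect_equal(rchits$size, fwdhits$size)
})

test_that("marker categories are exhaustive and follow the 3-Mb rule", {
  loci <- data.frame(gene_id = c("g1", "g2"),
                     seq_id = c("chr1", "scf_nbs"),
                     start = c(5e6, 2e5), end = c(5.002e6, 2.02e5),
                     strand = "+")
  seqinfo <- data.frame(seq_id = c("chr1", "scf_nbs", "scf_small",
                                   "scf_big"),
                        length = c(2e7, 1.8e6, 1.5e6, 2.5e6),
                        is_chromosome = c(TRUE, FALSE, FALSE, FALSE))
  mk <- function(id, sid, mid) data.frame(marker_id = id, seq_id = sid,
                                          start = mid - 100, end = mid + 99,
                                          size = 200, fwd_mismatches = 0,
                                          rev_mismatches = 0,
                                          orientation = "fwd_plus")
  placements <- rbind(mk("m_within", "chr1", 7.5e6),   # 2.5 Mb away
                      mk("m_out", "chr1", 1.01e7),     # 5 Mb away
                      mk("m_scaf", "scf_nbs", 9e5),
                      mk("m_small", "scf_small", 7e5),
                      mk("m_bigscaf", "scf_big", 1e6))
  ids <- c(placements$marker_id, "m_lost")
  cats <- categorize_markers(ids, placements, loci, seqinfo)
  got <- setNames(cats$category, cats$marker_id)
  expect_equal(got[["m_within"]], "within_flank")
  expect_equal(got[["m_out"]], "outside_flank")
  expect_equal(got[["m_scaf"]], "scaffold_with_nbs")
  expect_equal(got[["m_small"]], "small_scaffold_no_nbs")
  expect_equal(got[["m_bigscaf"]], "outside_flank")
  expect_equal(got[["m_lost"]], "unplaced")
  expect_equal(nrow(cats), length(ids))  # one category per marker
  expect_error(categorize_markers("x", mk("x", "nowhere", 5), loci, seqinfo),
               "unknown sequence")
})

test_that("multi-hit markers use the placement nearest an NBS gene", {
  loci <- data.frame(gene_id = "g1", seq_id = "chr1",
                     start = 1e6, end = 1.001e6, strand = "+")
  seqinfo <- data.frame(seq_id = c("chr1", "chr2"), length = c(2e7, 2e7),
                        is_chromosome = TRUE)
  placements <- data.frame(marker_id = "m", seq_id = c("chr1", "chr2"),
                           start = c(1.2e6, 5e6), end = c(1.2002e6, 5.0002e6),
                           size = 200, fwd_mismatches = 0,
                           rev_mismatches = 0, orientation = "fwd_plus")
  cats <- categorize_markers("m", placements, loci, seqinfo)
  expect_equal(cats$category, "within_flank")
  expect_equal(cats$seq_id, "chr1")
})

test_that("QTL summary reproduces the reporting percentages", {
  categories <- data.frame(
    marker_id = sprintf("m%02d", 1:98),
    category = rep(c("within_flank", "outside_flank",
                     "small_scaffold_no_nbs", "scaffold_with_nbs",
                     "unplaced"), c(34, 21, 17, 2, 24)),
    seq_id = NA_character_, position = NA_real_, distance = NA_real_)
  categories$seq_id[categories$category != "unplaced"] <- "chr1"
  loci <- data.frame(gene_id = "g", seq_id = "chr1", start = 1, end = 10,
                     strand = "+")
  seqinfo <- data.frame(seq_id = "chr1", length = 1e7, is_chromosome = TRUE)
  s <- summarize_qtl(categories, loci, seqinfo)
  expect_equal(s$totals$n_placed, 74L)
  expect_equal(s$totals$within_pct, 45.9)
  expect_equal(s$totals$placed_pct, 75.5)
  # empty input
  s0 <- summarize_qtl(categories[0, ], loci, seqinfo)
  expect_equal(s0$totals$n_markers, 0L)
})
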