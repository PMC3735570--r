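# Synthetic genome/proteome generator with planted ground truth.
#
# The generator builds proteins by construction: it plants the motif
# cassettes, heptad repeats, TIR/LRR markers and flank lengths that realize
# a requested letter code and regularity, and then verifies that the
# assembled protein actually scans and classifies to its intended label
# (resampling the random parts otherwise). Neutral filler is drawn from
# {C, G, H, S, T}, an alphabet that can produce neither NBS-motif matches
# nor coiled-coil signal, so negative regions are signal-free by
# construction.
# Planted truth labels are therefore well-defined and the generator's
# output is a fixture for exact truth-recovery testing.

FILL_NEUTRAL <- c("C", "G", "H", "S", "T")
FILL_X <- c("A", "S", "G", "T", "Q", "E", "K", "R", "N")
HEPTAD_CORE <- c("L", "I", "V", "M", "F")
HEPTAD_POLAR <- c("E", "K", "Q", "R", "N")
LRR_X <- c("S", "G", "T", "E", "Q", "K")

r_fill <- function(n, set = FILL_NEUTRAL) {
  paste(sample(set, n, replace = TRUE), collapse = "")
}

# one heptad unit; strong units polarize the outer face, weak ones do not
r_heptad <- function(strong = TRUE) {
  u <- character(7)
  u[c(1, 4)] <- sample(HEPTAD_CORE, 2, replace = TRUE)
  outer <- if (strong) HEPTAD_POLAR else FILL_NEUTRAL
  u[c(2, 3, 5, 6, 7)] <- sample(outer, 5, replace = TRUE)
  paste(u, collapse = "")
}

r_heptad_region <- function(n_units = 8, strong = TRUE) {
  paste(vapply(seq_len(n_units), function(i) r_heptad(strong), character(1)),
        collapse = "")
}

r_tir_region <- function(divergence = stats::runif(1, 0.18, 0.24)) {
  s <- .seq_chars(TIR_CONSENSUS)
  k <- round(divergence * length(s))
  if (k > 0) {
    pos <- sample(length(s), k)
    for (i in pos) s[i] <- sample(setdiff(AA20, s[i]), 1)
  }
  paste(s, collapse = "")
}

r_lrr_unit <- function() {
  x <- sample(LRR_X, 6, replace = TRUE)
  paste0("L", x[1], x[2], "L", x[3], "L", x[4], x[5], "N", x[6], "L")
}

r_lrr_region <- function(n_units = 6) {
  paste(vapply(seq_len(n_units), function(i) r_lrr_unit(), character(1)),
        collapse = "")
}

# sample a cassette realizing a motif model (constrained positions from the
# allowed class, wildcards from a neutral-ish alphabet)
sample_motif_cassette <- function(model) {
  vapply(model$positions, function(p) {
    if (is.null(p)) sample(FILL_X, 1) else sample(p, 1)
  }, character(1))
}

#' Parse a letter code
#'
#' @param letter_code Code such as `"CNL"`, `"cNX"`, `"TN"`, `"XNX"`, `"N"`.
#' @return List with `nterm` and `cterm` components (possibly `""`).
#' @export
parse_letter_code <- function(letter_code) {
  if (!grepl("^[CcTX]?N[LX]?$", letter_code))
    stop("not a valid letter code: ", letter_code)
  npos <- regexpr("N", letter_code, fixed = TRUE)
  list(nterm = substr(letter_code, 1, npos - 1),
       cterm = substr(letter_code, npos + 1, nchar(letter_code)))
}

.truncation_options <- list(1:3, 2:4, 3:5, 1:4, 2:5)

# assemble one candidate protein; returns list(sequence, layout)
.assemble_gene <- function(letter_code, regularity, truncation, models) {
  parts <- parse_letter_code(letter_code)
  ranks <- if (regularity == "regular") 1:5 else truncation
  # N-terminal region (before the NBS block)
  nterm_seq <- "M"
  tir_iv <- NULL
  cc_iv <- NULL
  if (parts$nterm %in% c("C", "c")) {
    pre <- r_fill(sample(3:8, 1))
    hep <- r_heptad_region(8, strong = parts$nterm == "C")
    post <- r_fill(sample(5:15, 1))
    cc_iv <- c(nchar(nterm_seq) + nchar(pre) + 1,
               nchar(nterm_seq) + nchar(pre) + nchar(hep))
    nterm_seq <- paste0(nterm_seq, pre, hep, post)
  } else if (parts$nterm == "T") {
    pre <- r_fill(sample(3:10, 1))
    tir <- r_tir_region()
    post <- r_fill(sample(5:15, 1))
    tir_iv <- c(nchar(nterm_seq) + nchar(pre) + 1,
                nchar(nterm_seq) + nchar(pre) + nchar(tir))
    nterm_seq <- paste0(nterm_seq, pre, tir, post)
  } else if (parts$nterm == "X") {
    nterm_seq <- paste0(nterm_seq, r_fill(sample(110:160, 1)))
  } else {
    nterm_seq <- paste0(nterm_seq, r_fill(sample(40:90, 1)))
  }
  # NBS block: present cassettes joined by neutral linkers
  offset <- nchar(nterm_seq)
  nbs_seq <- ""
  motifs <- list()
  for (r in ranks) {
    cassette <- paste(sample_motif_cassette(models[[r]]), collapse = "")
    start <- offset + nchar(nbs_seq) + 1
    motifs[[length(motifs) + 1L]] <- data.frame(
      motif = models[[r]]$name, start = start,
      end = start + nchar(cassette) - 1, stringsAsFactors = FALSE)
    nbs_seq <- paste0(nbs_seq, cassette)
    if (r != ranks[length(ranks)])
      nbs_seq <- paste0(nbs_seq, r_fill(sample(8:18, 1)))
  }
  motifs <- do.call(rbind, motifs)
  # C-terminal region
  cterm_seq <- ""
  lrr_iv <- NULL
  if (parts$cterm == "L") {
    pre <- r_fill(sample(5:12, 1))
    lrr <- r_lrr_region(6)
    post <- r_fill(sample(10:30, 1))
    base <- offset + nchar(nbs_seq)
    lrr_iv <- c(base + nchar(pre) + 1, base + nchar(pre) + nchar(lrr))
    cterm_seq <- paste0(pre, lrr, post)
  } else if (parts$cterm == "X") {
    cterm_seq <- r_fill(sample(110:160, 1))
  } else {
    cterm_seq <- r_fill(sample(40:90, 1))
  }
  sequence <- paste0(nterm_seq, nbs_seq, cterm_seq)
  layout <- list(motifs = motifs,
                 nbs = c(min(motifs$start), max(motifs$end)),
                 tir = tir_iv, cc = cc_iv, lrr = lrr_iv)
  list(sequence = sequence, layout = layout)
}

# intervals that must not be touched when mutating a gene copy
.protected_positions <- function(layout) {
  iv <- list(layout$tir, layout$cc, layout$lrr)
  pos <- unlist(lapply(seq_len(nrow(layout$motifs)), function(i)
    layout$motifs$start[i]:layout$motifs$end[i]))
  for (v in iv) if (!is.null(v)) pos <- c(pos, v[1]:v[2])
  unique(c(1L, pos))  # initial Met stays
}

# does this protein scan and classify to its intended label?
.verify_gene <- function(sequence, letter_code, regularity, layout, models) {
  cl <- tryCatch(
    classify_genes(stats::setNames(sequence, "g"), models = models),
    error = function(e) NULL)
  if (is.null(cl) || nrow(cl) != 1L) return(FALSE)
  ok <- cl$letter_code == letter_code && cl$regularity == regularity
  hits <- scan_nbs_motifs(sequence, models, gene_id = "g")
  ok && nrow(hits) == nrow(layout$motifs) &&
    all(hits$motif == layout$motifs$motif) &&
    all(hits$start == layout$motifs$start)
}

#' Generate one synthetic NBS gene
#'
#' Plants the cassettes required by a letter code and regularity: heptad
#' repeats for C/c (strong vs weak calibration), a TIR marker segment for
#' T, the five ordered NBS motif cassettes (regular) or a contiguous
#' end-truncated subset (non-regular), LRR repeats for L, and flank lengths
#' respecting the 100-residue rules. The assembled protein is verified to
#' scan and classify to its intended label; the random parts are resampled
#' on the rare failure.
#'
#' @param letter_code Target letter code.
#' @param regularity `"regular"` or `"non-regular"`.
#' @param truncation For non-regular genes, the canonical motif ranks kept
#'   (a contiguous range); default: sampled from the truncation patterns
#'   that drop motifs from one or both ends.
#' @param models Motif models.
#' @param max_tries Resampling budget.
#' @return List: `sequence`, `layout` (planted motif/domain coordinates),
#'   `letter_code`, `regularity`.
#' @export
generate_gene <- function(letter_code, regularity = "regular",
                          truncation = NULL, models = nbs_motif_models(),
                          max_tries = 50) {
  regularity <- match.arg(regularity, c("regular", "non-regular"))
  if (regularity == "regular") {
    if (!is.null(truncation) && !identical(as.integer(truncation), 1:5))
      stop("contradictory spec: a regular gene carries all five motifs")
    truncation <- 1:5
  }
  for (try in seq_len(max_tries)) {
    trunc <- if (is.null(truncation))
      .truncation_options[[sample(length(.truncation_options), 1)]]
    else truncation
    g <- .assemble_gene(letter_code, regularity, trunc, models)
    if (.verify_gene(g$sequence, letter_code, regularity, g$layout, models))
      return(list(sequence = g$sequence, layout = g$layout,
                  letter_code = letter_code, regularity = regularity))
  }
  stop("failed to realize class ", letter_code, " (", regularity,
       ") in ", max_tries, " attempts")
}

#' Mutate a protein to a target alignment identity
#'
#' Substitutes `round((1 - target) * length)` positions (no indels), chosen
#' outside `protected` positions, each to a uniformly chosen different
#' residue. Because there are no indels the post-alignment identity equals
#' `1 - k/L` exactly, within 1/(2L) of the target.
#'
#' @param sequence Protein sequence.
#' @param target Target identity in (0, 1].
#' @param protected Integer positions that must not be mutated.
#' @return Mutated sequence.
#' @export
mutate_to_identity <- function(sequence, target, protected = integer(0)) {
  if (!is.numeric(target) || target <= 0 || target > 1)
    stop("target identity must be in (0, 1]")
  s <- .seq_chars(sequence)
  L <- length(s)
  k <- round((1 - target) * L)
  if (k == 0) return(sequence)
  eligible <- setdiff(seq_len(L), protected)
  if (k > length(eligible))
    stop("cannot reach target identity: too few unprotected positions")
  pos <- sample(eligible, k)
  for (i in pos) s[i] <- sample(setdiff(AA20, s[i]), 1)
  paste(s, collapse = "")
}

#' Default per-class gene counts for the synthetic genome
#'
#' @return `data.frame(letter_code, regularity, n)` totalling 60 genes
#'   (33 regular, 27 non-regular) across 26 class cells.
#' @export
default_class_table <- function() {
  reg <- data.frame(
    letter_code = c("CNL", "CN", "CNX", "cNL", "cNX", "TNL", "TN", "TNX",
                    "N", "NL", "NX"),
    regularity = "regular",
    n = c(7, 2, 2, 5, 2, 6, 2, 2, 1, 2, 2))
  non <- data.frame(
    letter_code = c("CN", "CNL", "CNX", "cN", "cNL", "cNX", "TN", "TNL",
                    "TNX", "XN", "XNL", "XNX", "N", "NL", "NX"),
    regularity = "non-regular",
    n = c(2, 2, 2, 3, 2, 2, 2, 2, 2, 2, 2, 1, 1, 1, 1))
  rbind(reg, non)
}

#' Default cluster layout for the synthetic genome
#'
#' @return `data.frame(cluster_key, seq_id, size)`: five clusters of sizes
#'   12/8/10/6/5; the remaining genes are placed as isolated singletons.
#' @export
default_cluster_spec <- function() {
  data.frame(cluster_key = paste0("K", 1:5),
             seq_id = c("chr1", "chr1", "chr2", "chr2", "scf2"),
             size = c(12, 8, 10, 6, 5), stringsAsFactors = FALSE)
}

#' Default duplicate-family specification
#'
#' @return `data.frame(family_key, size, identity, letter_code, regularity,
#'   cluster_key)`: four families whose members are placed adjacently
#'   inside clusters.
#' @export
default_family_spec <- function() {
  data.frame(family_key = paste0("F", 1:4),
             size = c(2, 2, 3, 4),
             identity = c(0.90, 0.85, 0.88, 0.92),
             letter_code = c("CNL", "cNL", "TNL", "CNL"),
             regularity = "regular",
             cluster_key = c("K1", "K2", "K3", "K1"),
             stringsAsFactors = FALSE)
}

#' Default marker specification
#'
#' @return List of per-category marker counts and placement ranges.
#' @export
default_marker_spec <- function() {
  list(n_within = 14, n_outside = 6, n_small_scaffold = 5,
       n_scaffold_with_nbs = 2, n_unplaced = 3,
       primer_len = 20, size_range = c(150, 500),
       within_offset = c(5e4, 2.5e6), outside_margin = 3.2e6)
}

#' Synthetic genome configuration
#'
#' The defaults define the package's reference study conditions: two 9-Mb
#' chromosomes plus three scaffolds (1.5/1.8/1.2 Mb), 60 genes in 26 class
#' cells, five clusters, four duplicate families and 30 QTL markers.
#'
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the configuration.
#' @param chromosomes Named lengths of chromosome sequences.
#' @param scaffolds Named lengths of scaffold sequences; `scf1` carries no
#'   genes, `scf2` carries a gene cluster, `scf3` a singleton gene.
#' @param classes Per-class gene counts ([default_class_table()]).
#' @param clusters Cluster layout ([default_cluster_spec()]).
#' @param families Duplicate families ([default_family_spec()]).
#' @param markers Marker specification ([default_marker_spec()]).
#' @return `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       chromosomes = c(chr1 = 9e6, chr2 = 9e6),
                       scaffolds = c(scf1 = 1.5e6, scf2 = 1.8e6,
                                     scf3 = 1.2e6),
                       classes = default_class_table(),
                       clusters = default_cluster_spec(),
                       families = default_family_spec(),
                       markers = default_marker_spec()) {
  stopifnot(all(classes$n >= 0), all(clusters$size >= 2),
            all(families$identity > 0), all(families$identity <= 1),
            all(chromosomes > 0), all(scaffolds > 0))
  structure(list(seed = seed, chromosomes = chromosomes,
                 scaffolds = scaffolds, classes = classes,
                 clusters = clusters, families = families,
                 markers = markers),
            class = "sim_config")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome with planted truth
#'
#' Builds proteins for every configured class cell, realizes the duplicate
#' families by mutating a family seed to the target identity (outside the
#' planted cassettes), lays the genes out as the configured clusters
#' (adjacent gaps well under the 200-kb rule, everything else well over),
#' derives marker primer pairs from the genome sequence at controlled
#' distances from genes, and emits the evidence table an annotation tool
#' would produce. Everything is a deterministic function of the config.
#'
#' @param config [sim_config()].
#' @return List: `genome` (named character), `seqinfo`, `loci`, `proteins`,
#'   `evidence`, `primers`, `truth` (classes, clusters, families, markers),
#'   `config`.
#' @export
generate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  models <- nbs_motif_models()
  classes <- config$classes
  fams <- config$families

  # ---- roster: one row per gene, family members tagged
  roster <- do.call(rbind, lapply(seq_len(nrow(classes)), function(i) {
    if (classes$n[i] == 0) return(NULL)
    data.frame(letter_code = classes$letter_code[i],
               regularity = classes$regularity[i],
               idx = seq_len(classes$n[i]), stringsAsFactors = FALSE)
  }))
  roster$family_key <- NA_character_
  roster$family_role <- NA_integer_
  for (f in seq_len(nrow(fams))) {
    free <- which(roster$letter_code == fams$letter_code[f] &
                    roster$regularity == fams$regularity[f] &
                    is.na(roster$family_key))
    if (length(free) < fams$size[f])
      stop("family ", fams$family_key[f], " needs more ",
           fams$letter_code[f], " genes than configured")
    take <- free[seq_len(fams$size[f])]
    roster$family_key[take] <- fams$family_key[f]
    roster$family_role[take] <- seq_len(fams$size[f])
  }
  n_genes <- nrow(roster)
  roster$gene_id <- sprintf("GrN%03d", seq_len(n_genes))

  # ---- proteins: family seeds and singles generated, members mutated
  proteins <- character(n_genes)
  layouts <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    if (!is.na(roster$family_key[i]) && roster$family_role[i] > 1L) next
    g <- generate_gene(roster$letter_code[i], roster$regularity[i],
                       models = models)
    proteins[i] <- g$sequence
    layouts[[i]] <- g$layout
  }
  for (i in seq_len(n_genes)) {
    if (is.na(roster$family_key[i]) || roster$family_role[i] == 1L) next
    f <- fams[fams$family_key == roster$family_key[i], ]
    seed_i <- which(roster$family_key == roster$family_key[i] &
                      roster$family_role == 1L)
    prot <- .protected_positions(layouts[[seed_i]])
    for (try in 1:50) {
      cand <- mutate_to_identity(proteins[seed_i], f$identity, prot)
      if (.verify_gene(cand, roster$letter_code[i], roster$regularity[i],
                       layouts[[seed_i]], models)) {
        proteins[i] <- cand
        layouts[[i]] <- layouts[[seed_i]]
        break
      }
      if (try == 50) stop("failed to realize family member for ",
                          roster$gene_id[i])
    }
  }
  names(proteins) <- roster$gene_id

  # ---- genomic layout: cluster slots then singletons
  cl <- config$clusters
  slots <- list()  # per gene: seq_id, cluster_key (NA for singles)
  # family members occupy consecutive slots of their configured cluster
  assignment <- rep(NA_integer_, n_genes)  # slot index per gene
  slot_tab <- do.call(rbind, lapply(seq_len(nrow(cl)), function(k)
    data.frame(seq_id = cl$seq_id[k], cluster_key = cl$cluster_key[k],
               pos = seq_len(cl$size[k]), stringsAsFactors = FALSE)))
  chroms <- names(config$chromosomes)
  n_cluster_slots <- nrow(slot_tab)
  n_singles <- n_genes - n_cluster_slots
  if (n_singles < 1) stop("more cluster slots than genes")
  # singleton slots: scf3 gets one, the rest split across chromosomes
  single_seq <- c(rep(chroms, length.out = n_singles - 1L), "scf3")
  slot_tab <- rbind(slot_tab,
                    data.frame(seq_id = single_seq, cluster_key = NA,
                               pos = NA, stringsAsFactors = FALSE))
  # place families first (consecutive cluster slots), then everyone else
  taken <- logical(nrow(slot_tab))
  for (f in seq_len(nrow(fams))) {
    members <- which(roster$family_key == fams$family_key[f])
    kslots <- which(slot_tab$cluster_key %in% fams$cluster_key[f] & !taken)
    if (length(kslots) < length(members))
      stop("cluster ", fams$cluster_key[f], " too small for family ",
           fams$family_key[f])
    use <- kslots[seq_along(members)]
    assignment[members] <- use
    taken[use] <- TRUE
  }
  rest <- which(is.na(assignment))
  freeslots <- which(!taken)
  assignment[rest] <- sample(freeslots, length(freeslots))
  slot_tab$gene <- NA_integer_
  slot_tab$gene[assignment] <- seq_len(n_genes)

  # ---- coordinates
  seqlens <- c(config$chromosomes, config$scaffolds)
  loci <- list()
  for (sid in names(seqlens)) {
    rows <- which(slot_tab$seq_id == sid)
    if (!length(rows)) next
    # order: clusters first (in spec order), then singles
    rows <- rows[order(is.na(slot_tab$cluster_key[rows]),
                       slot_tab$cluster_key[rows], slot_tab$pos[rows])]
    pos <- 200000
    prev_key <- "<start>"
    for (r in rows) {
      key <- ifelse(is.na(slot_tab$cluster_key[r]), "<single>",
                    slot_tab$cluster_key[r])
      gap <- if (key == prev_key && key != "<single>")
        sample(5000:30000, 1) else sample(250000:350000, 1)
      start <- pos + gap
      gi <- slot_tab$gene[r]
      glen <- nchar(proteins[gi]) * 3L
      loci[[length(loci) + 1L]] <- data.frame(
        gene_id = roster$gene_id[gi], seq_id = sid, start = start,
        end = start + glen - 1L, strand = sample(c("+", "-"), 1),
        cluster_key = slot_tab$cluster_key[r], stringsAsFactors = FALSE)
      pos <- start + glen - 1L
      prev_key <- key
    }
    if (grepl("^chr", sid) && pos > seqlens[[sid]] - 3.6e6)
      stop("gene layout overruns chromosome ", sid)
    if (pos > seqlens[[sid]] - 1e5)
      stop("gene layout overruns sequence ", sid)
  }
  loci <- do.call(rbind, loci)
  rownames(loci) <- NULL

  # ---- genome sequence
  genome <- vapply(names(seqlens), function(sid) random_dna(seqlens[[sid]]),
                   character(1))
  seqinfo <- data.frame(seq_id = names(seqlens),
                        length = as.integer(seqlens),
                        is_chromosome = grepl("^chr", names(seqlens)),
                        stringsAsFactors = FALSE)

  # ---- markers: primers read off the genome at controlled positions
  ms <- config$markers
  plen <- ms$primer_len
  marker_rows <- list()
  truth_markers <- list()
  add_marker <- function(mid, sid, pstart, size, category, trait) {
    pend <- pstart + size - 1L
    fwd <- substr(genome[[sid]], pstart, pstart + plen - 1L)
    rev <- .revcomp(substr(genome[[sid]], pend - plen + 1L, pend))
    marker_rows[[length(marker_rows) + 1L]] <<- data.frame(
      marker_id = mid, fwd = fwd, rev = rev, trait = trait,
      stringsAsFactors = FALSE)
    truth_markers[[length(truth_markers) + 1L]] <<- data.frame(
      marker_id = mid, category = category, seq_id = sid,
      start = pstart, end = pend, size = size, stringsAsFactors = FALSE)
  }
  traits <- c("VW", "FW", "RKN")
  mk <- 0L
  for (i in seq_len(ms$n_within)) {
    mk <- mk + 1L
    sid <- chroms[1L + (i - 1L) %% length(chroms)]
    g <- loci[loci$seq_id == sid, ]
    gi <- g[sample(nrow(g), 1), ]
    size <- sample(ms$size_range[1]:ms$size_range[2], 1)
    off <- sample(ms$within_offset[1]:ms$within_offset[2], 1)
    pstart <- if (gi$start - off - size > 1000 && sample(2, 1) == 1)
      gi$start - off - size else gi$end + off
    add_marker(sprintf("MK%02d", mk), sid, pstart, size, "within_flank",
               sample(traits, 1))
  }
  for (i in seq_len(ms$n_outside)) {
    mk <- mk + 1L
    sid <- chroms[1L + (i - 1L) %% length(chroms)]
    far_from <- max(loci$end[loci$seq_id == sid]) + ms$outside_margin
    size <- sample(ms$size_range[1]:ms$size_range[2], 1)
    pstart <- sample(far_from:(seqlens[[sid]] - size - 1000), 1)
    add_marker(sprintf("MK%02d", mk), sid, pstart, size, "outside_flank",
               sample(traits, 1))
  }
  for (i in seq_len(ms$n_small_scaffold)) {
    mk <- mk + 1L
    size <- sample(ms$size_range[1]:ms$size_range[2], 1)
    pstart <- sample(1e5:(seqlens[["scf1"]] - size - 1000), 1)
    add_marker(sprintf("MK%02d", mk), "scf1", pstart, size,
               "small_scaffold_no_nbs", sample(traits, 1))
  }
  for (i in seq_len(ms$n_scaffold_with_nbs)) {
    mk <- mk + 1L
    size <- sample(ms$size_range[1]:ms$size_range[2], 1)
    pstart <- sample(1e5:(seqlens[["scf2"]] - size - 1000), 1)
    add_marker(sprintf("MK%02d", mk), "scf2", pstart, size,
               "scaffold_with_nbs", sample(traits, 1))
  }
  for (i in seq_len(ms$n_unplaced)) {
    mk <- mk + 1L
    for (try in 1:10) {
      fwd <- random_dna(plen)
      rev <- random_dna(plen)
      hits <- epcr(genome, fwd, rev, marker_id = "probe")
      if (!nrow(hits)) break
      if (try == 10) stop("could not realize an unplaceable marker")
    }
    marker_rows[[length(marker_rows) + 1L]] <- data.frame(
      marker_id = sprintf("MK%02d", mk), fwd = fwd, rev = rev,
      trait = sample(traits, 1), stringsAsFactors = FALSE)
    truth_markers[[length(truth_markers) + 1L]] <- data.frame(
      marker_id = sprintf("MK%02d", mk), category = "unplaced",
      seq_id = NA_character_, start = NA_integer_, end = NA_integer_,
      size = NA_integer_, stringsAsFactors = FALSE)
  }
  primers <- do.call(rbind, marker_rows)
  truth_markers <- do.call(rbind, truth_markers)

  # ---- evidence table (what an annotation tool would report)
  evidence <- list()
  for (i in seq_len(n_genes)) {
    g <- roster$gene_id[i]
    lay <- layouts[[i]]
    evidence[[length(evidence) + 1L]] <- data.frame(
      gene_id = g, accession = "PF00931", name = "NB-ARC",
      start = lay$nbs[1], end = lay$nbs[2], score = 1e-30,
      stringsAsFactors = FALSE)
    if (!is.null(lay$tir))
      evidence[[length(evidence) + 1L]] <- data.frame(
        gene_id = g, accession = "SYN_TIR", name = "TIR",
        start = lay$tir[1], end = lay$tir[2], score = 1e-20,
        stringsAsFactors = FALSE)
    if (!is.null(lay$lrr))
      evidence[[length(evidence) + 1L]] <- data.frame(
        gene_id = g, accession = "SYN_LRR", name = "LRR",
        start = lay$lrr[1], end = lay$lrr[2], score = 1e-10,
        stringsAsFactors = FALSE)
  }
  evidence <- do.call(rbind, evidence)

  truth <- list(
    classes = data.frame(gene_id = roster$gene_id,
                         letter_code = roster$letter_code,
                         regularity = roster$regularity,
                         stringsAsFactors = FALSE),
    clusters = loci[!is.na(loci$cluster_key),
                    c("gene_id", "cluster_key")],
    families = data.frame(
      gene_id = roster$gene_id[!is.na(roster$family_key)],
      family_key = roster$family_key[!is.na(roster$family_key)],
      stringsAsFactors = FALSE),
    markers = truth_markers)
  loci$cluster_key <- NULL

  list(genome = genome, seqinfo = seqinfo, loci = loci,
       proteins = proteins, evidence = evidence, primers = primers,
       truth = truth, config = config)
}

#' Write a synthetic genome to files
#'
#' Emits the standard file formats for a real-data run: genome FASTA, gene
#' GFF3, protein FASTA, domain-evidence TSV, primer TSV, and plain-text
#' truth tables.
#'
#' @param sim Output of [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
  prot <- Biostrings::AAStringSet(sim$proteins)
  Biostrings::writeXStringSet(prot, file.path(dir, "proteins.faa"))
  gr <- GenomicRanges::GRanges(
    seqnames = sim$loci$seq_id,
    ranges = IRanges::IRanges(sim$loci$start, sim$loci$end),
    strand = sim$loci$strand, type = "gene", ID = sim$loci$gene_id)
  rtracklayer::export(gr, file.path(dir, "genes.gff3"), format = "gff3")
  utils::write.table(sim$evidence, file.path(dir, "evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$primers, file.path(dir, "primers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$seqinfo, file.path(dir, "seqinfo.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(sim$truth))
    utils::write.table(sim$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
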