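# Domain evidence: built-in scanners, ingestion of tool output, and the
# NBS-gene qualification filter.

# Synthetic marker cassettes for TIR and LRR. The TIR cassette is a fixed
# 60-residue segment (synthetic, TIR-flavoured); the LRR consensus is the
# classical LxxLxLxxNxL repeat unit. Both are registered in the default
# accession map so ingestion mode and built-in mode exercise the same
# classifier paths.
TIR_CONSENSUS <- paste0(
  "YDVFPSFRGEDVRKGFLSHLWKEFQRKGIEVFMDNNIERGESIGPELVRAIEESQIAIVV")
LRR_UNIT_PATTERN <- "LxxLxLxxNxL"

#' Default accession-to-domain-type map
#'
#' Maps common Pfam accessions (and the package's synthetic marker
#' accessions) to domain types. Unknown accessions resolve to `OTHER` and
#' never block classification.
#'
#' @return `data.frame(accession, domain_type)`.
#' @export
default_accession_map <- function() {
  data.frame(
    accession = c("PF00931", "PF01582", "PF13676",
                  "PF00560", "PF07725", "PF12799", "PF13306", "PF13855",
                  "SYN_NBS", "SYN_TIR", "SYN_LRR"),
    domain_type = c("NBS", "TIR", "TIR",
                    "LRR", "LRR", "LRR", "LRR", "LRR",
                    "NBS", "TIR", "LRR"),
    stringsAsFactors = FALSE)
}

.empty_evidence <- function() {
  data.frame(gene_id = character(), domain_type = character(),
             accession = character(), name = character(),
             start = integer(), end = integer(), score = numeric(),
             source = character(), stringsAsFactors = FALSE)
}

#' Ingest an InterProScan-style domain TSV
#'
#' Expects a tab-separated file with header columns `gene_id`, `accession`,
#' `name`, `start`, `end`, `score` (1-based inclusive residue coordinates).
#' Accessions are resolved through `accession_map`; unknown accessions are
#' retained with `domain_type = "OTHER"`.
#'
#' @param path File path.
#' @param accession_map Accession-to-type table
#'   (default [default_accession_map()]).
#' @param proteins Optional protein set; when given, intervals are checked
#'   against protein lengths.
#' @return Evidence `data.frame(gene_id, domain_type, accession, name,
#'   start, end, score, source)` with `source = "ingested"`.
#' @export
ingest_domain_tsv <- function(path, accession_map = default_accession_map(),
                              proteins = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "accession", "name", "start", "end", "score")
  if (!all(need %in% names(d)))
    stop("domain TSV must have columns: ", paste(need, collapse = ", "))
  if (!nrow(d)) return(.empty_evidence())
  for (i in seq_len(nrow(d))) {
    line <- i + 1L  # header is line 1
    if (is.na(d$start[i]) || is.na(d$end[i]))
      stop("unparseable coordinates at line ", line)
    if (d$end[i] < d$start[i] || d$start[i] < 1)
      stop("coordinate error at line ", line, ": end < start or start < 1")
  }
  if (!is.null(proteins)) {
    proteins <- as_protein_set(proteins)
    known <- d$gene_id %in% names(proteins)
    too_long <- known & d$end > nchar(proteins)[match(d$gene_id, names(proteins))]
    if (any(too_long))
      stop("interval outside protein at line ",
           paste(which(too_long) + 1L, collapse = ", "))
  }
  type <- accession_map$domain_type[match(d$accession, accession_map$accession)]
  type[is.na(type)] <- "OTHER"
  data.frame(gene_id = d$gene_id, domain_type = type, accession = d$accession,
             name = d$name, start = as.integer(d$start),
             end = as.integer(d$end), score = as.numeric(d$score),
             source = "ingested", stringsAsFactors = FALSE)
}

#' Ingest BLAST tabular (outfmt 6) homology hits
#'
#' @param path Path to a 12-column BLAST tabular file (qseqid sseqid pident
#'   length mismatch gapopen qstart qend sstart send evalue bitscore), no
#'   header.
#' @return Data frame with the 12 standard columns.
#' @export
ingest_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) != 12L) stop("BLAST tabular file must have 12 columns")
  names(d) <- cols
  d
}

#' Homology filter parameters
#'
#' @param evalue_cutoff E-value cutoff for ingested BLAST hits
#'   (default 1e-15).
#' @param min_bitscore Raw local-alignment score threshold for the built-in
#'   homology screen (default 80, BLOSUM62 units).
#' @return Parameter list.
#' @export
homology_params <- function(evalue_cutoff = 1e-15, min_bitscore = 80) {
  stopifnot(evalue_cutoff > 0)
  list(evalue_cutoff = evalue_cutoff, min_bitscore = min_bitscore)
}

#' Built-in homology screen against reference resistance proteins
#'
#' Desk-scale stand-in for a database BLAST search: each protein is aligned
#' locally (Smith-Waterman via [Biostrings::pairwiseAlignment], BLOSUM62)
#' against each reference; the best score is reported per gene. E-values are
#' not computed (no database size at desk scale); qualification uses the raw
#' score against `min_bitscore`.
#'
#' @param proteins Protein set (named character vector or `AAStringSet`).
#' @param references Reference resistance proteins, same container types.
#' @return `data.frame(qseqid, sseqid, evalue, bitscore)` with one row per
#'   gene (its best-scoring reference); `evalue` is `NA`.
#' @export
homology_screen <- function(proteins, references) {
  proteins <- as_protein_set(proteins)
  references <- as_protein_set(references)
  out <- lapply(names(proteins), function(g) {
    sc <- vapply(references, function(r)
      Biostrings::pairwiseAlignment(proteins[[g]], r, type = "local",
                                    substitutionMatrix = .blosum62(),
                                    gapOpening = 10, gapExtension = 2,
                                    scoreOnly = TRUE), numeric(1))
    best <- which.max(sc)
    data.frame(qseqid = g, sseqid = names(references)[best],
               evalue = NA_real_, bitscore = sc[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Built-in TIR scanner: best sliding-window identity to the marker cassette.
scan_tir <- function(sequence, consensus = TIR_CONSENSUS, min_identity = 0.75) {
  s <- .seq_chars(toupper(sequence))
  cc <- .seq_chars(consensus)
  w <- length(cc)
  if (length(s) < w) return(NULL)
  n_off <- length(s) - w + 1L
  sc <- numeric(n_off)
  for (p in seq_len(w)) sc <- sc + (s[p:(p + n_off - 1L)] == cc[p])
  sc <- sc / w
  best <- which.max(sc)
  if (sc[best] < min_identity) return(NULL)
  list(start = best, end = best + w - 1L, score = sc[best])
}

# Built-in LRR scanner: >= min_units matches of the LxxLxLxxNxL unit.
scan_lrr <- function(sequence, min_units = 2, max_unit_gap = 30) {
  s <- .seq_chars(toupper(sequence))
  w <- 11L
  if (length(s) < w) return(NULL)
  n_off <- length(s) - w + 1L
  ok <- s[1:n_off] == "L" & s[4:(n_off + 3L)] == "L" &
    s[6:(n_off + 5L)] == "L" & s[9:(n_off + 8L)] == "N" &
    s[11:(n_off + 10L)] == "L"
  starts <- which(ok)
  if (length(starts) < min_units) return(NULL)
  # largest run of matches whose successive starts are close
  grp <- cumsum(c(1L, diff(starts) > max_unit_gap))
  runs <- split(starts, grp)
  runs <- runs[vapply(runs, length, integer(1)) >= min_units]
  if (!length(runs)) return(NULL)
  r <- runs[[which.max(vapply(runs, length, integer(1)))]]
  list(start = r[1], end = r[length(r)] + w - 1L,
       score = length(r))
}

#' Built-in domain scan of a protein set
#'
#' Produces per-gene evidence without external tools: NBS evidence as the
#' span of the selected motif chain, TIR/LRR evidence from the built-in
#' marker scanners, CC evidence as maximal segments of the coiled-coil
#' profile at its lowest threshold. Also returns the motif hits and CC
#' profiles used downstream by the classifier.
#'
#' @param proteins Protein set (named character vector or `AAStringSet`).
#' @param models Motif models (default [nbs_motif_models()]).
#' @param cc_window Coiled-coil window (default 21).
#' @param tir_min_identity Identity threshold for the TIR marker scanner
#'   (default 0.75).
#' @return A `domain_scan` list: `evidence` (data frame), `motif_hits`
#'   (data frame), `cc_profiles` (named list of `cc_profile`).
#' @export
scan_domains <- function(proteins, models = nbs_motif_models(),
                         cc_window = 21, tir_min_identity = 0.75) {
  proteins <- as_protein_set(proteins)
  ev <- list()
  hits <- list()
  profiles <- list()
  for (g in names(proteins)) {
    seq <- proteins[[g]]
    h <- scan_nbs_motifs(seq, models, gene_id = g)
    hits[[g]] <- h
    if (nrow(h)) {
      ev[[length(ev) + 1L]] <- data.frame(
        gene_id = g, domain_type = "NBS", accession = "SYN_NBS",
        name = "NBS", start = min(h$start), end = max(h$end),
        score = sum(h$score), source = "builtin", stringsAsFactors = FALSE)
    }
    tir <- scan_tir(seq, min_identity = tir_min_identity)
    if (!is.null(tir)) {
      ev[[length(ev) + 1L]] <- data.frame(
        gene_id = g, domain_type = "TIR", accession = "SYN_TIR",
        name = "TIR", start = tir$start, end = tir$end, score = tir$score,
        source = "builtin", stringsAsFactors = FALSE)
    }
    lrr <- scan_lrr(seq)
    if (!is.null(lrr)) {
      ev[[length(ev) + 1L]] <- data.frame(
        gene_id = g, domain_type = "LRR", accession = "SYN_LRR",
        name = "LRR", start = lrr$start, end = lrr$end, score = lrr$score,
        source = "builtin", stringsAsFactors = FALSE)
    }
    prof <- suppressWarnings(score_coiled_coil(seq, window = cc_window,
                                               gene_id = g))
    profiles[[g]] <- prof
    seg <- cc_segments(prof, thresholds = min(prof$thresholds))
    if (nrow(seg)) {
      ev[[length(ev) + 1L]] <- data.frame(
        gene_id = g, domain_type = "CC", accession = "SYN_CC",
        name = "CC", start = seg$start, end = seg$end, score = seg$max_prob,
        source = "builtin", stringsAsFactors = FALSE)
    }
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else .empty_evidence()
  rownames(evidence) <- NULL
  motif_hits <- do.call(rbind, hits)
  rownames(motif_hits) <- NULL
  structure(list(evidence = evidence, motif_hits = motif_hits,
                 cc_profiles = profiles),
            class = "domain_scan")
}

#' Qualify NBS-encoding genes
#'
#' A gene qualifies when it carries NBS domain evidence; when homology hits
#' are supplied, it must additionally hit a reference resistance protein at
#' `evalue <= evalue_cutoff` (ingested BLAST hits) or at
#' `bitscore >= min_bitscore` (built-in screen rows, which have `NA`
#' e-values).
#'
#' @param evidence Evidence data frame (ingested and/or builtin).
#' @param hits Optional homology hits ([ingest_blast_tab()] or
#'   [homology_screen()] output).
#' @param params [homology_params()].
#' @return Sorted character vector of qualifying gene ids (possibly empty).
#' @export
qualify_nbs_genes <- function(evidence, hits = NULL,
                              params = homology_params()) {
  with_nbs <- unique(evidence$gene_id[evidence$domain_type == "NBS"])
  if (is.null(hits)) return(sort(with_nbs))
  ok <- ifelse(is.na(hits$evalue),
               hits$bitscore >= params$min_bitscore,
               hits$evalue <= params$evalue_cutoff)
  passing <- unique(hits$qseqid[ok])
  sort(intersect(with_nbs, passing))
}

# BLOSUM62 substitution matrix from Biostrings, loaded once.
.blosum_env <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_env$mat <- e$BLOSUM62
  }
  .blosum_env$mat
}
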