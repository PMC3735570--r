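# Regularity assessment and letter-code classification.
#
# A gene is "regular" when all five NBS motifs are present in canonical
# order and the ORF is complete (initial Met, no internal stop); otherwise
# it is "non-regular" and carries the ordered motif subset it retains.
# The letter code composes an N-terminal code (T for TIR, C/c for strong/
# weak coiled-coil, X for a long undescribed N-terminus, or nothing), the
# mandatory "N", and a C-terminal code (L for LRR, X for a long undescribed
# C-terminus, or nothing): CNL, cNX, TN, XNX, N, ...

#' Classifier parameters
#'
#' @param cc_major_threshold Coiled-coil probability for a capital `C`
#'   (default 0.90).
#' @param cc_minor_thresholds Lower thresholds any of which yields a
#'   lower-case `c` (default 0.50, 0.10, 0.02).
#' @param min_flank_len Strict minimum flank length (in residues) for an `X`
#'   code (default 100: a flank must exceed 100 residues).
#' @param tir_priority When both TIR and CC are detected, `T` wins
#'   (default TRUE).
#' @return Parameter list.
#' @export
classifier_params <- function(cc_major_threshold = 0.90,
                              cc_minor_thresholds = c(0.50, 0.10, 0.02),
                              min_flank_len = 100,
                              tir_priority = TRUE) {
  stopifnot(min_flank_len > 0,
            all(cc_minor_thresholds < cc_major_threshold))
  list(cc_major_threshold = cc_major_threshold,
       cc_minor_thresholds = sort(cc_minor_thresholds),
       min_flank_len = min_flank_len,
       tir_priority = tir_priority)
}

#' Assess NBS regularity from motif hits
#'
#' @param hits Motif hits for one gene, as returned by [scan_nbs_motifs()]
#'   (already colinear and in canonical order).
#' @param sequence The gene's protein sequence (for the ORF check).
#' @return List: `regularity` ("regular"/"non-regular"), `motif_subset`
#'   (ordered character vector), `subset_contiguous` (logical; `NA` when
#'   fewer than one motif).
#' @export
assess_regularity <- function(hits, sequence) {
  ranks <- match(hits$motif, NBS_MOTIF_NAMES)
  ranks <- sort(ranks)
  subset <- NBS_MOTIF_NAMES[ranks]
  contiguous <- if (length(ranks)) all(diff(ranks) == 1L) else NA
  regular <- length(ranks) == 5L && orf_complete(sequence)
  list(regularity = if (regular) "regular" else "non-regular",
       motif_subset = subset,
       subset_contiguous = contiguous)
}

#' Assign the N-terminal letter code
#'
#' Evidence and coiled-coil signal are restricted to residues strictly
#' before the NBS start. Priority: `T` (TIR evidence), `C` (coiled-coil at
#' the major threshold), `c` (coiled-coil at any minor threshold), `X`
#' (flank longer than `min_flank_len` with no known domain), otherwise no
#' code.
#'
#' @param nbs_start 1-based start of the NBS domain.
#' @param evidence Evidence rows for this gene.
#' @param cc_profile Optional `cc_profile`; when `NULL`, CC-type evidence
#'   rows (score interpreted as probability) are used instead.
#' @param params [classifier_params()].
#' @return One of `"T"`, `"C"`, `"c"`, `"X"`, `""`.
#' @export
assign_nterm_code <- function(nbs_start, evidence, cc_profile = NULL,
                              params = classifier_params()) {
  if (is.na(nbs_start) || nbs_start < 1)
    stop("classification error: gene lacks an NBS domain interval")
  flank_len <- nbs_start - 1L
  before <- evidence[evidence$end < nbs_start, , drop = FALSE]
  has_tir <- any(before$domain_type == "TIR")
  cc_max <- 0
  if (flank_len >= 1L) {
    if (!is.null(cc_profile)) {
      cc_max <- max(cc_profile$prob[seq_len(flank_len)])
    } else {
      cc <- before[before$domain_type == "CC", , drop = FALSE]
      if (nrow(cc)) cc_max <- max(cc$score)
    }
  }
  if (params$tir_priority && has_tir) return("T")
  if (cc_max >= params$cc_major_threshold) return("C")
  if (has_tir) return("T")
  if (cc_max >= min(params$cc_minor_thresholds)) return("c")
  if (flank_len > params$min_flank_len) return("X")
  ""
}

#' Assign the C-terminal letter code
#'
#' Evidence restricted to residues strictly after the NBS end. `L` when LRR
#' evidence is present, `X` when the remaining C-terminal part exceeds
#' `min_flank_len` residues, otherwise no code.
#'
#' @param nbs_end 1-based end of the NBS domain.
#' @param protein_len Protein length in residues.
#' @param evidence Evidence rows for this gene.
#' @param params [classifier_params()].
#' @return One of `"L"`, `"X"`, `""`.
#' @export
assign_cterm_code <- function(nbs_end, protein_len, evidence,
                              params = classifier_params()) {
  after <- evidence[evidence$start > nbs_end, , drop = FALSE]
  if (any(after$domain_type == "LRR")) return("L")
  if (protein_len - nbs_end > params$min_flank_len) return("X")
  ""
}

#' Classify one gene
#'
#' @param gene_id Gene id.
#' @param sequence Protein sequence.
#' @param evidence Evidence rows for this gene (builtin and/or ingested).
#' @param hits Motif hits for this gene (from [scan_nbs_motifs()]).
#' @param cc_profile Optional `cc_profile` for this gene.
#' @param params [classifier_params()].
#' @return One-row classification data frame.
#' @export
classify_gene <- function(gene_id, sequence, evidence, hits,
                          cc_profile = NULL, params = classifier_params()) {
  nbs <- evidence[evidence$domain_type == "NBS", , drop = FALSE]
  if (nrow(nbs)) {
    nbs_start <- min(nbs$start)
    nbs_end <- max(nbs$end)
  } else if (nrow(hits)) {
    nbs_start <- min(hits$start)
    nbs_end <- max(hits$end)
  } else {
    stop("classification error: gene ", gene_id,
         " has no NBS evidence (should not have qualified)")
  }
  reg <- assess_regularity(hits, sequence)
  nterm <- assign_nterm_code(nbs_start, evidence, cc_profile, params)
  cterm <- assign_cterm_code(nbs_end, nchar(sequence), evidence, params)
  data.frame(gene_id = gene_id,
             regularity = reg$regularity,
             letter_code = paste0(nterm, "N", cterm),
             nterm_code = nterm, cterm_code = cterm,
             motif_subset = paste(reg$motif_subset, collapse = ","),
             n_motifs = length(reg$motif_subset),
             subset_contiguous = reg$subset_contiguous,
             nbs_start = nbs_start, nbs_end = nbs_end,
             stringsAsFactors = FALSE)
}

#' Classify a set of qualified NBS genes
#'
#' Runs the motif scanner and coiled-coil scorer on every protein; TIR, LRR
#' and NBS interval evidence comes from `evidence` when supplied (ingestion
#' mode) and from the built-in scanners otherwise. Every gene receives
#' exactly one letter code.
#'
#' @param proteins Protein set (named character vector or `AAStringSet`),
#'   already restricted to qualified genes.
#' @param evidence Optional ingested evidence data frame; `NULL` uses the
#'   built-in scanners.
#' @param params [classifier_params()].
#' @param models Motif models.
#' @param cc_window Coiled-coil window.
#' @return Classification data frame, one row per gene.
#' @export
classify_genes <- function(proteins, evidence = NULL,
                           params = classifier_params(),
                           models = nbs_motif_models(), cc_window = 21) {
  proteins <- as_protein_set(proteins)
  scan <- scan_domains(proteins, models = models, cc_window = cc_window)
  ev <- if (is.null(evidence)) scan$evidence else evidence
  out <- lapply(names(proteins), function(g) {
    classify_gene(g, proteins[[g]],
                  evidence = ev[ev$gene_id == g, , drop = FALSE],
                  hits = scan$motif_hits[scan$motif_hits$gene_id == g, ,
                                         drop = FALSE],
                  cc_profile = scan$cc_profiles[[g]],
                  params = params)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize letter-code classes
#'
#' Per-(regularity, letter code) counts with percentages of the total gene
#' number (half-up, 2 decimals), N-terminal group subtotals (CC = C/c, TIR,
#' other), and per-regularity totals.
#'
#' @param classes Classification data frame (needs `regularity` and
#'   `letter_code`).
#' @param total Total gene count used as the percentage denominator
#'   (default `nrow(classes)`; may exceed it when summarizing a subset).
#' @return List with `subgroups` (data frame: regularity, group,
#'   letter_code, n, pct), `groups` (regularity, group, n, pct) and
#'   `totals` (regularity, n, pct).
#' @export
summarize_classes <- function(classes, total = nrow(classes)) {
  if (total == 0) stop("total gene count is zero")
  if (total < nrow(classes)) stop("total smaller than number of records")
  if (!nrow(classes)) {
    return(list(subgroups = data.frame(regularity = character(),
                                       group = character(),
                                       letter_code = character(),
                                       n = integer(), pct = numeric()),
                groups = data.frame(regularity = character(),
                                    group = character(), n = integer(),
                                    pct = numeric()),
                totals = data.frame(regularity = character(), n = integer(),
                                    pct = numeric())))
  }
  nterm <- substr(classes$letter_code, 1L, 1L)
  group <- ifelse(nterm %in% c("C", "c"), "CC",
                  ifelse(nterm == "T", "TIR", "other"))
  tab <- stats::aggregate(list(n = seq_len(nrow(classes))),
                   by = list(regularity = classes$regularity, group = group,
                             letter_code = classes$letter_code),
                   FUN = length)
  tab <- tab[order(tab$regularity, tab$group, tab$letter_code), ]
  tab$pct <- pct(tab$n, total)
  gr <- stats::aggregate(list(n = tab$n),
                  by = list(regularity = tab$regularity, group = tab$group),
                  FUN = sum)
  gr$pct <- pct(gr$n, total)
  tot <- stats::aggregate(list(n = tab$n), by = list(regularity = tab$regularity),
                   FUN = sum)
  tot$pct <- pct(tot$n, total)
  rownames(tab) <- NULL
  list(subgroups = tab, groups = gr, totals = tot)
}
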