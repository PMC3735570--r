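# NBS motif models and the degenerate-pattern scanner.
#
# The five motifs are strictly ordered along the NB-ARC domain:
# P-loop < Kinase2 < Kinase3a < GLPL < MHDL. The scanner reports at most one
# hit per motif, chosen as the best-scoring colinear, non-overlapping chain,
# so downstream regularity assessment can read the hits in sequence order.

NBS_MOTIF_NAMES <- c("P-loop", "Kinase2", "Kinase3a", "GLPL", "MHDL")

#' Construct a motif model
#'
#' A model is a degenerate amino-acid pattern: literal residues, `x` for any
#' residue, and bracketed classes such as `[GA]`. `min_score` is the minimum
#' fraction of constrained (non-`x`) positions that must match for a window
#' to count as a candidate hit (default 1: every constrained position).
#'
#' @param name Motif name.
#' @param pattern Degenerate pattern string.
#' @param min_score Score threshold in (0, 1].
#' @return A `motif_model` list with parsed per-position residue classes.
#' @export
motif_model <- function(name, pattern, min_score = 1) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(min_score), min_score > 0, min_score <= 1)
  positions <- parse_motif_pattern(pattern)
  structure(list(name = name, pattern = pattern,
                 positions = positions, width = length(positions),
                 min_score = min_score),
            class = "motif_model")
}

#' Parse a degenerate motif pattern
#'
#' @param pattern Pattern string, e.g. `"[GA]xxGxGK[ST]T"`.
#' @return List with one element per position: a character vector of allowed
#'   residues, or `NULL` for a wildcard.
#' @export
parse_motif_pattern <- function(pattern) {
  chars <- .seq_chars(pattern)
  out <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("unbalanced '[' in motif pattern: ", pattern)
      out[[length(out) + 1L]] <- toupper(chars[(i + 1L):(j - 1L)])
      i <- j + 1L
    } else if (ch %in% c("x", "X")) {
      out[length(out) + 1L] <- list(NULL)
      i <- i + 1L
    } else {
      out[[length(out) + 1L]] <- toupper(ch)
      i <- i + 1L
    }
  }
  if (!length(out)) stop("empty motif pattern")
  out
}

#' Default models for the five conserved NBS motifs
#'
#' The canonical degenerate patterns shipped with the package. They are
#' deliberately strict (`min_score = 1`) so that random sequence almost never
#' matches; users may supply their own models (e.g. built from a reference
#' alignment) to `scan_nbs_motifs()`.
#'
#' @return Named list of five `motif_model` objects in canonical order.
#' @export
nbs_motif_models <- function() {
  m <- list(
    motif_model("P-loop",   "[GA]xxGxGK[ST]T"),
    motif_model("Kinase2",  "[LIVMF][LIVMF][LIVMF][LIVMF]DD[VILM]W"),
    motif_model("Kinase3a", "G[ST]x[LIVMF][LIVMF][LIVMF]TTR[DSE]"),
    motif_model("GLPL",     "xxGLPL[AT][LIVMF]"),
    motif_model("MHDL",     "[LIVMF]x[MI]HD[LVM]")
  )
  names(m) <- NBS_MOTIF_NAMES
  m
}

# Consensus cassettes realizing each default pattern; used by the synthetic
# generator and the worked examples.
nbs_motif_consensus <- function() {
  c("P-loop" = "GMGGVGKTT", "Kinase2" = "LLVLDDVW",
    "Kinase3a" = "GSRIIITTRD", "GLPL" = "CGGLPLAL", "MHDL" = "LSMHDL")
}

# All candidate windows for one model: data.frame(start, end, score).
motif_candidates <- function(seq_chars, model) {
  L <- length(seq_chars)
  w <- model$width
  empty <- data.frame(start = integer(), end = integer(), score = numeric())
  if (L < w) return(empty)
  n_off <- L - w + 1L
  cons <- which(!vapply(model$positions, is.null, logical(1)))
  sc <- numeric(n_off)
  for (p in cons) {
    sc <- sc + (seq_chars[p:(p + n_off - 1L)] %in% model$positions[[p]])
  }
  sc <- sc / length(cons)
  idx <- which(sc >= model$min_score - 1e-9)
  if (!length(idx)) return(empty)
  data.frame(start = idx, end = idx + w - 1L, score = sc[idx])
}

#' Scan a protein for the five conserved NBS motifs
#'
#' Finds all candidate windows for each motif model, then selects the
#' highest-total-score chain of at most one hit per motif that respects the
#' canonical motif order and does not overlap (ties broken toward the
#' leftmost positions). The result is therefore always reported in sequence
#' order, ready for regularity assessment.
#'
#' @param sequence Amino-acid string (no gaps).
#' @param models List of `motif_model` objects in canonical order
#'   (default [nbs_motif_models()]).
#' @param gene_id Id recorded in the output.
#' @return `data.frame(gene_id, motif, start, end, score)` sorted by start.
#' @export
scan_nbs_motifs <- function(sequence, models = nbs_motif_models(),
                            gene_id = "query") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("invalid input: sequence must be a non-empty string")
  seq_chars <- .seq_chars(toupper(sequence))
  cand <- lapply(models, function(m) motif_candidates(seq_chars, m))
  hits <- select_motif_chain(cand)
  if (nrow(hits)) {
    hits$motif <- vapply(models[hits$rank], `[[`, "", "name")
    hits <- data.frame(gene_id = gene_id, motif = hits$motif,
                       start = hits$start, end = hits$end, score = hits$score,
                       stringsAsFactors = FALSE)
  } else {
    hits <- data.frame(gene_id = character(), motif = character(),
                       start = integer(), end = integer(), score = numeric(),
                       stringsAsFactors = FALSE)
  }
  hits[order(hits$start), , drop = FALSE]
}

# Best colinear non-overlapping chain over per-rank candidate sets.
# Maximizes total score; ties resolved toward lexicographically smallest
# start positions. Returns data.frame(rank, start, end, score).
select_motif_chain <- function(cand_list) {
  cands <- do.call(rbind, lapply(seq_along(cand_list), function(r) {
    d <- cand_list[[r]]
    if (!nrow(d)) return(NULL)
    d$rank <- r
    d
  }))
  empty <- data.frame(rank = integer(), start = integer(),
                      end = integer(), score = numeric())
  if (is.null(cands) || !nrow(cands)) return(empty)
  cands <- cands[order(cands$rank, cands$start), , drop = FALSE]
  m <- nrow(cands)
  tot <- cands$score
  chain <- lapply(seq_len(m), function(i) i)
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      if (cands$rank[j] < cands$rank[i] && cands$end[j] < cands$start[i]) {
        cand_tot <- tot[j] + cands$score[i]
        cand_chain <- c(chain[[j]], i)
        better <- cand_tot > tot[i] + 1e-9 ||
          (abs(cand_tot - tot[i]) <= 1e-9 &&
             .lex_less(cands$start[cand_chain], cands$start[chain[[i]]]))
        if (better) {
          tot[i] <- cand_tot
          chain[[i]] <- cand_chain
        }
      }
    }
  }
  best <- 1L
  for (i in seq_len(m)) {
    if (tot[i] > tot[best] + 1e-9 ||
        (abs(tot[i] - tot[best]) <= 1e-9 &&
           .lex_less(cands$start[chain[[i]]], cands$start[chain[[best]]])))
      best <- i
  }
  cands[chain[[best]], c("rank", "start", "end", "score"), drop = FALSE]
}
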