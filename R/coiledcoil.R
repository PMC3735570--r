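# Windowed heptad-register coiled-coil scoring.
#
# Coiled coils show a seven-residue (abcdefg) periodicity with hydrophobic
# residues at the a/d core positions and polar/charged residues on the
# solvent-exposed face. For every window the score takes the best of the
# seven possible register phases and combines (i) the fraction of a/d
# positions that are core-hydrophobic, (ii) the fraction of non-a/d
# positions that are polar/charged, penalized by (iii) hydrophobics on the
# exposed face and (iv) helix-breaking prolines anywhere. The raw score is
# mapped through a logistic calibration to [0, 1] so that segments can be
# graded at the conventional probability thresholds 0.02/0.10/0.50/0.90.

CC_HYDRO_CORE <- c("L", "I", "V", "M", "F", "Y", "W", "A")
CC_HYDRO_PENALTY <- c("L", "I", "V", "M", "F", "Y", "W")
CC_POLAR <- c("E", "K", "Q", "R", "D", "N")

# Calibration anchors (fixed, part of the scorer definition):
#  - ideal heptad repeat (e.g. "LEALEKK" x 8): raw 0.9 -> prob 0.964 (>= 0.90)
#  - core-only repeat "LSSLSSS": raw 0.5 -> prob 0.063 (in [0.02, 0.10))
#  - polyproline: raw -2 -> prob ~ 0 (< 0.02)
CC_LOGISTIC_STEEPNESS <- 15
CC_LOGISTIC_MIDPOINT <- 0.68

#' Score coiled-coil propensity along a protein
#'
#' Computes a per-residue coiled-coil probability profile (each residue takes
#' the maximum over all windows covering it, each window the maximum over the
#' seven heptad phases). Profiles are threshold-nested by construction:
#' residues above a high threshold are a subset of those above any lower one.
#'
#' @param sequence Amino-acid string.
#' @param window Window width in residues; must be >= 14 (two heptads),
#'   default 21.
#' @param gene_id Id recorded in the profile.
#' @param thresholds Probability thresholds at which segments are graded.
#' @return A `cc_profile` list: `gene_id`, `prob` (length = protein length),
#'   `window`, `thresholds`.
#' @export
score_coiled_coil <- function(sequence, window = 21, gene_id = "query",
                              thresholds = c(0.02, 0.10, 0.50, 0.90)) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("invalid input: sequence must be a non-empty string")
  if (window < 14) stop("window must be at least 14 residues (two heptads)")
  chars <- .seq_chars(toupper(sequence))
  L <- length(chars)
  if (L < window) {
    warning("protein shorter than window; returning all-zero profile")
    prob <- rep(0, L)
  } else {
    nwin <- L - window + 1L
    core <- chars %in% CC_HYDRO_CORE
    pen <- chars %in% CC_HYDRO_PENALTY
    pol <- chars %in% CC_POLAR
    pro <- chars == "P"
    wsum <- function(v) {
      cs <- cumsum(c(0, v))
      cs[(window + 1L):(L + 1L)] - cs[1L:nwin]
    }
    n_pro <- wsum(pro)
    best <- rep(-Inf, nwin)
    for (phase in 0:6) {
      reg <- (seq_len(L) - 1L + phase) %% 7L
      ad <- reg == 0L | reg == 3L
      n_ad <- wsum(ad)
      n_core <- wsum(ad & core)
      n_non <- window - n_ad
      n_pol <- wsum(!ad & pol)
      n_pen <- wsum(!ad & pen)
      m <- 0.5 * n_core / pmax(n_ad, 1) + 0.5 * n_pol / pmax(n_non, 1) -
        n_pen / pmax(n_non, 1) - 2 * n_pro / window
      best <- pmax(best, m)
    }
    pw <- stats::plogis(CC_LOGISTIC_STEEPNESS * (best - CC_LOGISTIC_MIDPOINT))
    prob <- rep(0, L)
    for (s in seq_len(nwin)) {
      idx <- s:(s + window - 1L)
      prob[idx] <- pmax(prob[idx], pw[s])
    }
  }
  structure(list(gene_id = gene_id, prob = prob, window = window,
                 thresholds = sort(thresholds)),
            class = "cc_profile")
}

#' Extract maximal coiled-coil segments at each threshold
#'
#' @param profile A `cc_profile` from [score_coiled_coil()].
#' @param thresholds Probability thresholds (default: those stored in the
#'   profile).
#' @return `data.frame(gene_id, threshold, start, end, max_prob)`; segments
#'   at a higher threshold are always contained in a segment at any lower
#'   threshold.
#' @export
cc_segments <- function(profile, thresholds = NULL) {
  stopifnot(inherits(profile, "cc_profile"))
  if (is.null(thresholds)) thresholds <- profile$thresholds
  out <- list()
  for (t in sort(thresholds)) {
    r <- rle(profile$prob >= t)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = profile$gene_id, threshold = t,
        start = starts[keep], end = ends[keep],
        max_prob = vapply(keep, function(k)
          max(profile$prob[starts[k]:ends[k]]), numeric(1)))
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), threshold = numeric(),
                      start = integer(), end = integer(),
                      max_prob = numeric()))
  do.call(rbind, out)
}
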