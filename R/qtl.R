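# Electronic PCR marker placement and QTL co-localization categories.

#' e-PCR parameters
#'
#' @param size_min,size_max Product size window in bp (default 80-700).
#' @param max_mismatch Maximum mismatches per primer site (default 2).
#' @param anchor3 Number of 3'-terminal primer bases that must match
#'   exactly (default 3).
#' @return Parameter list.
#' @export
epcr_params <- function(size_min = 80, size_max = 700, max_mismatch = 2,
                        anchor3 = 3) {
  stopifnot(size_min > 0, size_min < size_max, max_mismatch >= 0,
            anchor3 >= 0)
  list(size_min = size_min, size_max = size_max,
       max_mismatch = max_mismatch, anchor3 = anchor3)
}

#' QTL co-localization parameters
#'
#' @param flank Symmetric flanking window around NBS genes in bp
#'   (default 3 Mb).
#' @param small_scaffold_max Scaffolds up to this length without NBS genes
#'   get their own category (default 2 Mb).
#' @return Parameter list.
#' @export
qtl_params <- function(flank = 3e6, small_scaffold_max = 2e6) {
  stopifnot(flank > 0, small_scaffold_max > 0)
  list(flank = flank, small_scaffold_max = small_scaffold_max)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# All binding sites of `primer` on `subject` (a DNAString holding the plus
# strand). strand "+": primer as given, 3' end at site end. strand "-":
# reverse complement matched on the plus text, primer 3' end at site start.
# Candidate matching runs through Biostrings' C matcher; the exact 3'
# anchor is enforced on the few candidates afterwards.
# Returns data.frame(start, end, mismatches).
primer_sites <- function(subject, primer, strand, max_mismatch, anchor3) {
  pat <- if (strand == "+") primer else .revcomp(primer)
  pc <- .seq_chars(pat)
  w <- length(pc)
  empty <- data.frame(start = integer(), end = integer(),
                      mismatches = integer())
  if (length(subject) < w) return(empty)
  m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mismatch,
                                with.indels = FALSE)
  if (!length(m)) return(empty)
  starts <- BiocGenerics::start(m)
  site_chars <- strsplit(as.character(m), "", fixed = TRUE)
  mm <- vapply(site_chars, function(s) sum(s != pc), integer(1))
  apos <- if (strand == "+") (w - anchor3 + 1L):w else seq_len(anchor3)
  anchor_ok <- if (anchor3 > 0)
    vapply(site_chars, function(s) all(s[apos] == pc[apos]), logical(1))
  else rep(TRUE, length(starts))
  idx <- which(mm <= max_mismatch & anchor_ok)
  if (!length(idx)) return(empty)
  data.frame(start = starts[idx], end = starts[idx] + w - 1L,
             mismatches = mm[idx])
}

#' Electronic PCR placement of a primer pair
#'
#' Finds every convergent pair of primer-binding sites (one primer on each
#' strand, 3' ends facing each other) with at most `max_mismatch`
#' mismatches per site, an exact `anchor3`-base 3' match, and a product
#' size inside the window. Both primer-orientation assignments are
#' searched.
#'
#' @param genome Named character vector or `DNAStringSet` of sequences.
#' @param fwd,rev Primer sequences, 5' to 3'.
#' @param marker_id Id recorded in the output.
#' @param params [epcr_params()].
#' @return `data.frame(marker_id, seq_id, start, end, size, fwd_mismatches,
#'   rev_mismatches, orientation)` (1-based inclusive product coordinates).
#' @export
epcr <- function(genome, fwd, rev, marker_id = "marker",
                 params = epcr_params()) {
  if (methods::is(genome, "XStringSet")) genome <- as.character(genome)
  if (is.null(names(genome))) stop("genome sequences must be named")
  fwd <- toupper(fwd); rev <- toupper(rev)
  if (nchar(fwd) < params$anchor3 || nchar(rev) < params$anchor3)
    stop("primer shorter than the 3' anchor")
  if (nchar(fwd) < 15 || nchar(rev) < 15)
    stop("primers must be at least 15 bases")
  out <- list()
  for (sid in names(genome)) {
    sc <- Biostrings::DNAString(toupper(genome[[sid]]))
    for (orient in c("fwd_plus", "rev_plus")) {
      left <- if (orient == "fwd_plus") fwd else rev
      right <- if (orient == "fwd_plus") rev else fwd
      lsites <- primer_sites(sc, left, "+", params$max_mismatch,
                             params$anchor3)
      rsites <- primer_sites(sc, right, "-", params$max_mismatch,
                             params$anchor3)
      if (!nrow(lsites) || !nrow(rsites)) next
      for (a in seq_len(nrow(lsites))) {
        size <- rsites$end - lsites$start[a] + 1L
        ok <- which(rsites$start > lsites$start[a] &
                      size >= params$size_min & size <= params$size_max)
        for (b in ok) {
          out[[length(out) + 1L]] <- data.frame(
            marker_id = marker_id, seq_id = sid,
            start = lsites$start[a], end = rsites$end[b],
            size = size[b],
            fwd_mismatches = if (orient == "fwd_plus")
              lsites$mismatches[a] else rsites$mismatches[b],
            rev_mismatches = if (orient == "fwd_plus")
              rsites$mismatches[b] else lsites$mismatches[a],
            orientation = orient, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(marker_id = character(), seq_id = character(),
                      start = integer(), end = integer(), size = integer(),
                      fwd_mismatches = integer(), rev_mismatches = integer(),
                      orientation = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- unique(res[order(res$seq_id, res$start, res$end), ])
  rownames(res) <- NULL
  res
}

#' Run e-PCR for a table of primer pairs
#'
#' @param genome Genome sequences.
#' @param primers `data.frame(marker_id, fwd, rev, trait)` (trait optional).
#' @param params [epcr_params()].
#' @return Row-bound placements for all markers.
#' @export
epcr_all <- function(genome, primers, params = epcr_params()) {
  out <- lapply(seq_len(nrow(primers)), function(i)
    epcr(genome, primers$fwd[i], primers$rev[i],
         marker_id = primers$marker_id[i], params = params))
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(marker_id = character(), seq_id = character(),
                      start = integer(), end = integer(), size = integer(),
                      fwd_mismatches = integer(), rev_mismatches = integer(),
                      orientation = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# distance from a point to a 1-based inclusive interval (0 if inside)
.point_interval_dist <- function(p, s, e) {
  ifelse(p < s, s - p, ifelse(p > e, p - e, 0))
}

#' Categorize markers by co-localization with NBS genes
#'
#' Each marker falls in exactly one category: `unplaced` (no e-PCR
#' placement), `within_flank` / `outside_flank` on chromosomes (product
#' midpoint within / beyond the flanking window of the nearest NBS gene),
#' `scaffold_with_nbs` (placed on a scaffold that carries NBS genes), or
#' `small_scaffold_no_nbs` (scaffold without NBS genes, no longer than
#' `small_scaffold_max`; longer NBS-free scaffolds count as
#' `outside_flank`). For multi-hit markers the placement nearest to any NBS
#' gene is the representative.
#'
#' @param marker_ids All marker ids (so unplaced markers are reported).
#' @param placements [epcr_all()] output.
#' @param loci NBS gene loci data frame.
#' @param seqinfo `data.frame(seq_id, length, is_chromosome)`.
#' @param params [qtl_params()].
#' @return `data.frame(marker_id, category, seq_id, position, distance)`;
#'   `seq_id`/`position`/`distance` are `NA` for unplaced markers.
#' @export
categorize_markers <- function(marker_ids, placements, loci, seqinfo,
                               params = qtl_params()) {
  unknown <- setdiff(placements$seq_id, seqinfo$seq_id)
  if (length(unknown))
    stop("placement on unknown sequence(s): ", paste(unknown, collapse = ", "))
  out <- lapply(unique(marker_ids), function(mk) {
    pl <- placements[placements$marker_id == mk, , drop = FALSE]
    if (!nrow(pl))
      return(data.frame(marker_id = mk, category = "unplaced",
                        seq_id = NA_character_, position = NA_real_,
                        distance = NA_real_, stringsAsFactors = FALSE))
    mid <- floor((pl$start + pl$end) / 2)
    dist <- vapply(seq_len(nrow(pl)), function(k) {
      g <- loci[loci$seq_id == pl$seq_id[k], , drop = FALSE]
      if (!nrow(g)) return(Inf)
      min(.point_interval_dist(mid[k], g$start, g$end))
    }, numeric(1))
    rep_k <- which.min(dist)
    sid <- pl$seq_id[rep_k]
    info <- seqinfo[seqinfo$seq_id == sid, , drop = FALSE]
    d <- dist[rep_k]
    category <- if (info$is_chromosome) {
      if (is.finite(d) && d <= params$flank) "within_flank" else "outside_flank"
    } else if (any(loci$seq_id == sid)) {
      "scaffold_with_nbs"
    } else if (info$length <= params$small_scaffold_max) {
      "small_scaffold_no_nbs"
    } else {
      "outside_flank"
    }
    data.frame(marker_id = mk, category = category, seq_id = sid,
               position = mid[rep_k],
               distance = ifelse(is.finite(d), d, NA_real_),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-location QTL co-localization summary
#'
#' Per chromosome/scaffold: NBS gene count, placed marker count, and
#' within-/outside-flank counts; plus totals with the two reporting
#' percentages (within-flank share of placed markers, and placed share of
#' all markers), both at one decimal.
#'
#' @param categories [categorize_markers()] output.
#' @param loci NBS gene loci.
#' @param seqinfo Sequence table (`seq_id`, `length`, `is_chromosome`).
#' @return List `per_location` (data frame over chromosomes, plus one
#'   `scaffolds` row) and `totals`.
#' @export
summarize_qtl <- function(categories, loci, seqinfo) {
  chroms <- seqinfo$seq_id[seqinfo$is_chromosome]
  rows <- lapply(chroms, function(sid) {
    cm <- categories[!is.na(categories$seq_id) & categories$seq_id == sid, ,
                     drop = FALSE]
    data.frame(seq_id = sid, n_genes = sum(loci$seq_id == sid),
               n_markers = nrow(cm),
               n_within = sum(cm$category == "within_flank"),
               n_outside = sum(cm$category == "outside_flank"),
               stringsAsFactors = FALSE)
  })
  sc <- categories[!is.na(categories$seq_id) &
                     !(categories$seq_id %in% chroms), , drop = FALSE]
  rows[[length(rows) + 1L]] <- data.frame(
    seq_id = "scaffolds",
    n_genes = sum(!(loci$seq_id %in% chroms)),
    n_markers = nrow(sc),
    n_within = sum(sc$category == "scaffold_with_nbs"),
    n_outside = sum(sc$category == "small_scaffold_no_nbs") +
      sum(sc$category == "outside_flank"),
    stringsAsFactors = FALSE)
  per_location <- do.call(rbind, rows)
  n_total <- nrow(categories)
  n_placed <- sum(categories$category != "unplaced")
  n_within <- sum(categories$category == "within_flank")
  totals <- list(
    n_markers = n_total, n_placed = n_placed, n_within = n_within,
    n_outside = sum(categories$category == "outside_flank"),
    n_scaffold_with_nbs = sum(categories$category == "scaffold_with_nbs"),
    n_small_scaffold_no_nbs =
      sum(categories$category == "small_scaffold_no_nbs"),
    n_unplaced = sum(categories$category == "unplaced"),
    within_pct = if (n_placed > 0) pct(n_within, n_placed, 1) else NA_real_,
    placed_pct = if (n_total > 0) pct(n_placed, n_total, 1) else NA_real_)
  list(per_location = per_location, totals = totals)
}
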