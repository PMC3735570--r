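# Genomic architecture: 200-kb gene clusters, 70/70 duplication events,
# single-linkage gene families and per-location summaries.

#' Read gene loci from a GFF3 file
#'
#' Thin wrapper over [rtracklayer::import()]: keeps features of the given
#' type and returns 1-based inclusive intervals.
#'
#' @param path GFF3 path.
#' @param feature Feature type to keep (default `"gene"`).
#' @return `data.frame(gene_id, seq_id, start, end, strand)`.
#' @export
read_gene_loci <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == feature]
  ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  data.frame(gene_id = as.character(ids),
             seq_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Detect gene clusters by the 200-kb rule
#'
#' Per chromosome/scaffold, genes sorted by start are chained while the
#' edge-to-edge gap to the previous gene (`max(0, next start - prev end)`)
#' is at most `max_gap`; chains of two or more genes are clusters. Chaining
#' is transitive, so a chain whose extremes are further apart than
#' `max_gap` is still one cluster.
#'
#' @param loci Locus data frame (`gene_id`, `seq_id`, `start`, `end`).
#' @param max_gap Maximum adjacent-gene gap in bp (default 200000).
#' @return Data frame with one row per cluster (`cluster_id`, `seq_id`,
#'   `start`, `end`, `n_members`) and a `members` list-column of gene ids in
#'   genomic order.
#' @export
detect_clusters <- function(loci, max_gap = 200000) {
  stopifnot(max_gap > 0)
  if (anyDuplicated(loci$gene_id)) stop("duplicate gene_id in loci")
  out <- list()
  for (sid in sort(unique(loci$seq_id))) {
    d <- loci[loci$seq_id == sid, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    if (nrow(d) < 2L) next
    gap <- pmax(0, d$start[-1L] - d$end[-nrow(d)])
    chain <- cumsum(c(1L, as.integer(gap > max_gap)))
    for (k in split(seq_len(nrow(d)), chain)) {
      if (length(k) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        seq_id = sid, start = min(d$start[k]), end = max(d$end[k]),
        n_members = length(k), stringsAsFactors = FALSE)
      out[[length(out)]]$members <- I(list(d$gene_id[k]))
    }
  }
  if (!length(out)) {
    res <- data.frame(cluster_id = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), stringsAsFactors = FALSE)
    res$members <- I(list())
    return(res)
  }
  res <- do.call(rbind, out)
  res <- cbind(cluster_id = paste0("cluster", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Cluster membership table
#'
#' @param clusters Output of [detect_clusters()].
#' @return `data.frame(gene_id, cluster_id)`.
#' @export
cluster_membership <- function(clusters) {
  if (!nrow(clusters))
    return(data.frame(gene_id = character(), cluster_id = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    gene_id = unlist(clusters$members, use.names = FALSE),
    cluster_id = rep(clusters$cluster_id,
                     vapply(clusters$members, length, integer(1))),
    stringsAsFactors = FALSE)
}

#' Duplication detection parameters
#'
#' @param min_coverage Alignable fraction of the longer gene that must be
#'   exceeded (default 0.70).
#' @param min_identity Identity fraction of the alignable region that must
#'   be exceeded (default 0.70).
#' @param collapse_linked Collapse tightly-linked adjacent duplicates to one
#'   event per adjacent run when counting (default FALSE; see
#'   [collapse_linked_events()]).
#' @return Parameter list.
#' @export
duplication_params <- function(min_coverage = 0.70, min_identity = 0.70,
                               collapse_linked = FALSE) {
  stopifnot(min_coverage > 0, min_coverage <= 1,
            min_identity > 0, min_identity <= 1)
  list(min_coverage = min_coverage, min_identity = min_identity,
       collapse_linked = collapse_linked)
}

#' Global pairwise alignment with identity and coverage
#'
#' Needleman-Wunsch global alignment (BLOSUM62, linear gap penalty) via
#' [Biostrings::pairwiseAlignment]. The alignable region is the set of
#' columns where both sequences have residues; identity is the fraction of
#' those columns that are identical, coverage the fraction of the longer
#' sequence that is alignable.
#'
#' @param seq_a,seq_b Amino-acid strings.
#' @param gap_penalty Linear per-residue gap cost (default 8).
#' @return List: `score`, `identity`, `coverage`.
#' @export
align_pair <- function(seq_a, seq_b, gap_penalty = 8) {
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = .blosum62(),
    gapOpening = 0, gapExtension = gap_penalty)
  pa <- .seq_chars(as.character(Biostrings::alignedPattern(aln)))
  pb <- .seq_chars(as.character(Biostrings::alignedSubject(aln)))
  both <- pa != "-" & pb != "-"
  alignable <- sum(both)
  identity <- if (alignable) sum(pa[both] == pb[both]) / alignable else 0
  coverage <- alignable / max(nchar(seq_a), nchar(seq_b))
  list(score = Biostrings::score(aln), identity = identity,
       coverage = coverage)
}

#' Detect duplication events among NBS genes
#'
#' All-vs-all global protein alignment; a pair is a duplication event when
#' coverage and identity both exceed their thresholds. When loci and
#' clusters are supplied, events between genes that are adjacent members of
#' the same cluster are flagged as tightly `linked`.
#'
#' @param proteins Protein set restricted to the genes of interest.
#' @param params [duplication_params()].
#' @param loci Optional locus data frame (for the linked flag).
#' @param clusters Optional [detect_clusters()] output.
#' @return `data.frame(gene_a, gene_b, coverage, identity, linked)`;
#'   pairs are unordered and reported with `gene_a < gene_b`.
#' @export
detect_duplications <- function(proteins, params = duplication_params(),
                                loci = NULL, clusters = NULL) {
  proteins <- as_protein_set(proteins)
  ids <- names(proteins)
  if (!is.null(loci)) {
    missing <- setdiff(loci$gene_id, ids)
    if (length(missing)) stop("missing protein for locus/loci: ",
                              paste(utils::head(missing, 5), collapse = ", "))
  }
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      coverage = numeric(), identity = numeric(),
                      linked = logical(), stringsAsFactors = FALSE)
  if (length(ids) < 2L) return(empty)
  adjacency <- character(0)
  if (!is.null(clusters) && nrow(clusters) && !is.null(loci)) {
    for (k in seq_len(nrow(clusters))) {
      mem <- clusters$members[[k]]
      ord <- mem[order(loci$start[match(mem, loci$gene_id)])]
      if (length(ord) >= 2L)
        adjacency <- c(adjacency, paste(pmin(ord[-length(ord)], ord[-1L]),
                                        pmax(ord[-length(ord)], ord[-1L]),
                                        sep = "\r"))
    }
  }
  pairs <- utils::combn(sort(ids), 2L)
  out <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    al <- align_pair(proteins[[a]], proteins[[b]])
    if (al$coverage > params$min_coverage &&
        al$identity > params$min_identity) {
      out[[length(out) + 1L]] <- data.frame(
        gene_a = a, gene_b = b, coverage = al$coverage,
        identity = al$identity,
        linked = paste(a, b, sep = "\r") %in% adjacency,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse tightly-linked duplication events
#'
#' Within each run of linked (cluster-adjacent) duplicates only the
#' highest-identity event per adjacent pair run is kept, mirroring the
#' "one duplication event per tightly-linked gene run" counting rule. All
#' unlinked events are kept.
#'
#' @param events Output of [detect_duplications()].
#' @return Subset of `events`.
#' @export
collapse_linked_events <- function(events) {
  if (!nrow(events)) return(events)
  linked <- events[events$linked, , drop = FALSE]
  rest <- events[!events$linked, , drop = FALSE]
  if (!nrow(linked)) return(events)
  g <- igraph::graph_from_data_frame(linked[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)$membership
  run <- comp[linked$gene_a]
  keep <- unlist(lapply(split(seq_len(nrow(linked)), run), function(k) {
    k[which.max(linked$identity[k])]
  }))
  res <- rbind(rest, linked[keep, , drop = FALSE])
  res[order(res$gene_a, res$gene_b), , drop = FALSE]
}

#' Build gene families from duplication events
#'
#' Families are single-linkage connected components of the duplication
#' graph: every member shows identity to at least one other member.
#'
#' @param events Output of [detect_duplications()].
#' @return `data.frame(gene_id, family_id)`; families partition the
#'   duplicated gene set and are numbered by decreasing size then by first
#'   member.
#' @export
build_families <- function(events) {
  if (!nrow(events))
    return(data.frame(gene_id = character(), family_id = character(),
                      stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(events[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)$membership
  d <- data.frame(gene_id = names(comp), comp = as.integer(comp),
                  stringsAsFactors = FALSE)
  d <- d[order(d$gene_id), , drop = FALSE]
  sizes <- table(d$comp)
  first <- vapply(split(d$gene_id, d$comp), min, character(1))
  ord <- order(-as.integer(sizes[as.character(names(sizes))]),
               first[as.character(names(sizes))])
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  d$family_id <- paste0("family", relabel[as.character(d$comp)])
  rownames(d) <- NULL
  d[, c("gene_id", "family_id")]
}

#' Per-location architecture summary
#'
#' Per chromosome/scaffold: gene count, clustered count, duplicated count
#' (genes in at least one event) and duplicated-in-cluster count, plus
#' global totals and the two percentage conventions: the clustered share is
#' computed after excluding genes that are the only NBS gene on their
#' sequence, and the duplicated-in-cluster share over all duplicated genes.
#'
#' @param loci Locus data frame.
#' @param clusters [detect_clusters()] output.
#' @param events [detect_duplications()] output.
#' @param exclusions Genes excluded from the clustered-share denominator;
#'   default: genes that are the sole NBS gene on their sequence.
#' @return List with `per_location` (data frame) and `totals` (list with
#'   counts, `clustered_pct` at 2 decimals, `dup_in_cluster_pct` at 1
#'   decimal).
#' @export
summarize_architecture <- function(loci, clusters, events,
                                   exclusions = NULL) {
  per_seq <- table(loci$seq_id)
  if (is.null(exclusions))
    exclusions <- loci$gene_id[loci$seq_id %in% names(per_seq)[per_seq == 1L]]
  clustered <- cluster_membership(clusters)$gene_id
  duplicated_genes <- unique(c(events$gene_a, events$gene_b))
  dup_in_cluster <- intersect(duplicated_genes, clustered)
  seqs <- sort(unique(loci$seq_id))
  per_location <- do.call(rbind, lapply(seqs, function(sid) {
    g <- loci$gene_id[loci$seq_id == sid]
    data.frame(seq_id = sid, n_genes = length(g),
               n_clustered = sum(g %in% clustered),
               n_duplicated = sum(g %in% duplicated_genes),
               n_dup_in_cluster = sum(g %in% dup_in_cluster),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_location))
    per_location <- data.frame(seq_id = character(), n_genes = integer(),
                               n_clustered = integer(),
                               n_duplicated = integer(),
                               n_dup_in_cluster = integer())
  n_total <- nrow(loci)
  n_clustered <- length(clustered)
  n_dup <- length(duplicated_genes)
  n_dic <- length(dup_in_cluster)
  totals <- list(
    n_genes = n_total, n_clustered = n_clustered,
    n_duplicated = n_dup, n_dup_in_cluster = n_dic,
    n_excluded = length(exclusions),
    clustered_pct = if (n_total - length(exclusions) > 0)
      pct(n_clustered, n_total - length(exclusions), 2) else NA_real_,
    dup_in_cluster_pct = if (n_dup > 0) pct(n_dic, n_dup, 1) else NA_real_)
  list(per_location = per_location, totals = totals)
}
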