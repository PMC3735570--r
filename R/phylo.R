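# Distance phylogenetics: pairwise-deletion distances, neighbor-joining,
# bootstrap support, and clade-monophyly testing on unrooted trees.

#' Normalize an alignment to a character matrix
#'
#' Accepts a named character vector of equal-length aligned sequences
#' (gaps `-`), an `AAStringSet`/`DNAStringSet`, or a character matrix.
#'
#' @param aln Alignment in any accepted form.
#' @return Character matrix, rows = sequences, named.
#' @export
as_alignment_matrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- toupper(aln)
  } else {
    if (methods::is(aln, "XStringSet")) aln <- as.character(aln)
    if (!is.character(aln) || is.null(names(aln)))
      stop("alignment must be a named character vector, XStringSet or matrix")
    if (length(unique(nchar(aln))) != 1L)
      stop("aligned sequences must all have the same length")
    m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
    rownames(m) <- names(aln)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate sequence labels")
  m
}

#' Pairwise distances from an alignment
#'
#' Gap columns are deleted pairwise (a column is compared for a pair only
#' when neither row has a gap there). Models: `p` (mismatch proportion),
#' `poisson` (Poisson correction, `-ln(1 - p)`, the default for proteins),
#' `k2p_nt` (Kimura two-parameter for nucleotide alignments,
#' `-ln(1 - 2P - Q) / 2 - ln(1 - 2Q) / 4` with transition and transversion
#' proportions P and Q).
#'
#' @param aln Alignment (see [as_alignment_matrix()]).
#' @param model `"p"`, `"poisson"` or `"k2p_nt"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
compute_distances <- function(aln, model = c("poisson", "p", "k2p_nt")) {
  model <- match.arg(model)
  m <- as_alignment_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least two sequences")
  labs <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  purines <- c("A", "G")
  pyrimidines <- c("C", "T", "U")
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      nc <- sum(ok)
      if (nc == 0L) stop("no comparable columns for pair ", labs[i], ", ", labs[j])
      a <- m[i, ok]; b <- m[j, ok]
      if (model == "k2p_nt") {
        ts <- sum((a %in% purines & b %in% purines |
                     a %in% pyrimidines & b %in% pyrimidines) & a != b)
        tv <- sum(a != b) - ts
        P <- ts / nc; Q <- tv / nc
        arg1 <- 1 - 2 * P - Q
        arg2 <- 1 - 2 * Q
        if (arg1 <= 0 || arg2 <= 0)
          stop("saturated distance for pair ", labs[i], ", ", labs[j])
        dij <- -0.5 * log(arg1) - 0.25 * log(arg2)
      } else {
        p <- sum(a != b) / nc
        if (model == "p") {
          dij <- p
        } else {
          if (p >= 1)
            stop("saturated distance for pair ", labs[i], ", ", labs[j])
          dij <- -log(1 - p)
        }
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (Saitou-Nei Q criterion, canonical
#' branch-length formulas). Ties in the Q matrix are broken toward the
#' lowest-index pair in the current label order, so results are
#' reproducible. On an additive distance matrix the tree's path lengths
#' reproduce the input exactly. Negative branch lengths are kept by
#' default.
#'
#' @param d Symmetric distance matrix (or `dist`) with labels.
#' @param clamp_negative Clamp negative branch lengths to zero
#'   (default FALSE).
#' @return Unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d, clamp_negative = FALSE) {
  D <- as.matrix(d)
  if (is.null(rownames(D))) stop("distance matrix needs labels")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix is not symmetric")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  fmt <- function(x) sprintf("%.12g", x)
  node <- rownames(D)  # newick fragment per active node
  while (n > 3L) {
    R <- rowSums(D)
    best <- NULL; bestq <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        q <- (n - 2) * D[i, j] - R[i] - R[j]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (clamp_negative) { bi <- max(bi, 0); bj <- max(bj, 0) }
    newu <- paste0("(", node[i], ":", fmt(bi), ",", node[j], ":", fmt(bj), ")")
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    node <- c(node[keep], newu)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
    n <- n - 1L
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (clamp_negative) { b1 <- max(b1, 0); b2 <- max(b2, 0); b3 <- max(b3, 0) }
  nwk <- paste0("(", node[1], ":", fmt(b1), ",", node[2], ":", fmt(b2), ",",
                node[3], ":", fmt(b3), ");")
  ape::read.tree(text = nwk)
}

# Canonical keys for the non-trivial bipartitions of an unrooted tree:
# each internal edge splits the tips; the side not containing the first
# tip label (alphabetically) is sorted and pasted.
tree_bipartitions <- function(phy) {
  tips <- sort(phy$tip.label)
  anchor <- tips[1L]
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) == 0L || length(side) >= length(tips) - 1L)
      return(NA_character_)
    paste(sort(side), collapse = "\r")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Columns are resampled with replacement `replicates` times; each
#' replicate alignment is run through [compute_distances()] and
#' [nj_tree()], and the support of each internal edge of the full-data tree
#' is the percentage of replicates whose tree contains the same
#' bipartition. Runs are reproducible for a given seed.
#'
#' @param aln Alignment.
#' @param model Distance model (see [compute_distances()]).
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @return The full-data `phylo` tree with `node.label` holding supports in
#'   `[0, 100]` (root label empty).
#' @export
bootstrap_support <- function(aln, model = "poisson", replicates = 1000,
                              seed = 1) {
  if (replicates < 1) stop("replicates must be >= 1")
  m <- as_alignment_matrix(aln)
  base <- nj_tree(compute_distances(m, model))
  counts <- stats::setNames(numeric(0), character(0))
  set.seed(seed)
  done <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    keys <- tryCatch(
      tree_bipartitions(nj_tree(compute_distances(m[, cols, drop = FALSE],
                                                  model))),
      error = function(e) NULL)
    if (is.null(keys)) next  # saturated replicate
    done <- done + 1L
    for (k in keys) counts[k] <- ifelse(is.na(counts[k]), 1, counts[k] + 1)
  }
  if (done == 0L) stop("all bootstrap replicates failed (saturated distances)")
  # attach support to internal nodes of the base tree
  ntip <- length(base$tip.label)
  pp <- ape::prop.part(base)
  labs <- attr(pp, "labels")
  tips <- sort(base$tip.label)
  anchor <- tips[1L]
  node_keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) == 0L || length(side) >= ntip - 1L)
      return(NA_character_)
    paste(sort(side), collapse = "\r")
  }, character(1))
  supp <- vapply(node_keys, function(k) {
    if (is.na(k)) return(NA_real_)
    cnt <- counts[k]
    if (is.na(cnt)) cnt <- 0
    100 * cnt / done
  }, numeric(1))
  base$node.label <- ifelse(is.na(supp), "", sprintf("%g", supp))
  attr(base, "bootstrap") <- list(replicates = replicates,
                                  completed = done, seed = seed)
  base
}

#' Test clade monophyly on an unrooted tree
#'
#' A tip set is monophyletic when some edge of the unrooted tree induces
#' exactly the bipartition tip set vs. complement. Singleton sets, their
#' complements and the full tip set are trivially monophyletic.
#'
#' @param tree `phylo` tree.
#' @param tip_set Character vector of tip labels.
#' @return `TRUE` or `FALSE`.
#' @export
test_monophyly <- function(tree, tip_set) {
  tips <- tree$tip.label
  unknown <- setdiff(tip_set, tips)
  if (length(unknown)) stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  if (!length(tip_set)) stop("empty tip set")
  k <- length(unique(tip_set))
  n <- length(tips)
  if (k == 1L || k >= n - 1L) return(TRUE)
  anchor <- sort(tips)[1L]
  side <- unique(tip_set)
  if (anchor %in% side) side <- setdiff(tips, side)
  key <- paste(sort(side), collapse = "\r")
  key %in% tree_bipartitions(tree)
}

#' Simulate an alignment down a tree
#'
#' Simple planted-signal sequence evolution used by the synthetic suite: a
#' uniform-random root sequence evolves along the tree, each site
#' substituting on a branch of length b with probability `1 - exp(-b)`
#' (branch lengths in expected substitutions per site), to a uniformly
#' chosen different state. No indels, so the rows are pre-aligned.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param ncol Alignment columns.
#' @param alphabet Character states (default the 20 amino acids).
#' @param seed Integer RNG seed.
#' @return Named character vector of aligned tip sequences.
#' @export
simulate_alignment <- function(tree, ncol, alphabet = AA20, seed = 1) {
  set.seed(seed)
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample(alphabet, ncol, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    p_sub <- 1 - exp(-tree$edge.length[e])
    s <- seqs[[par]]
    hit <- which(stats::runif(ncol) < p_sub)
    for (i in hit) s[i] <- sample(setdiff(alphabet, s[i]), 1L)
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  stats::setNames(out, tree$tip.label)
}
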