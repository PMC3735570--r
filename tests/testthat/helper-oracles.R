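# Independent brute-force oracles used to validate the package's
# implementations on small instances. Deliberately naive: plain loops and
# exhaustive enumeration, sharing no code with the implementation paths.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len) paste(sample(AA, len, TRUE), collapse = "")
random_dna_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                      collapse = "")

# ---- exhaustive motif scan oracle ------------------------------------------
# scores every offset of every model, then enumerates every colinear
# non-overlapping selection of at most one hit per motif and returns the
# best-total-score selection (ties toward lexicographically smallest starts).
oracle_scan_motifs <- function(sequence, models = nbs_motif_models()) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  cand <- lapply(models, function(m) {
    w <- m$width
    res <- list()
    if (L >= w) {
      for (s in seq_len(L - w + 1)) {
        hit <- 0; tot <- 0
        for (p in seq_len(w)) {
          allowed <- m$positions[[p]]
          if (is.null(allowed)) next
          tot <- tot + 1
          if (chars[s + p - 1] %in% allowed) hit <- hit + 1
        }
        sc <- hit / tot
        if (sc >= m$min_score - 1e-9)
          res[[length(res) + 1]] <- c(start = s, end = s + w - 1, score = sc)
      }
    }
    if (length(res)) as.data.frame(do.call(rbind, res))
    else data.frame(start = integer(), end = integer(), score = numeric())
  })
  counts <- vapply(cand, nrow, integer(1))
  stopifnot(prod(counts + 1) <= 20000)  # keep enumeration honest but finite
  grid <- expand.grid(lapply(counts, function(k) 0:k))
  best_tot <- -1; best_rows <- NULL; best_starts <- NULL
  for (r in seq_len(nrow(grid))) {
    sel <- as.integer(grid[r, ])
    prev_end <- 0; tot <- 0; ok <- TRUE
    rows <- list(); starts <- numeric(0)
    for (k in seq_along(sel)) {
      if (sel[k] == 0) next
      cc <- cand[[k]][sel[k], ]
      if (cc$start <= prev_end) { ok <- FALSE; break }
      prev_end <- cc$end
      tot <- tot + cc$score
      starts <- c(starts, cc$start)
      rows[[length(rows) + 1]] <- data.frame(motif = models[[k]]$name,
                                             start = cc$start, end = cc$end,
                                             score = cc$score)
    }
    if (!ok) next
    better <- tot > best_tot + 1e-9 ||
      (abs(tot - best_tot) <= 1e-9 && !is.null(best_starts) &&
         nbsatlas:::.lex_less(starts, best_starts))
    if (is.null(best_rows) || better) {
      best_tot <- tot
      best_rows <- rows
      best_starts <- starts
    }
  }
  if (!length(best_rows))
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), score = numeric()))
  do.call(rbind, best_rows)
}

# ---- naive global alignment oracle -----------------------------------------
# Needleman-Wunsch with BLOSUM62 and a linear gap penalty, including end
# gaps; traceback prefers diagonal, then up.
oracle_align <- function(a, b, gap = 8) {
  M <- nbsatlas:::.blosum62()
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[1, ] <- -gap * (0:m)
  S[, 1] <- -gap * (0:n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + M[A[i], B[j]],
                             S[i, j + 1] - gap,
                             S[i + 1, j] - gap)
    }
  }
  i <- n; j <- m; matches <- 0; alignable <- 0
  while (i > 0 && j > 0) {
    if (abs(S[i + 1, j + 1] - (S[i, j] + M[A[i], B[j]])) < 1e-9) {
      alignable <- alignable + 1
      if (A[i] == B[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (abs(S[i + 1, j + 1] - (S[i, j + 1] - gap)) < 1e-9) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(score = S[n + 1, m + 1],
       identity = if (alignable) matches / alignable else 0,
       coverage = alignable / max(n, m))
}

# ---- brute-force e-PCR oracle ----------------------------------------------
# every position pair on both strands, checked by character comparison.
oracle_epcr <- function(genome, fwd, rev, params = epcr_params()) {
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  res <- list()
  for (sid in names(genome)) {
    sc <- strsplit(toupper(genome[[sid]]), "")[[1]]
    L <- length(sc)
    sites <- function(primer, strand) {
      pat <- if (strand == "+") primer else rc(primer)
      pc <- strsplit(pat, "")[[1]]
      w <- length(pc)
      out <- list()
      if (L >= w) {
        for (s in seq_len(L - w + 1)) {
          mm <- sum(sc[s:(s + w - 1)] != pc)
          if (mm > params$max_mismatch) next
          if (params$anchor3 > 0) {
            apos <- if (strand == "+") (w - params$anchor3 + 1):w
                    else seq_len(params$anchor3)
            if (any(sc[s + apos - 1] != pc[apos])) next
          }
          out[[length(out) + 1]] <- c(start = s, end = s + w - 1)
        }
      }
      if (length(out)) as.data.frame(do.call(rbind, out))
      else data.frame(start = integer(), end = integer())
    }
    for (orient in 1:2) {
      l <- sites(if (orient == 1) fwd else rev, "+")
      r <- sites(if (orient == 1) rev else fwd, "-")
      if (!nrow(l) || !nrow(r)) next
      for (a in seq_len(nrow(l))) {
        for (b in seq_len(nrow(r))) {
          size <- r$end[b] - l$start[a] + 1
          if (r$start[b] > l$start[a] &&
              size >= params$size_min && size <= params$size_max)
            res[[length(res) + 1]] <- data.frame(
              seq_id = sid, start = l$start[a], end = r$end[b], size = size)
        }
      }
    }
  }
  if (!length(res))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), size = integer()))
  unique(do.call(rbind, res))
}

# ---- random additive distance matrix ----------------------------------------
random_additive_matrix <- function(n) {
  tr <- ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1)))
  ape::cophenetic.phylo(tr)
}

# canonical partition representation for truth comparisons
partition_of <- function(df, key) {
  unname(sort(vapply(split(df$gene_id, df[[key]]),
                     function(x) paste(sort(x), collapse = ","),
                     character(1))))
}
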