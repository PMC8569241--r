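# Internal exact k-mer seed + ungapped extension alignment engine, shared by
# gene binning, split alignment of contigs, and construct support counting.
# Scoring is BWA-like (match +1, mismatch -4); extension is the best-scoring
# contiguous ungapped segment on a seeded diagonal (no indels, which matches
# the substitution-only error model of the consensus reads it aligns).

#' Build a k-mer index over a set of reference sequences
#'
#' @param seqs Named character vector of reference sequences.
#' @param k Seed length (default 17; must be <= 26 for exact numeric codes).
#' @return A list of class `kmer_index` used by [align_best()] and
#'   [split_align()].
#' @export
kmer_index <- function(seqs, k = 17L) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)), k >= 4, k <= 26)
  codes <- vector("list", length(seqs))
  tgts <- vector("list", length(seqs))
  poss <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    cc <- kmer_codes(seqs[[i]], k)
    ok <- !is.na(cc)
    codes[[i]] <- cc[ok]
    poss[[i]] <- which(ok)
    tgts[[i]] <- rep(i, sum(ok))
  }
  code <- unlist(codes)
  tgt <- unlist(tgts)
  pos <- unlist(poss)
  o <- order(code, tgt, pos)
  code <- code[o]
  tgt <- tgt[o]
  pos <- pos[o]
  ukeys <- unique(code)
  off <- c(0L, cumsum(tabulate(findInterval(code, ukeys), length(ukeys))))
  structure(
    list(
      k = as.integer(k), ukeys = ukeys, off = off, tgt = tgt, pos = pos,
      targets = names(seqs), tlen = unname(nchar(seqs)), seqs = seqs
    ),
    class = "kmer_index"
  )
}

# seed hits of one query against the index; returns list(qpos, tgt, tpos)
# (binary search on the sorted unique codes; no per-call hash build)
seed_hits <- function(index, qseq) {
  cc <- kmer_codes(qseq, index$k)
  none <- list(qpos = integer(0), tgt = integer(0), tpos = integer(0))
  if (length(cc) == 0) {
    return(none)
  }
  i <- findInterval(cc, index$ukeys)
  hit <- which(i > 0 & !is.na(cc))
  hit <- hit[index$ukeys[i[hit]] == cc[hit]]
  if (length(hit) == 0) {
    return(none)
  }
  ii <- i[hit]
  counts <- index$off[ii + 1L] - index$off[ii]
  rows <- sequence(counts, from = index$off[ii] + 1L)
  list(
    qpos = rep(hit, counts),
    tgt = index$tgt[rows],
    tpos = index$pos[rows]
  )
}

# best-scoring ungapped segment of query vs target on diagonal d
# (target position of query base i is i + d, 1-based); match +1, mismatch -4
extend_diagonal <- function(qseq, tseq, d, match = 1, mismatch = -4) {
  lq <- nchar(qseq)
  lt <- nchar(tseq)
  i1 <- max(1L, 1L - d)
  i2 <- min(lq, lt - d)
  if (i2 - i1 + 1L < 1L) {
    return(NULL)
  }
  m <- char_matches(
    substring(qseq, i1, i2),
    substring(tseq, i1 + d, i2 + d)
  )
  sc <- ifelse(m, match, mismatch)
  # max-sum contiguous subsegment via prefix minima
  S <- cumsum(sc)
  P <- c(0, S[-length(S)])
  gains <- S - cummin(P)
  j <- which.max(gains)
  score <- gains[j]
  i <- which.min(P[seq_len(j)])
  qs <- i1 + i - 1L
  qe <- i1 + j - 1L
  mm <- m[i:j]
  list(
    qstart = qs, qend = qe, tstart = qs + d, tend = qe + d,
    score = score, matches = sum(mm), mismatches = sum(!mm),
    identity = mean(mm)
  )
}

# the `top_diags` most seed-supported diagonals per target: returns
# list(tgt, diag) ordered by decreasing support
top_diagonals <- function(hits, top_diags) {
  d <- hits$tpos - hits$qpos
  key <- as.numeric(hits$tgt) * 2^32 + (d + 2^30)
  o <- order(key)
  key <- key[o]
  r <- rle(key)
  tgt_u <- hits$tgt[o][cumsum(r$lengths)]
  d_u <- d[o][cumsum(r$lengths)]
  cnt <- r$lengths
  keep <- integer(0)
  oo <- order(-cnt)
  taken <- integer(max(tgt_u))
  for (ix in oo) {
    t <- tgt_u[ix]
    if (taken[t] >= top_diags) next
    taken[t] <- taken[t] + 1L
    keep <- c(keep, ix)
  }
  list(tgt = tgt_u[keep], diag = d_u[keep])
}

#' Best-hit alignment of query sequences against an index
#'
#' Each query is seeded on both strands; the most seed-supported diagonals per
#' (target, strand) are extended and the single best-scoring local segment is
#' reported. Score ties are broken by target name, then start, then strand
#' ("+" first), so results are deterministic.
#'
#' @param qids,qseqs Parallel vectors of query ids and sequences.
#' @param index A [kmer_index()].
#' @param min_score Minimum alignment score to report.
#' @param top_diags Number of most-supported diagonals extended per
#'   (target, strand).
#' @param both_strands Also align the reverse complement.
#' @return A tibble with one row per aligned query: read_id, target, strand,
#'   qstart/qend (1-based on the oriented query), tstart/tend (1-based on the
#'   target), score, matches, mismatches, identity, aligned_len. Queries with
#'   no alignment above `min_score` are absent.
#' @export
align_best <- function(qids, qseqs, index, min_score = 20,
                       top_diags = 2L, both_strands = TRUE) {
  stopifnot(length(qids) == length(qseqs))
  n_out <- 0L
  o_id <- character(length(qids))
  o_tgt <- character(length(qids))
  o_strand <- character(length(qids))
  o_num <- matrix(0, length(qids), 8) # qstart qend tstart tend score m mm id
  strands <- if (both_strands) c("+", "-") else "+"
  for (qi in seq_along(qids)) {
    best <- NULL
    fwd <- qseqs[qi]
    for (st in strands) {
      qs <- if (st == "+") fwd else revcomp(fwd)
      hits <- seed_hits(index, qs)
      if (length(hits$qpos) == 0) next
      tops <- top_diagonals(hits, top_diags)
      for (gi in seq_along(tops$tgt)) {
        ext <- extend_diagonal(qs, index$seqs[[tops$tgt[gi]]], tops$diag[gi])
        if (is.null(ext) || ext$score < min_score) next
        cand <- c(ext, list(
          target = index$targets[tops$tgt[gi]], strand = st
        ))
        if (is.null(best) || better_alignment(cand, best)) best <- cand
      }
    }
    if (!is.null(best)) {
      n_out <- n_out + 1L
      o_id[n_out] <- qids[qi]
      o_tgt[n_out] <- best$target
      o_strand[n_out] <- best$strand
      o_num[n_out, ] <- c(
        best$qstart, best$qend, best$tstart, best$tend,
        best$score, best$matches, best$mismatches, best$identity
      )
    }
  }
  if (n_out == 0L) {
    return(tibble(
      read_id = character(0), target = character(0), strand = character(0),
      qstart = integer(0), qend = integer(0), tstart = integer(0),
      tend = integer(0), score = numeric(0), matches = integer(0),
      mismatches = integer(0), identity = numeric(0), aligned_len = integer(0)
    ))
  }
  ix <- seq_len(n_out)
  tibble(
    read_id = o_id[ix], target = o_tgt[ix], strand = o_strand[ix],
    qstart = as.integer(o_num[ix, 1]), qend = as.integer(o_num[ix, 2]),
    tstart = as.integer(o_num[ix, 3]), tend = as.integer(o_num[ix, 4]),
    score = o_num[ix, 5], matches = as.integer(o_num[ix, 6]),
    mismatches = as.integer(o_num[ix, 7]), identity = o_num[ix, 8],
    aligned_len = as.integer(o_num[ix, 2] - o_num[ix, 1] + 1)
  )
}

better_alignment <- function(a, b) {
  if (a$score != b$score) {
    return(a$score > b$score)
  }
  if (a$target != b$target) {
    return(a$target < b$target)
  }
  if (a$tstart != b$tstart) {
    return(a$tstart < b$tstart)
  }
  a$strand == "+" && b$strand == "-"
}
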