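# Split alignment of contigs to the reference genome and breakpoint candidate
# calling. A contig aligning as a single contiguous segment is ordinary
# transcript sequence; a contig whose best explanation is two segments from
# non-contiguous genomic regions (different chromosomes, a genomic gap larger
# than intron scale, or a strand change) that together tile the contig is a
# breakpoint candidate.

#' Split-align a contig to the genome
#'
#' Seeds the contig on both strands of every chromosome, groups seed hits into
#' near-diagonal bands, and extends each band into a maximal ungapped local
#' segment. All segments with length >= `min_segment` and identity >=
#' `min_identity` are reported.
#'
#' @param contig_seq Contig sequence.
#' @param genome_index A [kmer_index()] over the genome.
#' @param min_segment Minimum reported segment length (bases).
#' @param min_identity Minimum segment identity.
#' @param diag_tol Seed diagonals within this many bases are grouped into one
#'   band.
#' @param contig_id Id copied into the output.
#' @return Tibble of segments: contig_id, contig_start/contig_end (0-based
#'   half-open on the contig), chrom, genome_start/genome_end (0-based
#'   half-open), strand, identity, score. For minus-strand segments the contig
#'   interval still refers to the forward contig.
#' @export
split_align <- function(contig_seq, genome_index, min_segment = 25L,
                        min_identity = 0.9, diag_tol = 3L,
                        contig_id = "contig") {
  L <- nchar(contig_seq)
  if (L < genome_index$k) {
    warning("contig shorter than seed length; no segments")
    return(empty_segments())
  }
  out <- list()
  for (st in c("+", "-")) {
    qs <- if (st == "+") contig_seq else revcomp(contig_seq)
    hits <- seed_hits(genome_index, qs)
    if (length(hits$qpos) == 0) next
    hits <- tibble(qpos = hits$qpos, tgt = hits$tgt, tpos = hits$tpos)
    hits$diag <- hits$tpos - hits$qpos
    hits <- dplyr::arrange(hits, .data$tgt, .data$diag, .data$qpos)
    band <- cumsum(
      c(TRUE, diff(hits$diag) > diag_tol | diff(hits$tgt) != 0)
    )
    for (b in split(seq_len(nrow(hits)), band)) {
      h <- hits[b, , drop = FALSE]
      d <- as.integer(round(stats::median(h$diag)))
      tgt <- h$tgt[1]
      ext <- extend_diagonal(qs, genome_index$seqs[[tgt]], d)
      if (is.null(ext)) next
      len <- ext$qend - ext$qstart + 1L
      if (len < min_segment || ext$identity < min_identity) next
      # map the oriented-query interval back to the forward contig
      if (st == "+") {
        cs <- ext$qstart - 1L
        ce <- ext$qend
      } else {
        cs <- L - ext$qend
        ce <- L - ext$qstart + 1L
      }
      out[[length(out) + 1L]] <- tibble(
        contig_id = contig_id,
        contig_start = cs, contig_end = ce,
        chrom = genome_index$targets[tgt],
        genome_start = ext$tstart - 1L, genome_end = ext$tend,
        strand = st, identity = ext$identity, score = ext$score
      )
    }
  }
  if (length(out) == 0) {
    return(empty_segments())
  }
  segs <- dplyr::bind_rows(out)
  # drop segments fully shadowed by a higher-scoring segment on the contig
  segs <- dplyr::arrange(segs, dplyr::desc(.data$score))
  keep <- rep(TRUE, nrow(segs))
  for (i in seq_len(nrow(segs))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(segs))) {
      if (i == j || !keep[j]) next
      if (segs$contig_start[j] >= segs$contig_start[i] - 5L &&
        segs$contig_end[j] <= segs$contig_end[i] + 5L &&
        segs$score[j] <= segs$score[i]) {
        keep[j] <- FALSE
      }
    }
  }
  dplyr::arrange(segs[keep, , drop = FALSE], .data$contig_start)
}

empty_segments <- function() {
  tibble(
    contig_id = character(0), contig_start = integer(0),
    contig_end = integer(0), chrom = character(0),
    genome_start = integer(0), genome_end = integer(0),
    strand = character(0), identity = numeric(0), score = numeric(0)
  )
}

# breakpoint at the junction-adjacent end of a segment, 1-based genomic
segment_breakpoint <- function(seg, side) {
  if (side == "5") {
    pos <- if (seg$strand == "+") seg$genome_end else seg$genome_start + 1L
  } else {
    pos <- if (seg$strand == "+") seg$genome_start + 1L else seg$genome_end
  }
  list(chrom = seg$chrom, pos = as.integer(pos), strand = seg$strand)
}

#' Call breakpoint candidates from a contig's segments
#'
#' For each ordered pair of segments that tile the contig (gap and overlap on
#' the contig both <= `max_junction_slop`) and come from non-contiguous
#' genomic regions -- different chromosomes, a genomic gap above
#' `min_genomic_gap` (fusion scale rather than intron scale), or a strand
#' change -- emits one candidate with the junction offset at the segment
#' join. Single-segment contigs emit nothing.
#'
#' When the two segments overlap on the contig (the aligner extended each
#' past the junction through microhomology or chance matches), the junction
#' is refined to the split point that maximises the total matches of the
#' contig against the two genomic continuations, provided the contig sequence
#' and genome are supplied.
#'
#' @param segments Segment tibble for one contig from [split_align()].
#' @param min_genomic_gap Same-chromosome, same-strand gaps at or below this
#'   size are treated as splicing, not fusion.
#' @param max_junction_slop Maximum contig-coordinate gap/overlap between the
#'   two segments.
#' @param contig_seq,genome Optional contig sequence and genome for junction
#'   refinement.
#' @return Tibble of candidates: contig_id, junction_offset, breakpoint
#'   chrom/pos/strand for the 5' and 3' sides (1-based), and the segment
#'   coordinates for both sides.
#' @export
call_candidates <- function(segments, min_genomic_gap = 10000L,
                            max_junction_slop = 10L,
                            contig_seq = NULL, genome = NULL) {
  n <- nrow(segments)
  if (n < 2) {
    return(empty_candidates())
  }
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s5 <- segments[i, ]
      s3 <- segments[j, ]
      if (s3$contig_start < s5$contig_start) next # 5' side comes first
      slop <- s3$contig_start - s5$contig_end
      if (abs(slop) > max_junction_slop) next
      noncontig <- s5$chrom != s3$chrom ||
        s5$strand != s3$strand ||
        genomic_gap(s5, s3) > min_genomic_gap
      if (!noncontig) next
      bp5 <- segment_breakpoint(s5, "5")
      bp3 <- segment_breakpoint(s3, "3")
      junction <- as.integer(s5$contig_end)
      if (slop != 0) {
        # the segments overlap (microhomology, chance matches past the
        # junction) or leave a gap (errors at the junction went unaligned);
        # both breakpoints must come from one split point or the construct
        # acquires an indel relative to the reads. Place the split optimally
        # against the two genomic continuations when sequence is available,
        # else resolve the inconsistency toward the 5' side.
        if (!is.null(contig_seq) && !is.null(genome)) {
          ref <- refine_junction(contig_seq, s5, s3, genome)
          junction <- ref$junction
          bp5$pos <- ref$pos5
          bp3$pos <- ref$pos3
        } else if (slop < 0) {
          bp3$pos <- if (s3$strand == "+") bp3$pos - slop else bp3$pos + slop
        } else {
          junction <- as.integer(s3$contig_start)
          bp5$pos <- if (s5$strand == "+") bp5$pos + slop else bp5$pos - slop
        }
      }
      out[[length(out) + 1L]] <- tibble(
        contig_id = s5$contig_id,
        junction_offset = junction,
        chrom5 = bp5$chrom, pos5 = bp5$pos, strand5 = bp5$strand,
        chrom3 = bp3$chrom, pos3 = bp3$pos, strand3 = bp3$strand,
        contig_start5 = s5$contig_start, contig_end5 = s5$contig_end,
        contig_start3 = s3$contig_start, contig_end3 = s3$contig_end,
        span5 = s5$contig_end - s5$contig_start,
        span3 = s3$contig_end - s3$contig_start
      )
    }
  }
  if (length(out) == 0) {
    return(empty_candidates())
  }
  cand <- dplyr::bind_rows(out)
  # one candidate per contig junction: keep the pair with the largest total
  # aligned span
  cand <- dplyr::slice_head(
    dplyr::arrange(
      dplyr::group_by(cand, .data$contig_id, .data$junction_offset),
      dplyr::desc(.data$span5 + .data$span3), .data$chrom5, .data$chrom3
    ),
    n = 1
  )
  dplyr::ungroup(cand)
}

# genomic position a contig base maps to when carried by a segment's diagonal
seg_gpos <- function(seg, p, side) {
  if (side == "5") {
    if (seg$strand == "+") {
      seg$genome_end - seg$contig_end + p
    } else {
      seg$genome_start + 1L + seg$contig_end - p
    }
  } else {
    if (seg$strand == "+") {
      seg$genome_start - seg$contig_start + p
    } else {
      seg$genome_end + seg$contig_start - p + 1L
    }
  }
}

genome_base <- function(genome, chrom, pos, strand) {
  s <- genome[[chrom]]
  if (pos < 1L || pos > nchar(s)) {
    return("N")
  }
  b <- substring(s, pos, pos)
  if (strand == "+") b else chartr("ACGTN", "TGCAN", b)
}

# optimal split of the contig's ambiguous junction window between the 5' and
# 3' genomic continuations: maximises total matches; ties resolve to the
# smallest junction offset. The window covers the segment overlap or gap.
refine_junction <- function(contig_seq, s5, s3, genome) {
  lo <- max(min(s3$contig_start, s5$contig_end), s5$contig_start + 1L)
  hi <- min(max(s3$contig_start, s5$contig_end), s3$contig_end - 1L)
  if (hi <= lo) {
    x <- max(lo, hi)
    return(list(
      junction = as.integer(x),
      pos5 = as.integer(seg_gpos(s5, x, "5")),
      pos3 = as.integer(seg_gpos(s3, x + 1L, "3"))
    ))
  }
  ps <- (lo + 1L):hi # contig bases inside the overlap window (1-based)
  cb <- strsplit(substring(contig_seq, lo + 1L, hi), "", fixed = TRUE)[[1]]
  m5 <- vapply(seq_along(ps), function(i) {
    cb[i] == genome_base(
      genome, s5$chrom, seg_gpos(s5, ps[i], "5"), s5$strand
    )
  }, TRUE)
  m3 <- vapply(seq_along(ps), function(i) {
    cb[i] == genome_base(
      genome, s3$chrom, seg_gpos(s3, ps[i], "3"), s3$strand
    )
  }, TRUE)
  # score of junction offset x = matches to 5' side through x plus matches to
  # 3' side after x, for x in lo..hi
  left <- c(0, cumsum(m5))
  right <- rev(c(0, cumsum(rev(m3))))
  score <- left + right
  x <- (lo:hi)[which.max(score)]
  list(
    junction = as.integer(x),
    pos5 = as.integer(seg_gpos(s5, x, "5")),
    pos3 = as.integer(seg_gpos(s3, x + 1L, "3"))
  )
}

genomic_gap <- function(s5, s3) {
  if (s5$chrom != s3$chrom) {
    return(Inf)
  }
  lo <- min(s5$genome_end, s3$genome_end)
  hi <- max(s5$genome_start, s3$genome_start)
  max(0L, hi - lo)
}

empty_candidates <- function() {
  tibble(
    contig_id = character(0), junction_offset = integer(0),
    chrom5 = character(0), pos5 = integer(0), strand5 = character(0),
    chrom3 = character(0), pos3 = integer(0), strand3 = character(0),
    contig_start5 = integer(0), contig_end5 = integer(0),
    contig_start3 = integer(0), contig_end3 = integer(0),
    span5 = integer(0), span3 = integer(0)
  )
}

#' Collapse redundant breakpoint candidates
#'
#' Candidates whose breakpoints agree within `merge_window` bases on both
#' sides (same chromosomes and strands) merge into one, keeping the candidate
#' from the longest contig and recording every member contig id.
#'
#' @param candidates Candidate tibble (from [call_candidates()], possibly
#'   many contigs), with a `contig_length` column if contig lengths are known.
#' @param merge_window Breakpoint agreement window (bases).
#' @return The collapsed candidate tibble with a `member_contigs` list-column
#'   and `n_contigs` count.
#' @export
collapse_redundant <- function(candidates, merge_window = 5L) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates,
      member_contigs = list(), n_contigs = integer(0)
    ))
  }
  if (!"contig_length" %in% names(candidates)) {
    candidates$contig_length <- candidates$contig_end3
  }
  ord <- order(-candidates$contig_length, candidates$contig_id)
  cand <- candidates[ord, , drop = FALSE]
  taken <- rep(FALSE, nrow(cand))
  out <- list()
  for (i in seq_len(nrow(cand))) {
    if (taken[i]) next
    same <- !taken &
      cand$chrom5 == cand$chrom5[i] & cand$chrom3 == cand$chrom3[i] &
      cand$strand5 == cand$strand5[i] & cand$strand3 == cand$strand3[i] &
      abs(cand$pos5 - cand$pos5[i]) <= merge_window &
      abs(cand$pos3 - cand$pos3[i]) <= merge_window
    taken[same] <- TRUE
    row <- cand[i, , drop = FALSE]
    row$member_contigs <- list(sort(cand$contig_id[same]))
    row$n_contigs <- sum(same)
    out[[length(out) + 1L]] <- row
  }
  dplyr::bind_rows(out)
}
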