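# Greedy per-gene overlap-layout-consensus assembly. Candidate suffix-prefix
# overlaps are found through shared k-mers (both orientations), the pair with
# the longest admissible overlap is merged first, and merging repeats until no
# overlap of at least `min_overlap` bases at `min_identity` remains. Ties are
# broken by lexicographic contig ids, so assembly is deterministic.

ctg_record <- function(id, seq, members, k) {
  codes <- kmer_codes(seq, k)
  rc_seq <- revcomp(seq)
  list(
    id = id, seq = seq, rc_seq = rc_seq, members = members,
    codes = codes,
    rc_codes = kmer_codes(rc_seq, k),
    scodes = sort(codes[!is.na(codes)])
  )
}

# identity-checked overlap length for contig b (oriented) at shift s rel a;
# 0 when inadmissible. Scattered mismatches are sequencing error, but a
# contiguous mismatch block marks an incompatible branch (e.g. two different
# junctions sharing one gene); such overlaps must not merge or the minority
# branch is silently overwritten.
eval_shift <- function(aseq, bseq, s, min_overlap, min_identity,
                       max_mismatch_run = 5L) {
  la <- nchar(aseq)
  lb <- nchar(bseq)
  ov <- min(la, s + lb) - max(0L, s)
  if (ov < min_overlap) {
    return(0L)
  }
  a1 <- max(0L, s) + 1L
  b1 <- max(0L, -s) + 1L
  m <- char_matches(
    substring(aseq, a1, a1 + ov - 1L),
    substring(bseq, b1, b1 + ov - 1L)
  )
  if (mean(m) < min_identity) {
    return(0L)
  }
  if (!all(m)) {
    r <- rle(m)
    if (max(r$lengths[!r$values]) > max_mismatch_run) {
      return(0L)
    }
  }
  ov
}

# best admissible merge of contig b onto contig a; shift s is the 0-based
# offset of (oriented) b's start relative to a's start
best_overlap <- function(ca, cb, min_overlap, min_identity, max_shifts = 8L) {
  la <- nchar(ca$seq)
  lb <- nchar(cb$seq)
  best <- NULL
  # forward overlaps take precedence; the reverse complement is only
  # consulted when the pair has no admissible forward overlap
  for (orient in c("+", "-")) {
    if (orient == "-" && !is.null(best)) break
    bcodes <- if (orient == "+") cb$codes else cb$rc_codes
    if (length(bcodes) == 0 || length(ca$codes) == 0) next
    ia <- match(bcodes, ca$codes)
    hit <- which(!is.na(ia))
    if (length(hit) == 0) next
    shifts <- unique(ia[hit] - hit)
    ov_of <- pmin(la, shifts + lb) - pmax(0L, shifts)
    keep <- ov_of >= min_overlap
    shifts <- shifts[keep]
    ov_of <- ov_of[keep]
    o <- order(-ov_of)
    shifts <- head(shifts[o], max_shifts)
    bseq <- if (orient == "+") cb$seq else cb$rc_seq
    for (s in shifts) {
      ov <- eval_shift(ca$seq, bseq, s, min_overlap, min_identity)
      if (ov > 0 && (is.null(best) || ov > best$ov)) {
        best <- list(ov = ov, shift = s, orient = orient)
      }
      if (!is.null(best) && length(shifts) > 0 && ov == max(ov_of)) break
    }
  }
  best
}

merge_pair <- function(ca, cb, ov) {
  bseq <- if (ov$orient == "+") cb$seq else cb$rc_seq
  la <- nchar(ca$seq)
  lb <- nchar(bseq)
  s <- ov$shift
  if (s >= 0) {
    if (s + lb <= la) ca$seq else paste0(ca$seq, substring(bseq, la - s + 1L))
  } else {
    if (-s + la <= lb) bseq else paste0(substring(bseq, 1L, -s), ca$seq)
  }
}

# initial overlap edges from one global k-mer join: for every contig pair and
# orientation, candidate shifts are the (a-position - b-position) differences
# of shared k-mers; the longest identity-passing shift per pair becomes the
# edge weight
initial_edges <- function(ctgs, min_overlap, min_identity) {
  n <- length(ctgs)
  nc <- vapply(ctgs, function(x) length(x$codes), 0L)
  fwd <- list(
    code = unlist(lapply(ctgs, `[[`, "codes"), use.names = FALSE),
    id = rep(seq_len(n), nc),
    pos = unlist(lapply(nc, seq_len), use.names = FALSE)
  )
  nrc <- vapply(ctgs, function(x) length(x$rc_codes), 0L)
  rc <- list(
    code = unlist(lapply(ctgs, `[[`, "rc_codes"), use.names = FALSE),
    id = rep(seq_len(n), nrc),
    pos = unlist(lapply(nrc, seq_len), use.names = FALSE)
  )
  join_pairs <- function(a, b, orient) {
    ok_a <- !is.na(a$code)
    ua <- sort(unique(a$code[ok_a]))
    ib <- findInterval(b$code, ua)
    okb <- which(ib > 0 & !is.na(b$code))
    okb <- okb[ua[ib[okb]] == b$code[okb]]
    if (length(okb) == 0) {
      return(NULL)
    }
    # expand: group a rows by code, then match each b row to its a rows
    oa <- order(a$code[ok_a])
    a_id <- a$id[ok_a][oa]
    a_pos <- a$pos[ok_a][oa]
    a_code <- a$code[ok_a][oa]
    code_off <- c(0L, cumsum(tabulate(findInterval(a_code, ua), length(ua))))
    bi <- ib[okb]
    counts <- code_off[bi + 1L] - code_off[bi]
    rows <- sequence(counts, from = code_off[bi] + 1L)
    list(
      a = a_id[rows], b = rep(b$id[okb], counts),
      s = a_pos[rows] - rep(b$pos[okb], counts),
      orient = orient
    )
  }
  ff <- join_pairs(fwd, fwd, "+")
  fr <- join_pairs(fwd, rc, "-")
  edges <- list()
  fwd_edges <- character(0)
  for (jp in list(ff, fr)) {
    if (is.null(jp)) next
    keep <- jp$a < jp$b
    if (jp$orient == "+") {
      # (a, b, s) and (b, a, -s) describe the same forward overlap
      a <- jp$a[keep]
      b <- jp$b[keep]
      s <- jp$s[keep]
    } else {
      a <- jp$a[keep]
      b <- jp$b[keep]
      s <- jp$s[keep]
    }
    if (length(a) == 0) next
    key <- (a * 2^22 + b) * 2^15 + (s + 2^14)
    o <- order(key)
    r <- rle(key[o])
    last <- cumsum(r$lengths)
    ua <- a[o][last]
    ub <- b[o][last]
    us <- s[o][last]
    for (i in seq_along(ua)) {
      ia <- ua[i]
      ib2 <- ub[i]
      bseq <- if (jp$orient == "+") ctgs[[ib2]]$seq else ctgs[[ib2]]$rc_seq
      ov <- eval_shift(
        ctgs[[ia]]$seq, bseq, us[i], min_overlap, min_identity
      )
      if (ov > 0) {
        pk <- paste(ctgs[[ia]]$id, ctgs[[ib2]]$id)
        if (jp$orient == "-" && pk %in% fwd_edges) next
        old <- edges[[pk]]
        if (is.null(old) || ov > old) {
          edges[[pk]] <- ov
          if (jp$orient == "+") fwd_edges <- c(fwd_edges, pk)
        }
      }
    }
  }
  edges
}

#' Assemble reads into contigs by greedy overlap merging
#'
#' @param seqs Character vector of read sequences (uppercase ACGTN),
#'   transcript-oriented where orientation is known; reverse-complement
#'   overlaps are still considered.
#' @param ids Optional read ids (default seq_along names).
#' @param min_overlap Minimum suffix-prefix overlap merged (bases).
#' @param min_identity Minimum identity within the overlap.
#' @param k Seed length used to locate candidate overlaps (capped at
#'   `min_overlap`).
#' @return A tibble with one contig per row: contig_id, seq, length,
#'   member_count and a `members` list-column of read ids; every input read
#'   appears in exactly one contig (singletons are emitted as contigs).
#'   Contigs are ordered by decreasing length, then sequence.
#' @export
#' @examples
#' assemble_reads(c("AAAACCCCGGGG", "CCCCGGGGTTTT"), min_overlap = 8)
assemble_reads <- function(seqs, ids = NULL, min_overlap = 30L,
                           min_identity = 0.9, k = 15L) {
  if (length(seqs) == 0) {
    return(tibble(
      contig_id = character(0), seq = character(0), length = integer(0),
      member_count = integer(0), members = list()
    ))
  }
  k <- min(as.integer(k), as.integer(min_overlap))
  ids <- ids %||% sprintf("read_%d", seq_along(seqs))
  # identical sequences collapse up front; they assemble identically
  grp <- match(seqs, unique(seqs))
  useqs <- unique(seqs)
  ctgs <- list()
  for (i in seq_along(useqs)) {
    cid <- sprintf("c%06d", i)
    ctgs[[cid]] <- ctg_record(cid, useqs[i], ids[grp == i], k)
  }
  next_id <- length(useqs)
  einit <- initial_edges(ctgs, min_overlap, min_identity)
  if (length(einit) > 0) {
    parts <- strsplit(names(einit), " ", fixed = TRUE)
    e_a <- vapply(parts, `[`, "", 1)
    e_b <- vapply(parts, `[`, "", 2)
    e_ov <- as.integer(unlist(einit, use.names = FALSE))
  } else {
    e_a <- e_b <- character(0)
    e_ov <- integer(0)
  }

  while (length(e_ov) > 0) {
    best_i <- order(-e_ov, e_a, e_b)[1]
    ea <- e_a[best_i]
    eb <- e_b[best_i]
    ca <- ctgs[[ea]]
    cb <- ctgs[[eb]]
    ov <- best_overlap(ca, cb, min_overlap, min_identity)
    next_id <- next_id + 1L
    nid <- sprintf("c%06d", next_id)
    ctgs[[nid]] <- ctg_record(
      nid, merge_pair(ca, cb, ov), c(ca$members, cb$members), k
    )
    ctgs[[ea]] <- NULL
    ctgs[[eb]] <- NULL
    keep <- !(e_a %in% c(ea, eb) | e_b %in% c(ea, eb))
    e_a <- e_a[keep]
    e_b <- e_b[keep]
    e_ov <- e_ov[keep]
    # new contig vs remaining contigs sharing a k-mer
    cn <- ctgs[[nid]]
    slook <- sort(unique(c(cn$codes, cn$rc_codes)))
    for (oid in setdiff(names(ctgs), nid)) {
      co <- ctgs[[oid]]
      fi <- findInterval(co$scodes, slook)
      shared <- any(fi > 0 & slook[pmax(fi, 1L)] == co$scodes)
      if (!shared) next
      ovn <- best_overlap(cn, co, min_overlap, min_identity)
      if (!is.null(ovn)) {
        e_a <- c(e_a, nid)
        e_b <- c(e_b, oid)
        e_ov <- c(e_ov, ovn$ov)
      }
    }
  }

  seq_out <- vapply(ctgs, `[[`, "", "seq")
  members <- lapply(ctgs, `[[`, "members")
  o <- order(-nchar(seq_out), seq_out)
  tibble(
    contig_id = sprintf("CTG%04d", seq_along(o)),
    seq = unname(seq_out[o]),
    length = unname(nchar(seq_out[o])),
    member_count = unname(vapply(members[o], length, 0L)),
    members = unname(members[o])
  )
}
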