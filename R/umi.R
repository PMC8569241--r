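# Alignment-free PCR-duplicate collapsing. Reads are clustered by UMI with a
# hamming-distance tolerance; each cluster yields a single consensus read per
# mate whose base calls and Phred scores come from a Bayesian posterior over
# the four nucleotides, assuming conditionally independent observations with
# the standard Phred error model.

#' Hamming distance between two equal-length strings
#'
#' @param u1,u2 Character scalars of equal length.
#' @return Integer count of mismatching positions.
#' @export
#' @examples
#' umi_hamming("ACGT", "ACGA")
umi_hamming <- function(u1, u2) {
  if (nchar(u1) != nchar(u2)) {
    stop("hamming distance requires equal-length strings", call. = FALSE)
  }
  sum(utf8ToInt(u1) != utf8ToInt(u2))
}

#' Encode/decode a UMI as a 2-bit-per-base integer
#'
#' The encoding is injective for UMIs up to 16 bases over {A,C,G,T}
#' (A=0, C=1, G=2, T=3, most significant base first); the numeric value is
#' exact as a double.
#'
#' @param umi A character scalar over {A,C,G,T}, length <= 16.
#' @param code A numeric code from `encode_umi()`.
#' @param length UMI length to decode to.
#' @return `encode_umi()` a numeric scalar; `decode_umi()` the UMI string.
#' @export
#' @examples
#' decode_umi(encode_umi("ACGT"), 4)
encode_umi <- function(umi) {
  if (nchar(umi) > 16) {
    stop("UMI longer than 16 bases cannot be 2-bit encoded", call. = FALSE)
  }
  codes <- base_codes(umi)
  if (anyNA(codes)) {
    stop("UMI contains a non-ACGT base", call. = FALSE)
  }
  sum(as.numeric(codes) * 4^(rev(seq_along(codes)) - 1))
}

#' @rdname encode_umi
#' @export
decode_umi <- function(code, length) {
  codes <- integer(length)
  for (i in rev(seq_len(length))) {
    codes[i] <- code %% 4
    code <- code %/% 4
  }
  codes_to_seq(codes)
}

#' Cluster reads by UMI
#'
#' Greedy count-descending clustering: the most frequent exact UMI seeds a
#' cluster and absorbs all unassigned UMIs within `max_hamming` of it. Seeds
#' are taken in descending (count, encoded-UMI) order so the result is
#' deterministic regardless of input order. UMIs containing N form their own
#' singleton clusters.
#'
#' @param umis Character vector of per-read (or per-pair) UMIs, equal lengths.
#' @param max_hamming Maximum hamming distance absorbed into a cluster.
#' @return An integer vector of cluster ids parallel to `umis`, with attribute
#'   `representatives` giving the seed UMI of each cluster.
#' @export
cluster_umis <- function(umis, max_hamming = 1L) {
  if (length(umis) == 0) {
    return(structure(integer(0), representatives = character(0)))
  }
  if (length(unique(nchar(umis))) != 1) {
    stop("all UMIs must have the same length", call. = FALSE)
  }
  has_n <- grepl("N", umis, fixed = TRUE)
  uniq <- unique(umis[!has_n])
  assign <- integer(length(umis))
  reps <- character(0)
  if (length(uniq) > 0) {
    counts <- table(factor(umis[!has_n], levels = uniq))
    enc <- vapply(uniq, encode_umi, 0)
    ord <- order(-as.integer(counts), enc)
    uniq <- uniq[ord]
    umat <- matrix(
      utf8ToInt(paste(uniq, collapse = "")),
      nrow = length(uniq), byrow = TRUE
    )
    cl_of_uniq <- integer(length(uniq))
    next_cl <- 0L
    for (i in seq_along(uniq)) {
      if (cl_of_uniq[i] != 0L) next
      next_cl <- next_cl + 1L
      reps[next_cl] <- uniq[i]
      open <- which(cl_of_uniq == 0L)
      hd <- rowSums(umat[open, , drop = FALSE] !=
        matrix(umat[i, ], length(open), ncol(umat), byrow = TRUE))
      cl_of_uniq[open[hd <= max_hamming]] <- next_cl
    }
    assign[!has_n] <- cl_of_uniq[match(umis[!has_n], uniq)]
  } else {
    next_cl <- 0L
  }
  if (any(has_n)) {
    n_ids <- next_cl + seq_len(sum(has_n))
    assign[has_n] <- n_ids
    reps[n_ids] <- umis[has_n]
  }
  structure(assign, representatives = reps)
}

#' Bayesian consensus for one position
#'
#' Posterior over the four bases given independent observations:
#' P(b | obs) is proportional to pi_b * prod_i L(obs_i | b), with
#' L = (1 - e_i) when the observed base equals b and e_i / 3 otherwise, where
#' e_i = 10^(-Q_i / 10). The consensus is the posterior argmax (ties broken
#' A < C < G < T) and its Phred score is -10 log10(1 - P_max), capped.
#'
#' @param bases Character vector of observed bases at the position.
#' @param quals Integer vector of their Phred scores.
#' @param prior Length-4 prior over A,C,G,T (defaults to uniform).
#' @param qual_cap Maximum reported consensus quality.
#' @return A list: `base`, `qual`, and the length-4 `posterior`.
#' @export
#' @examples
#' consensus_base(c("A", "A", "A"), c(30, 30, 30))
consensus_base <- function(bases, quals, prior = rep(0.25, 4), qual_cap = 60L) {
  if (length(bases) == 0) {
    stop("consensus requires at least one observation", call. = FALSE)
  }
  stopifnot(length(bases) == length(quals), length(prior) == 4)
  e <- 10^(-quals / 10)
  loglik <- vapply(BASES, function(b) {
    sum(ifelse(bases == b, log1p(-e), log(e / 3)))
  }, 0)
  logpost <- log(prior) + loglik
  logpost <- logpost - max(logpost)
  post <- exp(logpost) / sum(exp(logpost))
  k <- which.max(post) # which.max takes the first maximum: A < C < G < T
  q <- -10 * log10(max(1 - post[k], 1e-300))
  list(
    base = BASES[k],
    qual = as.integer(min(round(q), qual_cap)),
    posterior = setNames(post, BASES)
  )
}

# consensus over a cluster of sequences (one mate): modal length wins, shorter
# members contribute only to the positions they cover; returns seq + quals
consensus_sequence <- function(seqs, qual_strs, qual_cap = 60L) {
  if (length(seqs) == 1) {
    return(list(seq = seqs, qual = qual_strs))
  }
  lens <- nchar(seqs)
  tab <- table(lens)
  L <- as.integer(names(tab)[which.max(tab)]) # modal length, ties -> shortest
  n <- length(seqs)
  bmat <- matrix(NA_integer_, n, L)
  qmat <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    li <- min(lens[i], L)
    bmat[i, seq_len(li)] <- base_codes(substring(seqs[i], 1, li))
    qmat[i, seq_len(li)] <- chr_to_phred(substring(qual_strs[i], 1, li))
  }
  e <- 10^(-qmat / 10)
  log_mis <- log(e / 3)
  log_hit <- log1p(-e)
  # per-position log-likelihood for each of the 4 hypotheses (uniform prior)
  post_best <- numeric(L)
  best <- integer(L)
  ll <- matrix(0, 4, L)
  for (b in 0:3) {
    contrib <- ifelse(bmat == b, log_hit, log_mis)
    contrib[is.na(contrib)] <- 0 # uncovered or N positions are uninformative
    ll[b + 1L, ] <- colSums(contrib)
  }
  mx <- apply(ll, 2, max)
  pw <- exp(sweep(ll, 2, mx))
  ps <- sweep(pw, 2, colSums(pw), "/")
  best <- apply(ps, 2, which.max)
  post_best <- ps[cbind(best, seq_len(L))]
  q <- pmin(as.integer(round(-10 * log10(pmax(1 - post_best, 1e-300)))), qual_cap)
  list(seq = codes_to_seq(best - 1L), qual = phred_to_chr(q))
}

#' Collapse PCR duplicates to UMI consensus read pairs
#'
#' Extracts the UMI from the configured mate, clusters read pairs by UMI, and
#' emits one consensus pair per cluster. Consensus bases and qualities come
#' from [consensus_base()]'s posterior model applied per position; the UMI
#' bases are removed from the output sequence. Output rows are ordered by the
#' encoded representative UMI so results are reproducible.
#'
#' @param reads A reads tibble (read_id, mate, seq, qual) with synchronized
#'   mates.
#' @param umi_length,umi_read,umi_offset UMI read structure.
#' @param max_hamming UMI clustering tolerance.
#' @param qual_cap Consensus quality cap.
#' @param split_by_prefix If > 0, clusters are additionally split by the first
#'   `split_by_prefix` template bases, so distinct molecules that collided on
#'   one UMI are not merged.
#' @return A list: `reads` (consensus reads tibble with columns read_id, mate,
#'   seq, qual, umi, duplicate_count, source_read_ids) and `stats`
#'   (input_pairs, clusters, mean_duplicates).
#' @export
dedupe_reads <- function(reads, umi_length = 12L, umi_read = "R1",
                         umi_offset = 0L, max_hamming = 1L, qual_cap = 60L,
                         split_by_prefix = 0L) {
  r1 <- reads[reads$mate == "R1", , drop = FALSE]
  r2 <- reads[reads$mate == "R2", , drop = FALSE]
  if (nrow(r1) != nrow(r2) || !setequal(r1$read_id, r2$read_id)) {
    bad <- c(setdiff(r1$read_id, r2$read_id), setdiff(r2$read_id, r1$read_id))
    stop("desynchronized mates; offending read id(s): ",
      paste(head(bad, 3), collapse = ", "),
      call. = FALSE
    )
  }
  r2 <- r2[match(r1$read_id, r2$read_id), , drop = FALSE]
  n <- nrow(r1)
  if (n == 0) {
    return(list(
      reads = tibble(
        read_id = character(0), mate = character(0), seq = character(0),
        qual = character(0), umi = character(0),
        duplicate_count = integer(0), source_read_ids = list()
      ),
      stats = list(input_pairs = 0L, clusters = 0L, mean_duplicates = NA_real_)
    ))
  }
  carrier <- if (umi_read == "R1") r1 else r2
  umi <- substring(carrier$seq, umi_offset + 1L, umi_offset + umi_length)
  strip <- function(x) {
    x$seq <- paste0(
      substring(x$seq, 1L, umi_offset),
      substring(x$seq, umi_offset + umi_length + 1L)
    )
    x$qual <- paste0(
      substring(x$qual, 1L, umi_offset),
      substring(x$qual, umi_offset + umi_length + 1L)
    )
    x
  }
  if (umi_read == "R1") r1 <- strip(r1) else r2 <- strip(r2)

  cl <- cluster_umis(umi, max_hamming = max_hamming)
  reps <- attr(cl, "representatives")
  key <- as.integer(cl)
  if (split_by_prefix > 0) {
    pre <- substring(r1$seq, 1L, split_by_prefix)
    key <- match(paste(key, pre), unique(paste(key, pre)))
    # representative of a split cluster is still its UMI seed
    reps <- reps[as.integer(cl)][!duplicated(paste(as.integer(cl), pre))]
  }
  groups <- split(seq_len(n), key)
  rep_of_group <- vapply(groups, function(ix) reps[unique(key[ix])][1], "")
  # deterministic output order: by encoded representative UMI (N-containing
  # representatives sort last, by string)
  enc <- suppressWarnings(vapply(rep_of_group, function(u) {
    tryCatch(encode_umi(u), error = function(e) NA_real_)
  }, 0))
  ord <- order(is.na(enc), enc, rep_of_group)
  groups <- groups[ord]
  rep_of_group <- unname(rep_of_group[ord])

  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    ix <- groups[[gi]]
    c1 <- consensus_sequence(r1$seq[ix], r1$qual[ix], qual_cap)
    c2 <- consensus_sequence(r2$seq[ix], r2$qual[ix], qual_cap)
    id <- sprintf("umi_%s_%d", rep_of_group[gi], length(ix))
    out[[gi]] <- tibble(
      read_id = id, mate = c("R1", "R2"),
      seq = c(c1$seq, c2$seq), qual = c(c1$qual, c2$qual),
      umi = rep_of_group[gi],
      duplicate_count = length(ix),
      source_read_ids = list(r1$read_id[ix])
    )
  }
  cons <- dplyr::bind_rows(out)
  list(
    reads = cons,
    stats = list(
      input_pairs = n,
      clusters = length(groups),
      mean_duplicates = n / length(groups)
    )
  )
}

#' File-level FASTQ dedup wrapper
#'
#' @param r1,r2 Input FASTQ paths.
#' @param out_r1,out_r2 Output FASTQ paths for the consensus pairs.
#' @param ... Passed to [dedupe_reads()].
#' @return The `stats` list, invisibly; consensus FASTQs are written to the
#'   output paths.
#' @export
dedupe_fastq <- function(r1, r2, out_r1, out_r2, ...) {
  res <- dedupe_reads(read_fastq_pair(r1, r2), ...)
  write_fastq(res$reads, out_r1, mate = "R1")
  write_fastq(res$reads, out_r2, mate = "R2")
  invisible(res$stats)
}
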