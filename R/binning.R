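# Gene-level read binning: reads are aligned to a reference of one transcript
# per gene (the longest coding transcript), each pair is binned by its better
# scoring mate, and identical-coordinate alignment copies are capped before
# assembly.

#' Build the gene-level transcript reference
#'
#' Selects per gene the transcript with the longest CDS (ties broken by total
#' transcript length, then lexicographic transcript id) and splices its
#' sequence from the genome, reverse-complementing minus-strand transcripts.
#' Genes without CDS annotation fall back to the longest transcript with a
#' warning.
#'
#' @param transcripts Exon-level transcript tibble (gene, transcript_id,
#'   chrom, strand, exon, start, end, cds_start, cds_end).
#' @param genome Named character vector of chromosome sequences.
#' @return Named character vector of per-gene transcript sequences with a
#'   `provenance` attribute (tibble: gene, transcript_id).
#' @export
build_gene_reference <- function(transcripts, genome) {
  # CDS length = exonic overlap with [cds_start, cds_end]
  per_tx <- dplyr::summarise(
    dplyr::group_by(transcripts, .data$gene, .data$transcript_id),
    cds_len = if (all(is.na(.data$cds_start))) {
      0L
    } else {
      sum(pmax(
        0L,
        pmin(.data$end, .data$cds_end) - pmax(.data$start, .data$cds_start) + 1L
      ))
    },
    total_len = sum(.data$end - .data$start + 1L),
    .groups = "drop"
  )
  pick <- dplyr::slice_head(
    dplyr::arrange(
      dplyr::group_by(per_tx, .data$gene),
      dplyr::desc(.data$cds_len), dplyr::desc(.data$total_len),
      .data$transcript_id
    ),
    n = 1
  )
  pick <- dplyr::ungroup(pick)
  noncoding <- pick$gene[pick$cds_len == 0]
  if (length(noncoding) > 0) {
    warning(
      "no coding transcript for gene(s) ",
      paste(noncoding, collapse = ", "), "; using longest transcript"
    )
  }
  seqs <- vapply(seq_len(nrow(pick)), function(i) {
    ex <- transcripts[
      transcripts$transcript_id == pick$transcript_id[i], ,
      drop = FALSE
    ]
    ex <- ex[order(ex$exon), , drop = FALSE]
    pieces <- substring(genome[[ex$chrom[1]]], ex$start, ex$end)
    if (ex$strand[1] == "-") pieces <- revcomp(pieces)
    paste(pieces, collapse = "")
  }, "")
  structure(setNames(seqs, pick$gene),
    provenance = pick[, c("gene", "transcript_id")]
  )
}

#' Align consensus reads to the gene reference and bin read pairs by gene
#'
#' Every read is aligned to the per-gene transcript reference with the
#' internal seed-and-extend engine; its single best alignment (score ties
#' broken by gene name, then start) decides the bin. A pair is binned by its
#' better-scoring mate and both mates enter that gene's bin, oriented to the
#' transcript's forward strand. Pairs with no alignment form the unassigned
#' pool, which is still carried to confirmation.
#'
#' @param reads Reads tibble (consensus reads).
#' @param gene_ref Named per-gene sequences from [build_gene_reference()].
#' @param k Seed length.
#' @param min_score Minimum alignment score for a read to be considered
#'   aligned.
#' @return A list: `alignments` (tibble with read_id, mate, gene, start, end
#'   0-based half-open on the transcript, strand, score, aligned_len, and the
#'   transcript-oriented sequence `oriented_seq`), and `unassigned` (reads
#'   tibble).
#' @export
align_to_genes <- function(reads, gene_ref, k = 17L, min_score = 20) {
  if (length(gene_ref) == 0) {
    stop("empty gene reference", call. = FALSE)
  }
  if (nrow(reads) == 0) {
    return(list(
      alignments = tibble(), unassigned = reads
    ))
  }
  idx <- kmer_index(unclass(gene_ref), k = k)
  key <- paste(reads$read_id, reads$mate)
  aln <- align_best(key, reads$seq, idx, min_score = min_score)
  if (nrow(aln) == 0) {
    return(list(alignments = tibble(), unassigned = reads))
  }
  aln <- dplyr::left_join(
    tibble(
      key = key, read_id = reads$read_id, mate = reads$mate,
      seq = reads$seq
    ),
    dplyr::rename(aln, key = "read_id"),
    by = "key"
  )
  aln <- aln[!is.na(aln$target), , drop = FALSE]
  # pair-level bin: better-scoring mate wins; both mates join that gene
  pair_best <- dplyr::slice_head(
    dplyr::arrange(
      dplyr::group_by(aln, .data$read_id),
      dplyr::desc(.data$score), .data$target, .data$tstart
    ),
    n = 1
  )
  pair_gene <- setNames(pair_best$target, pair_best$read_id)
  pair_strand <- setNames(pair_best$strand, pair_best$read_id)
  bin_mate <- setNames(pair_best$mate, pair_best$read_id)

  assigned_ids <- names(pair_gene)
  rows <- reads[reads$read_id %in% assigned_ids, , drop = FALSE]
  rows$gene <- unname(pair_gene[rows$read_id])
  # own alignment coordinates where this mate aligned to the pair's gene
  own <- aln[paste(aln$read_id, aln$mate) %in%
    paste(rows$read_id, rows$mate), , drop = FALSE]
  own_key <- paste(own$read_id, own$mate, own$target)
  row_key <- paste(rows$read_id, rows$mate, rows$gene)
  mi <- match(row_key, own_key)
  rows$start <- ifelse(is.na(mi), NA_integer_, own$tstart[mi] - 1L)
  rows$end <- ifelse(is.na(mi), NA_integer_, own$tend[mi])
  rows$score <- ifelse(is.na(mi), NA_real_, own$score[mi])
  rows$aligned_len <- ifelse(is.na(mi), NA_integer_, own$aligned_len[mi])
  # strand: the mate's own alignment strand, else opposite of the binning mate
  own_strand <- ifelse(is.na(mi), NA_character_, own$strand[mi])
  partner_strand <- unname(pair_strand[rows$read_id])
  same_mate <- rows$mate == unname(bin_mate[rows$read_id])
  rows$strand <- ifelse(!is.na(own_strand), own_strand,
    ifelse(same_mate, partner_strand,
      ifelse(partner_strand == "+", "-", "+")
    )
  )
  rows$oriented_seq <- ifelse(rows$strand == "+", rows$seq, revcomp(rows$seq))
  unassigned <- reads[!(reads$read_id %in% assigned_ids), , drop = FALSE]
  list(
    alignments = as_tibble(rows[, c(
      "read_id", "mate", "gene", "start", "end", "strand", "score",
      "aligned_len", "seq", "oriented_seq"
    )]),
    unassigned = unassigned
  )
}

#' Cap identical-coordinate alignment copies within a gene bin
#'
#' Groups a gene bin's alignments by (aligned length, start, end) and keeps at
#' most `max_copies` reads per group (the first by read-id sort), so PCR- or
#' primer-driven pileups cannot overwhelm assembly. Reads without their own
#' coordinates on the binned gene (mates carried by their partner) are kept
#' unconditionally.
#'
#' @param bin Alignment tibble for one gene from [align_to_genes()].
#' @param max_copies Maximum reads retained per identical-coordinate group.
#' @return The reduced alignment tibble.
#' @export
reduce_bin <- function(bin, max_copies = 5L) {
  if (nrow(bin) == 0) {
    return(bin)
  }
  stopifnot(length(unique(bin$gene)) == 1)
  nocoord <- bin[is.na(bin$start), , drop = FALSE]
  coord <- bin[!is.na(bin$start), , drop = FALSE]
  kept <- dplyr::slice_head(
    dplyr::arrange(
      dplyr::group_by(coord, .data$aligned_len, .data$start, .data$end),
      .data$read_id, .data$mate
    ),
    n = max_copies
  )
  dplyr::bind_rows(dplyr::ungroup(kept), nocoord)
}
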