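# Event confirmation: chimeric junction constructs are built from the genome
# (150 bases bidirectional beyond the breakpoint by default), consensus reads
# that do not perfectly match any known transcript are realigned to the
# constructs, and reads spanning the junction by at least `min_span` bases on
# both sides at high identity count as support. Confirmed calls are emitted
# as paired VCF breakend (BND) records plus an IGV review session.

#' Remove reads that perfectly match a known transcript
#'
#' A read is removed iff it matches some transcript (or its reverse
#' complement) end-to-end with zero mismatches; such reads represent normal
#' transcription and cannot support a junction.
#'
#' @param reads Reads tibble.
#' @param transcript_seqs Named character vector of transcript sequences.
#' @return The retained reads tibble.
#' @export
remove_known_transcript_reads <- function(reads, transcript_seqs) {
  if (nrow(reads) == 0 || length(transcript_seqs) == 0) {
    return(reads)
  }
  hay <- paste(c(transcript_seqs, revcomp(transcript_seqs)), collapse = "#")
  hit <- stringr::str_detect(hay, stringr::fixed(reads$seq))
  reads[!hit, , drop = FALSE]
}

#' Build a chimeric junction construct for a candidate
#'
#' Takes up to `flank` genomic bases ending at the 5' breakpoint and up to
#' `flank` bases starting at the 3' breakpoint (strand-aware), truncating at
#' chromosome ends. Constructs with fewer than 20 bases on either side are
#' rejected.
#'
#' @param candidate One-row candidate tibble with chrom5/pos5/strand5 and
#'   chrom3/pos3/strand3.
#' @param genome Named character vector of chromosome sequences.
#' @param flank Flank length per side (bases).
#' @return A list: construct_id, seq, junction_index (0-based index of the
#'   first 3'-side base == flank5_length), flank5_length, flank3_length; or
#'   NULL when either flank is shorter than 20 bases (the candidate is
#'   rejected with flag "SHORT_CONSTRUCT" downstream).
#' @export
build_construct <- function(candidate, genome, flank = 150L) {
  g5 <- genome[[candidate$chrom5]]
  g3 <- genome[[candidate$chrom3]]
  if (is.null(g5) || is.null(g3)) {
    stop("candidate breakpoint on unknown chromosome", call. = FALSE)
  }
  p5 <- candidate$pos5
  p3 <- candidate$pos3
  if (candidate$strand5 == "+") {
    f5 <- substring(g5, max(1L, p5 - flank + 1L), p5)
  } else {
    f5 <- revcomp(substring(g5, p5, min(nchar(g5), p5 + flank - 1L)))
  }
  if (candidate$strand3 == "+") {
    f3 <- substring(g3, p3, min(nchar(g3), p3 + flank - 1L))
  } else {
    f3 <- revcomp(substring(g3, max(1L, p3 - flank + 1L), p3))
  }
  if (nchar(f5) < 20L || nchar(f3) < 20L) {
    return(NULL) # too little flank to recruit spanning reads
  }
  cid <- if ("call_id" %in% names(candidate)) {
    candidate$call_id
  } else {
    sprintf(
      "%s_%d_%s_%d", candidate$chrom5, p5, candidate$chrom3, p3
    )
  }
  list(
    construct_id = cid,
    seq = paste0(f5, f3),
    junction_index = nchar(f5),
    flank5_length = nchar(f5),
    flank3_length = nchar(f3)
  )
}

#' Count junction-spanning support for a construct
#'
#' Aligns reads to the construct with the internal engine; a read supports
#' the junction iff its alignment covers at least `min_span` bases on each
#' side of the junction with identity >= `min_identity`. Reads are counted as
#' distinct read ids, so a consensus pair (R1+R2 sharing an id) contributes
#' one molecule of support.
#'
#' @param reads Retained reads tibble.
#' @param construct A construct from [build_construct()].
#' @param min_span Minimum bases required beyond the breakpoint on each side.
#' @param min_identity Minimum alignment identity.
#' @param k Seed length for the construct alignment.
#' @return A list: `count` (distinct supporting read ids) and `alignments`
#'   (tibble of the supporting read alignments on the construct).
#' @export
count_support <- function(reads, construct, min_span = 10L,
                          min_identity = 0.9, k = 13L) {
  if (nrow(reads) == 0) {
    return(list(count = 0L, alignments = tibble()))
  }
  idx <- kmer_index(setNames(construct$seq, construct$construct_id), k = k)
  key <- paste(reads$read_id, reads$mate)
  aln <- align_best(key, reads$seq, idx, min_score = 20)
  if (nrow(aln) == 0) {
    return(list(count = 0L, alignments = tibble()))
  }
  J <- construct$junction_index # 1-based position of the last 5' base
  ok <- aln$tstart <= J - min_span + 1L &
    aln$tend >= J + min_span &
    aln$identity >= min_identity
  aln <- aln[ok, , drop = FALSE]
  if (nrow(aln) == 0) {
    return(list(count = 0L, alignments = tibble()))
  }
  km <- match(aln$read_id, key)
  aln$pair_id <- reads$read_id[km]
  aln$mate <- reads$mate[km]
  aln$seq <- ifelse(aln$strand == "+", reads$seq[km], revcomp(reads$seq[km]))
  aln$construct_id <- construct$construct_id
  list(count = length(unique(aln$pair_id)), alignments = aln)
}

#' Confirm candidates by construct realignment
#'
#' Builds a construct per kept candidate (single-transcript candidates must
#' already carry allowlist approval), counts junction-spanning consensus
#' reads, and keeps calls with at least `min_support` distinct supporting
#' molecules.
#'
#' @param candidates Annotated, filtered candidate tibble (`keep == TRUE`
#'   rows are used).
#' @param reads Consensus reads retained by
#'   [remove_known_transcript_reads()].
#' @param genome Named character vector of chromosome sequences.
#' @param flank,min_span,min_identity See [build_construct()] and
#'   [count_support()].
#' @param min_support Minimum distinct supporting molecules (default 1).
#' @return A list: `calls` (confirmed call tibble with supporting_reads,
#'   supporting_read_ids, construct_id, construct_seq, junction_index),
#'   `support_alignments`, and `rejected` (candidates that failed
#'   confirmation, with a reason).
#' @export
confirm_fusions <- function(candidates, reads, genome, flank = 150L,
                            min_span = 10L, min_identity = 0.9,
                            min_support = 1L) {
  cand <- if ("keep" %in% names(candidates)) {
    candidates[candidates$keep, , drop = FALSE]
  } else {
    candidates
  }
  calls <- list()
  support <- list()
  rejected <- list()
  if (nrow(cand) > 0) {
    cand$call_id <- sprintf("FUS%03d", seq_len(nrow(cand)))
  }
  # build all constructs, then realign the read set once against all of them
  ctrs <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ctrs[[i]] <- build_construct(cand[i, ], genome, flank = flank)
  }
  built <- !vapply(ctrs, is.null, TRUE)
  batch <- NULL
  if (any(built) && nrow(reads) > 0) {
    seqs <- vapply(ctrs[built], `[[`, "", "seq")
    names(seqs) <- vapply(ctrs[built], `[[`, "", "construct_id")
    idx <- kmer_index(seqs, k = 13L)
    key <- paste(reads$read_id, reads$mate)
    aln <- align_best(key, reads$seq, idx, min_score = 20)
    if (nrow(aln) > 0) {
      km <- match(aln$read_id, key)
      aln$pair_id <- reads$read_id[km]
      aln$mate <- reads$mate[km]
      aln$seq <- ifelse(aln$strand == "+", reads$seq[km], revcomp(reads$seq[km]))
      aln$construct_id <- aln$target
    }
    batch <- aln
  }
  for (i in seq_len(nrow(cand))) {
    cc <- cand[i, ]
    ctr <- ctrs[[i]]
    if (is.null(ctr)) {
      cc$reject_reason <- "SHORT_CONSTRUCT"
      rejected[[length(rejected) + 1L]] <- cc
      next
    }
    sup <- list(count = 0L, alignments = tibble())
    if (!is.null(batch) && nrow(batch) > 0) {
      J <- ctr$junction_index
      ok <- batch$construct_id == ctr$construct_id &
        batch$tstart <= J - min_span + 1L &
        batch$tend >= J + min_span &
        batch$identity >= min_identity
      ba <- batch[ok, , drop = FALSE]
      sup <- list(count = length(unique(ba$pair_id)), alignments = ba)
    }
    if (sup$count < min_support) {
      cc$reject_reason <- sprintf("SUPPORT_%d_LT_%d", sup$count, min_support)
      rejected[[length(rejected) + 1L]] <- cc
      next
    }
    cc$supporting_reads <- sup$count
    cc$supporting_read_ids <- list(sort(unique(sup$alignments$pair_id)))
    cc$construct_id <- ctr$construct_id
    cc$construct_seq <- ctr$seq
    cc$junction_index <- ctr$junction_index
    calls[[length(calls) + 1L]] <- cc
    support[[length(support) + 1L]] <- sup$alignments
  }
  list(
    calls = dplyr::bind_rows(calls),
    support_alignments = dplyr::bind_rows(support),
    rejected = dplyr::bind_rows(rejected)
  )
}

bnd_alt <- function(ref, o_self, mate_chrom, mate_pos, o_mate, side) {
  m <- sprintf("%s:%d", mate_chrom, mate_pos)
  if (side == "5") {
    if (o_self == "+") {
      if (o_mate == "+") paste0(ref, "[", m, "[") else paste0(ref, "]", m, "]")
    } else {
      if (o_mate == "+") paste0("[", m, "[", ref) else paste0("]", m, "]", ref)
    }
  } else {
    if (o_self == "+") {
      if (o_mate == "+") paste0("]", m, "]", ref) else paste0("[", m, "[", ref)
    } else {
      if (o_mate == "+") paste0(ref, "]", m, "]") else paste0(ref, "[", m, "[")
    }
  }
}

#' Write confirmed calls as a VCF of paired breakends
#'
#' Each call becomes two BND records with mutual MATEID references and INFO
#' keys GENE5, GENE3, EXON5, EXON3, FRAME, SR, CONTIG, MRR5 and MRR3.
#' Records are sorted by (contig order, position).
#'
#' @param calls Confirmed call tibble from [confirm_fusions()].
#' @param genome Named character vector of chromosome sequences (declares the
#'   contig header lines and supplies REF bases).
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_fusion_vcf <- function(calls, genome, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=fusionforge",
    sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##INFO=<ID=GENE5,Number=1,Type=String,Description=\"5' partner gene\">",
    "##INFO=<ID=GENE3,Number=1,Type=String,Description=\"3' partner gene\">",
    "##INFO=<ID=EXON5,Number=1,Type=String,Description=\"5' exon annotation label\">",
    "##INFO=<ID=EXON3,Number=1,Type=String,Description=\"3' exon annotation label\">",
    "##INFO=<ID=FRAME,Number=1,Type=String,Description=\"Reading frame status\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Distinct supporting consensus reads\">",
    "##INFO=<ID=CONTIG,Number=1,Type=String,Description=\"Assembled contig id\">",
    "##INFO=<ID=MRR5,Number=1,Type=Float,Description=\"Mononucleotide repeat ratio, 5' junction flank\">",
    "##INFO=<ID=MRR3,Number=1,Type=Float,Description=\"Mononucleotide repeat ratio, 3' junction flank\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    cc <- calls[i, ]
    ref5 <- substring(genome[[cc$chrom5]], cc$pos5, cc$pos5)
    ref3 <- substring(genome[[cc$chrom3]], cc$pos3, cc$pos3)
    id5 <- paste0(cc$call_id, "_1")
    id3 <- paste0(cc$call_id, "_2")
    v_or_na <- function(x) {
      if (is.null(x) || is.na(x)) "NA" else as.character(x)
    }
    info_common <- sprintf(
      "GENE5=%s;GENE3=%s;EXON5=%s;EXON3=%s;FRAME=%s;SR=%d;CONTIG=%s;MRR5=%s;MRR3=%s",
      v_or_na(cc$gene5), v_or_na(cc$gene3),
      v_or_na(cc$exon5_label), v_or_na(cc$exon3_label),
      v_or_na(cc$frame), cc$supporting_reads, v_or_na(cc$contig_id),
      v_or_na(if (is.null(cc$mrr5)) NULL else format(cc$mrr5, digits = 4)),
      v_or_na(if (is.null(cc$mrr3)) NULL else format(cc$mrr3, digits = 4))
    )
    rows[[length(rows) + 1L]] <- tibble(
      chrom = cc$chrom5, pos = cc$pos5, id = id5, ref = ref5,
      alt = bnd_alt(ref5, cc$strand5, cc$chrom3, cc$pos3, cc$strand3, "5"),
      info = sprintf("SVTYPE=BND;MATEID=%s;%s", id3, info_common)
    )
    rows[[length(rows) + 1L]] <- tibble(
      chrom = cc$chrom3, pos = cc$pos3, id = id3, ref = ref3,
      alt = bnd_alt(ref3, cc$strand3, cc$chrom5, cc$pos5, cc$strand5, "3"),
      info = sprintf("SVTYPE=BND;MATEID=%s;%s", id5, info_common)
    )
  }
  body <- character(0)
  if (length(rows) > 0) {
    rec <- dplyr::bind_rows(rows)
    rec <- rec[order(match(rec$chrom, names(genome)), rec$pos), , drop = FALSE]
    body <- sprintf(
      "%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
      rec$chrom, rec$pos, rec$id, rec$ref, rec$alt, rec$info
    )
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a fusionforge VCF back into a calls tibble
#'
#' @param path VCF path written by [write_fusion_vcf()].
#' @return Tibble with one row per call: call_id, chrom5, pos5, chrom3, pos3,
#'   gene5, gene3, exon5_label, exon3_label, frame, supporting_reads,
#'   contig_id, mrr5, mrr3.
#' @export
read_fusion_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(
      call_id = character(0), chrom5 = character(0), pos5 = integer(0),
      chrom3 = character(0), pos3 = integer(0), gene5 = character(0),
      gene3 = character(0), exon5_label = character(0),
      exon3_label = character(0), frame = character(0),
      supporting_reads = integer(0), contig_id = character(0),
      mrr5 = numeric(0), mrr3 = numeric(0)
    ))
  }
  info_get <- function(key) vcfR::extract.info(v, element = key)
  primary <- grepl("_1$", fix$ID)
  mate_id <- info_get("MATEID")[primary]
  mate_ix <- match(mate_id, fix$ID)
  tibble(
    call_id = sub("_1$", "", fix$ID[primary]),
    chrom5 = fix$CHROM[primary],
    pos5 = as.integer(fix$POS[primary]),
    chrom3 = fix$CHROM[mate_ix],
    pos3 = as.integer(fix$POS[mate_ix]),
    gene5 = info_get("GENE5")[primary],
    gene3 = info_get("GENE3")[primary],
    exon5_label = info_get("EXON5")[primary],
    exon3_label = info_get("EXON3")[primary],
    frame = info_get("FRAME")[primary],
    supporting_reads = as.integer(info_get("SR")[primary]),
    contig_id = info_get("CONTIG")[primary],
    mrr5 = suppressWarnings(as.numeric(info_get("MRR5")[primary])),
    mrr3 = suppressWarnings(as.numeric(info_get("MRR3")[primary]))
  )
}

#' Write an IGV review session for confirmed calls
#'
#' Writes the construct FASTA (+ .fai), a coordinate-sorted indexed BAM of
#' the supporting-read alignments against the constructs, and an IGV session
#' XML referencing both with relative paths. With no calls, nothing is
#' written.
#'
#' @param calls Confirmed call tibble.
#' @param support_alignments Supporting alignments from [confirm_fusions()].
#' @param dir Output directory.
#' @return Invisibly, the paths written (empty character vector when there
#'   are no calls).
#' @export
igv_session <- function(calls, support_alignments, dir) {
  if (nrow(calls) == 0) {
    return(invisible(character(0)))
  }
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("writing the IGV session requires the Rsamtools package", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "constructs.fa")
  write_fasta(setNames(calls$construct_seq, calls$construct_id), fa)
  Rsamtools::indexFa(fa)
  sam <- file.path(dir, "support.sam")
  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", calls$construct_id, nchar(calls$construct_seq))
  )
  al <- support_alignments
  recs <- character(0)
  if (nrow(al) > 0) {
    lq <- nchar(al$seq)
    cig <- sprintf(
      "%s%dM%s",
      ifelse(al$qstart > 1, sprintf("%dS", al$qstart - 1L), ""),
      al$qend - al$qstart + 1L,
      ifelse(al$qend < lq, sprintf("%dS", lq - al$qend), "")
    )
    recs <- sprintf(
      "%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
      paste0(al$pair_id, "/", al$mate),
      ifelse(al$strand == "-", 16L, 0L),
      al$construct_id, al$tstart, cig, al$seq
    )
  }
  writeLines(c(hdr, recs), sam)
  bam0 <- Rsamtools::asBam(sam, file.path(dir, "support_unsorted"),
    overwrite = TRUE, indexDestination = FALSE
  )
  Rsamtools::sortBam(bam0, file.path(dir, "support"))
  Rsamtools::indexBam(file.path(dir, "support.bam"))
  unlink(c(sam, bam0))
  xml <- xml2::xml_new_root("Session",
    genome = "constructs.fa", version = "8"
  )
  res <- xml2::xml_add_child(xml, "Resources")
  xml2::xml_add_child(res, "Resource", path = "support.bam")
  panel <- xml2::xml_add_child(xml, "Panel", name = "DataPanel")
  xml2::xml_add_child(panel, "Track", id = "support.bam", name = "Supporting reads")
  session <- file.path(dir, "igv_session.xml")
  xml2::write_xml(xml, session)
  invisible(c(fa, file.path(dir, "support.bam"), session))
}
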