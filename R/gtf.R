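# GTF interchange for transcript models. Internally models are an exon-level
# tibble (gene, transcript_id, chrom, strand, exon, start, end, cds_start,
# cds_end, canonical); on disk they are exon + CDS features with gene_name
# and transcript_id attributes.

#' Write transcript models as GTF
#'
#' @param transcripts Exon-level transcript tibble.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_transcript_gtf <- function(transcripts, path) {
  tx <- transcripts[order(
    transcripts$chrom, transcripts$transcript_id, transcripts$exon
  ), , drop = FALSE]
  attr_str <- sprintf(
    "gene_name \"%s\"; transcript_id \"%s\"; exon_number \"%d\";",
    tx$gene, tx$transcript_id, tx$exon
  )
  exon_lines <- sprintf(
    "%s\tfusionforge\texon\t%d\t%d\t.\t%s\t.\t%s",
    tx$chrom, tx$start, tx$end, tx$strand, attr_str
  )
  cds <- tx[!is.na(tx$cds_start), , drop = FALSE]
  cds_lines <- character(0)
  if (nrow(cds) > 0) {
    s <- pmax(cds$start, cds$cds_start)
    e <- pmin(cds$end, cds$cds_end)
    keep <- s <= e
    cds_lines <- sprintf(
      "%s\tfusionforge\tCDS\t%d\t%d\t.\t%s\t.\t%s",
      cds$chrom[keep], s[keep], e[keep], cds$strand[keep],
      sprintf(
        "gene_name \"%s\"; transcript_id \"%s\"; exon_number \"%d\";",
        cds$gene[keep], cds$transcript_id[keep], cds$exon[keep]
      )
    )
  }
  writeLines(c(exon_lines, cds_lines), path)
  invisible(path)
}

#' Read transcript models from GTF
#'
#' Uses exon and CDS features with `gene_name` (or `gene_id`) and
#' `transcript_id` attributes; the CDS span per transcript becomes
#' cds_start/cds_end.
#'
#' @param path GTF path.
#' @return Exon-level transcript tibble.
#' @export
read_transcript_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GTF requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  gene_col <- if ("gene_name" %in% names(df)) "gene_name" else "gene_id"
  ex <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  cds_span <- if (nrow(cds) > 0) {
    dplyr::summarise(
      dplyr::group_by(as_tibble(cds), .data$transcript_id),
      cds_start = min(.data$start), cds_end = max(.data$end),
      .groups = "drop"
    )
  } else {
    tibble(transcript_id = character(0), cds_start = integer(0), cds_end = integer(0))
  }
  out <- tibble(
    gene = as.character(ex[[gene_col]]),
    transcript_id = as.character(ex$transcript_id),
    chrom = as.character(ex$seqnames),
    strand = as.character(ex$strand),
    start = ex$start, end = ex$end
  )
  out <- dplyr::left_join(out, cds_span, by = "transcript_id")
  # exon numbering in transcription order: genomic order for +, reversed for -
  out <- dplyr::arrange(out, .data$transcript_id, .data$start)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$transcript_id),
    exon = if (.data$strand[1] == "+") {
      dplyr::row_number()
    } else {
      dplyr::n() - dplyr::row_number() + 1L
    }
  )
  out <- dplyr::ungroup(out)
  out$canonical <- TRUE
  dplyr::arrange(out, .data$chrom, .data$transcript_id, .data$exon)
}
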