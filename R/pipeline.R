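# End-to-end orchestration: dedupe -> trim -> gene binning -> per-gene
# {reduce, assemble} -> split alignment -> candidate filters -> annotation ->
# construct confirmation -> VCF / IGV / reports. The per-gene stage is the
# parallelism unit; results are merged in sorted gene order so output is
# identical for any thread count.

#' Pipeline configuration with the package defaults
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `fusion_pipeline_config`.
#' @export
fusion_config <- function(...) {
  cfg <- list(
    umi_length = 12L, umi_read = "R1", umi_offset = 0L, max_hamming = 1L,
    qual_cap = 60L, split_by_prefix = 0L,
    trim_min_overlap = 4L, trim_max_mismatch_rate = 0.2, trim_min_length = 30L,
    bin_k = 17L, bin_min_score = 20, max_copies = 5L,
    asm_min_overlap = 30L, asm_min_identity = 0.9,
    genome_k = 17L, min_segment = 25L, seg_min_identity = 0.9,
    min_genomic_gap = 10000L, merge_window = 5L,
    mrr_window = 20L, mrr_threshold = 0.6,
    blocklist = NULL, allowlist = NULL,
    boundary_tolerance = 3L,
    flank = 150L, min_span = 10L, support_min_identity = 0.9,
    min_support = 1L,
    threads = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config option(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "fusion_pipeline_config")
}

#' Run the full fusion detection pipeline
#'
#' @param reads A reads tibble, or a length-2 character vector of R1/R2 FASTQ
#'   paths.
#' @param genome Named character vector of chromosome sequences (or a FASTA
#'   path).
#' @param transcripts Exon-level transcript tibble (or a GTF path).
#' @param adapters Optional [adapter_set()] (or adapter FASTA path); when
#'   given, consensus reads are adapter-trimmed before binning.
#' @param config A [fusion_config()].
#' @param out_dir Optional output directory; when given, writes calls.vcf,
#'   candidates.tsv, rejected.tsv, contigs.fa, manifest.json and (with
#'   Rsamtools available and calls present) an IGV session.
#' @param threads Per-gene worker count (forked; results are merged in sorted
#'   gene order, so the output is thread-count-invariant).
#' @return An object of class `fusion_result`: calls, candidates, contigs,
#'   dedup stats and a stage-count manifest.
#' @export
run_fusion_pipeline <- function(reads, genome, transcripts, adapters = NULL,
                                config = fusion_config(), out_dir = NULL,
                                threads = config$threads) {
  if (is.character(reads)) {
    stopifnot(length(reads) == 2)
    reads <- read_fastq_pair(reads[1], reads[2])
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (is.character(transcripts)) transcripts <- read_transcript_gtf(transcripts)
  if (is.character(adapters)) adapters <- read_adapters(adapters)
  manifest <- list(parameters = unclass(config))
  if (nrow(reads) == 0) {
    warning("empty input FASTQ; producing empty outputs")
  }
  manifest$input_reads <- nrow(reads)

  # 1. UMI consensus
  dd <- dedupe_reads(reads,
    umi_length = config$umi_length, umi_read = config$umi_read,
    umi_offset = config$umi_offset, max_hamming = config$max_hamming,
    qual_cap = config$qual_cap, split_by_prefix = config$split_by_prefix
  )
  cons <- dd$reads
  manifest$dedup <- dd$stats

  # 2. adapter trimming
  if (!is.null(adapters)) {
    cons <- trim_reads(cons, adapters, min_length = config$trim_min_length)
  }
  manifest$consensus_reads_after_trim <- nrow(cons)

  # 3. gene binning
  gene_ref <- build_gene_reference(transcripts, genome)
  binned <- align_to_genes(cons, gene_ref,
    k = config$bin_k,
    min_score = config$bin_min_score
  )
  manifest$binned_reads <- nrow(binned$alignments)
  manifest$unassigned_reads <- nrow(binned$unassigned)

  # 4. per-gene reduce + assemble (parallel unit), merged in sorted order
  genes <- if (nrow(binned$alignments) > 0) {
    sort(unique(binned$alignments$gene))
  } else {
    character(0)
  }
  assemble_one <- function(g) {
    bin <- binned$alignments[binned$alignments$gene == g, , drop = FALSE]
    red <- reduce_bin(bin, max_copies = config$max_copies)
    ctg <- assemble_reads(
      red$oriented_seq,
      ids = paste(red$read_id, red$mate),
      min_overlap = config$asm_min_overlap,
      min_identity = config$asm_min_identity
    )
    ctg$gene <- if (nrow(ctg)) g else character(0)
    ctg$contig_id <- if (nrow(ctg)) paste0(g, "_", ctg$contig_id) else character(0)
    ctg
  }
  contigs <- if (length(genes) == 0) {
    tibble(
      contig_id = character(0), seq = character(0), length = integer(0),
      member_count = integer(0), members = list(), gene = character(0)
    )
  } else if (threads > 1 && requireNamespace("parallel", quietly = TRUE) &&
    .Platform$OS.type == "unix") {
    dplyr::bind_rows(parallel::mclapply(genes, assemble_one, mc.cores = threads))
  } else {
    dplyr::bind_rows(lapply(genes, assemble_one))
  }
  manifest$contigs <- nrow(contigs)

  # 5. split alignment and candidate calling
  gidx <- kmer_index(genome, k = config$genome_k)
  cand_list <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    segs <- suppressWarnings(split_align(
      contigs$seq[i], gidx,
      min_segment = config$min_segment,
      min_identity = config$seg_min_identity,
      contig_id = contigs$contig_id[i]
    ))
    cand_list[[i]] <- call_candidates(segs,
      min_genomic_gap = config$min_genomic_gap,
      contig_seq = contigs$seq[i], genome = genome
    )
  }
  candidates <- dplyr::bind_rows(cand_list)
  manifest$raw_candidates <- nrow(candidates)
  if (nrow(candidates) > 0) {
    ci <- match(candidates$contig_id, contigs$contig_id)
    candidates$contig_seq <- contigs$seq[ci]
    candidates$contig_length <- contigs$length[ci]
    candidates <- collapse_redundant(candidates,
      merge_window = config$merge_window
    )
  } else {
    candidates$contig_seq <- character(0)
    candidates$contig_length <- integer(0)
    candidates <- collapse_redundant(candidates)
  }
  manifest$collapsed_candidates <- nrow(candidates)

  # 6. annotation + filters
  candidates <- annotate_candidates(candidates, transcripts,
    tolerance = config$boundary_tolerance
  )
  candidates <- filter_candidates(candidates, filter_config(
    mrr_window = config$mrr_window, mrr_threshold = config$mrr_threshold,
    blocklist = config$blocklist, allowlist = config$allowlist
  ))
  manifest$kept_candidates <- sum(candidates$keep)

  # 7. confirmation on reads that are not perfect transcript matches
  retained <- remove_known_transcript_reads(cons, gene_ref)
  manifest$confirmation_reads <- nrow(retained)
  conf <- confirm_fusions(candidates, retained, genome,
    flank = config$flank, min_span = config$min_span,
    min_identity = config$support_min_identity,
    min_support = config$min_support
  )
  manifest$calls <- nrow(conf$calls)

  res <- structure(
    list(
      calls = conf$calls,
      support_alignments = conf$support_alignments,
      rejected = dplyr::bind_rows(
        conf$rejected,
        dplyr::mutate(candidates[!candidates$keep, , drop = FALSE],
          reject_reason = .data$flags
        )
      ),
      candidates = candidates,
      contigs = contigs,
      dedup_stats = dd$stats,
      manifest = manifest,
      genome = genome
    ),
    class = "fusion_result"
  )
  if (!is.null(out_dir)) {
    write_pipeline_outputs(res, out_dir)
  }
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fusion_vcf(res$calls, res$genome, file.path(out_dir, "calls.vcf"))
  drop_lists <- function(x) x[, !vapply(x, is.list, TRUE), drop = FALSE]
  utils::write.table(drop_lists(res$candidates),
    file.path(out_dir, "candidates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(drop_lists(res$rejected),
    file.path(out_dir, "rejected.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (nrow(res$contigs) > 0) {
    write_fasta(
      setNames(res$contigs$seq, res$contigs$contig_id),
      file.path(out_dir, "contigs.fa")
    )
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE
  )
  if (nrow(res$calls) > 0 && requireNamespace("Rsamtools", quietly = TRUE)) {
    igv_session(res$calls, res$support_alignments, out_dir)
  }
  invisible(out_dir)
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("<fusion_result>\n")
  cat(sprintf(
    "  %d input reads -> %d consensus pairs -> %d contigs -> %d candidates -> %d calls\n",
    x$manifest$input_reads, x$dedup_stats$clusters,
    x$manifest$contigs, x$manifest$collapsed_candidates, nrow(x$calls)
  ))
  if (nrow(x$calls) > 0) {
    cat("  calls:\n")
    for (i in seq_len(nrow(x$calls))) {
      cat(sprintf(
        "    %s-%s %s:%d ~ %s:%d SR=%d %s\n",
        x$calls$gene5[i], x$calls$gene3[i],
        x$calls$chrom5[i], x$calls$pos5[i],
        x$calls$chrom3[i], x$calls$pos3[i],
        x$calls$supporting_reads[i], x$calls$frame[i]
      ))
    }
  }
  invisible(x)
}
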