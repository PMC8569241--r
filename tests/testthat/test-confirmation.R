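test_that("perfect transcript matches are removed before confirmation", {
  tx <- c(T1 = rand_dna(400, seed = 101), T2 = rand_dna(400, seed = 102))
  perfect <- substring(tx[["T1"]], 51, 130)
  perfect_rc <- revcomp(substring(tx[["T2"]], 201, 280))
  one_off <- perfect
  substr(one_off, 40, 40) <- if (substring(one_off, 40, 40) == "A") "C" else "A"
  # verify by exhaustive scan that the mutated read matches no transcript
  all_subs <- unlist(lapply(c(tx, revcomp(tx)), function(s) {
    substring(s, 1:(nchar(s) - 79), 80:nchar(s))
  }))
  expect_false(one_off %in% all_subs)
  junction <- paste0(
    substring(tx[["T1"]], 361, 400), substring(tx[["T2"]], 1, 40)
  )
  reads <- tibble::tibble(
    read_id = c("a", "b", "c", "d"), mate = "R1",
    seq = c(perfect, perfect_rc, one_off, junction),
    qual = strrep("I", 80)
  )
  kept <- remove_known_transcript_reads(reads, tx)
  expect_setequal(kept$read_id, c("c", "d"))
})

deep_candidate <- function(genome, pos5 = 2000L, pos3 = 3000L) {
  tibble::tibble(
    contig_id = "c1", junction_offset = 80L,
    chrom5 = "chrA", pos5 = pos5, strand5 = "+",
    chrom3 = "chrB", pos3 = pos3, strand3 = "+",
    call_id = "FUS001"
  )
}

test_that("constructs carry 150 bases on each side of the junction", {
  set.seed(103)
  genome <- c(chrA = rand_dna(4000), chrB = rand_dna(4000))
  ctr <- build_construct(deep_candidate(genome), genome)
  expect_identical(nchar(ctr$seq), 300L)
  expect_identical(ctr$junction_index, 150L)
  expect_identical(
    ctr$seq,
    paste0(
      substring(genome[["chrA"]], 1851, 2000),
      substring(genome[["chrB"]], 3000, 3149)
    )
  )
})

test_that("constructs truncate at chromosome ends and reject short flanks", {
  set.seed(104)
  genome <- c(chrA = rand_dna(4000), chrB = rand_dna(3079))
  ctr <- build_construct(deep_candidate(genome), genome)
  expect_identical(nchar(ctr$seq), 230L) # 150 + 80 available on the 3' side
  expect_identical(ctr$junction_index, 150L)

  genome2 <- c(chrA = rand_dna(4000), chrB = rand_dna(3010))
  expect_null(build_construct(deep_candidate(genome2), genome2))
})

test_that("minus-strand flanks are reverse-complemented into the construct", {
  set.seed(105)
  genome <- c(chrA = rand_dna(4000), chrB = rand_dna(4000))
  cand <- deep_candidate(genome)
  cand$strand5 <- "-"
  cand$strand3 <- "-"
  ctr <- build_construct(cand, genome)
  expect_identical(
    ctr$seq,
    paste0(
      revcomp(substring(genome[["chrA"]], 2000, 2149)),
      revcomp(substring(genome[["chrB"]], 2851, 3000))
    )
  )
})

test_that("support requires the paper's spanning rule on both sides", {
  set.seed(106)
  genome <- c(chrA = rand_dna(4000), chrB = rand_dna(4000))
  ctr <- build_construct(deep_candidate(genome), genome)
  J <- ctr$junction_index
  # reads with every 3' overhang 1..20 (60 bases on the 5' side)
  reads <- tibble::tibble(
    read_id = sprintf("ov%02d", 1:20), mate = "R1",
    seq = substring(ctr$seq, J - 59, J + 1:20),
    qual = vapply(60 + 1:20, function(n) strrep("I", n), "")
  )
  sup <- count_support(reads, ctr, min_span = 10)
  supported <- as.integer(sub("ov", "", unique(sup$alignments$pair_id)))
  expect_identical(min(supported), 10L)
  expect_setequal(supported, 10:20)

  # a read entirely within the 5' flank is never support
  inside <- tibble::tibble(
    read_id = "in5", mate = "R1",
    seq = substring(ctr$seq, 11, 100), qual = strrep("I", 90)
  )
  expect_identical(count_support(inside, ctr)$count, 0L)
})

test_that("support counts distinct molecules, not mates", {
  set.seed(107)
  genome <- c(chrA = rand_dna(4000), chrB = rand_dna(4000))
  ctr <- build_construct(deep_candidate(genome), genome)
  J <- ctr$junction_index
  reads <- tibble::tibble(
    read_id = c("m1", "m1"), mate = c("R1", "R2"),
    seq = c(
      substring(ctr$seq, J - 50, J + 30),
      revcomp(substring(ctr$seq, J - 30, J + 50))
    ),
    qual = strrep("I", 81)
  )
  sup <- count_support(reads, ctr)
  expect_identical(sup$count, 1L)
  expect_identical(nrow(sup$alignments), 2L)
})

confirmed_run <- function() {
  s <- small_sim(n_genes = 4, n_fusions = 2, sim_seed = 37, n_molecules = 12)
  res <- run_fusion_pipeline(s$sim$reads, s$panel$genome, s$panel$transcripts)
  list(s = s, res = res)
}

test_that("support thresholds act monotonically on emitted calls", {
  cr <- confirmed_run()
  s <- cr$s
  base <- cr$res$calls
  expect_gte(nrow(base), 1)
  high <- run_fusion_pipeline(
    s$sim$reads, s$panel$genome, s$panel$transcripts,
    config = fusion_config(min_support = max(base$supporting_reads) + 1L)
  )
  low_ids <- paste(tidy(cr$res)$chrom5, tidy(cr$res)$pos5)
  high_td <- tidy(high)
  expect_true(all(paste(high_td$chrom5, high_td$pos5) %in% low_ids))
  expect_lt(nrow(high_td), nrow(base))
})

test_that("VCF output pairs breakends and round-trips every call field", {
  cr <- confirmed_run()
  res <- cr$res
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_fusion_vcf(res$calls, res$genome, tmp)
  lines <- readLines(tmp)
  body <- lines[!startsWith(lines, "#")]
  expect_identical(length(body), 2L * nrow(res$calls))
  # MATEID cross-referencing
  ids <- sub("\t.*", "", sub("^([^\t]*\t){2}", "", body))
  info <- sub(".*\t", "", body)
  mate <- sub(".*MATEID=([^;]+);.*", "\\1", info)
  expect_setequal(mate, ids)
  expect_true(all(grepl("SVTYPE=BND", info)))

  back <- read_fusion_vcf(tmp)
  expect_identical(nrow(back), nrow(res$calls))
  back <- back[match(res$calls$call_id, back$call_id), ]
  expect_identical(back$chrom5, res$calls$chrom5)
  expect_identical(back$pos5, res$calls$pos5)
  expect_identical(back$chrom3, res$calls$chrom3)
  expect_identical(back$pos3, res$calls$pos3)
  expect_identical(back$gene5, res$calls$gene5)
  expect_identical(back$gene3, res$calls$gene3)
  expect_identical(back$exon5_label, res$calls$exon5_label)
  expect_identical(back$exon3_label, res$calls$exon3_label)
  expect_identical(back$frame, res$calls$frame)
  expect_identical(back$supporting_reads, res$calls$supporting_reads)
  expect_equal(back$mrr5, res$calls$mrr5, tolerance = 1e-3)
})

test_that("an empty call set writes a valid header-only VCF", {
  set.seed(108)
  genome <- c(chrA = rand_dna(500))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_fusion_vcf(tibble::tibble(), genome, tmp)
  lines <- readLines(tmp)
  expect_true(all(startsWith(lines, "#")))
  expect_match(lines[1], "fileformat=VCFv4.2")
  expect_identical(nrow(read_fusion_vcf(tmp)), 0L)
})

test_that("the IGV session writes an indexed BAM with one record per support alignment", {
  cr <- confirmed_run()
  res <- cr$res
  dir <- withr::local_tempdir()
  igv_session(res$calls, res$support_alignments, dir)
  expect_true(file.exists(file.path(dir, "constructs.fa")))
  expect_true(file.exists(file.path(dir, "constructs.fa.fai")))
  expect_true(file.exists(file.path(dir, "support.bam")))
  expect_true(file.exists(file.path(dir, "support.bam.bai")))
  bam <- Rsamtools::scanBam(file.path(dir, "support.bam"))[[1]]
  expect_identical(length(bam$qname), nrow(res$support_alignments))
  per_construct <- table(as.character(bam$rname))
  for (i in seq_len(nrow(res$calls))) {
    cid <- res$calls$construct_id[i]
    n_aln <- sum(res$support_alignments$construct_id == cid)
    expect_identical(unname(per_construct[cid]), n_aln)
  }
  xml <- xml2::read_xml(file.path(dir, "igv_session.xml"))
  expect_identical(xml2::xml_name(xml), "Session")
  expect_true(length(xml2::xml_find_all(xml, ".//Resources/Resource")) >= 1)
  expect_true(length(xml2::xml_find_all(xml, ".//Panel")) >= 1)

  # empty call set: nothing written, no error
  out <- igv_session(tibble::tibble(), tibble::tibble(), withr::local_tempdir())
  expect_length(out, 0)
})
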