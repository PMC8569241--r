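two_chrom_genome <- function(seed = 81) {
  set.seed(seed)
  c(
    chrA = rand_dna(3000),
    chrB = rand_dna(3000)
  )
}

test_that("a contig that is an exact substring yields one full segment", {
  g <- two_chrom_genome()
  idx <- kmer_index(g, k = 17)
  contig <- substring(g[["chrA"]], 1001, 1160)
  segs <- split_align(contig, idx, contig_id = "c1")
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$chrom, "chrA")
  expect_identical(segs$contig_start, 0L)
  expect_identical(segs$contig_end, 160L)
  expect_identical(segs$genome_start, 1000L)
  expect_identical(segs$genome_end, 1160L)
  expect_identical(segs$strand, "+")
})

test_that("a synthetic chimeric contig splits into its two source segments", {
  g <- two_chrom_genome()
  # preclude chance microhomology at the junction so the segment boundaries
  # are exact by construction
  substr(g[["chrA"]], 1080, 1082) <- chartr(
    "ACGT", "TGCA", substring(g[["chrB"]], 2000, 2002)
  )
  substr(g[["chrB"]], 1997, 1999) <- chartr(
    "ACGT", "TGCA", substring(g[["chrA"]], 1077, 1079)
  )
  idx <- kmer_index(g, k = 17)
  contig <- paste0(
    substring(g[["chrA"]], 1000, 1079),
    substring(g[["chrB"]], 2000, 2079)
  )
  segs <- split_align(contig, idx, contig_id = "c1")
  segs <- segs[order(segs$contig_start), ]
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$chrom, c("chrA", "chrB"))
  expect_identical(segs$contig_start, c(0L, 80L))
  expect_identical(segs$contig_end, c(80L, 160L))

  # strand symmetry: the reverse-complemented contig gives the same segments
  # with flipped strands
  segs_rc <- split_align(revcomp(contig), idx, contig_id = "c1")
  segs_rc <- segs_rc[order(segs_rc$contig_start), ]
  expect_identical(nrow(segs_rc), 2L)
  expect_setequal(segs_rc$strand, "-")
  expect_setequal(segs_rc$genome_start, segs$genome_start)
  expect_setequal(segs_rc$genome_end, segs$genome_end)
})

test_that("contigs shorter than the seed produce no segments", {
  g <- two_chrom_genome()
  idx <- kmer_index(g, k = 17)
  expect_warning(segs <- split_align("ACGTACGT", idx), "shorter than")
  expect_identical(nrow(segs), 0L)
})

seg_row <- function(contig_id, cs, ce, chrom, gs, ge, strand = "+") {
  tibble::tibble(
    contig_id = contig_id, contig_start = cs, contig_end = ce,
    chrom = chrom, genome_start = gs, genome_end = ge,
    strand = strand, identity = 1, score = ce - cs
  )
}

test_that("candidate calling applies the non-contiguity rules", {
  # single segment: nothing
  expect_identical(
    nrow(call_candidates(seg_row("c", 0L, 160L, "chrA", 1000L, 1160L))), 0L
  )
  # two chromosomes tiling the contig: one candidate
  segs <- dplyr::bind_rows(
    seg_row("c", 0L, 80L, "chrA", 1000L, 1080L),
    seg_row("c", 80L, 160L, "chrB", 2000L, 2080L)
  )
  cand <- call_candidates(segs)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$chrom5, "chrA")
  expect_identical(cand$pos5, 1080L)
  expect_identical(cand$pos3, 2001L)
  expect_identical(cand$junction_offset, 80L)

  # same chromosome, 500-base gap: intron scale, no candidate; brute-force
  # the rule: gap <= min_genomic_gap and same strand and same chromosome
  near <- dplyr::bind_rows(
    seg_row("c", 0L, 80L, "chrA", 1000L, 1080L),
    seg_row("c", 80L, 160L, "chrA", 1580L, 1660L)
  )
  gap <- 1580L - 1080L
  expect_true(gap <= 10000)
  expect_identical(nrow(call_candidates(near)), 0L)
  expect_identical(nrow(call_candidates(near, min_genomic_gap = 400L)), 1L)

  # a strand change is non-contiguous even nearby
  inv <- dplyr::bind_rows(
    seg_row("c", 0L, 80L, "chrA", 1000L, 1080L),
    seg_row("c", 80L, 160L, "chrA", 1580L, 1660L, strand = "-")
  )
  expect_identical(nrow(call_candidates(inv)), 1L)

  # segments that do not tile the contig (gap > 10) are not joined
  apart <- dplyr::bind_rows(
    seg_row("c", 0L, 60L, "chrA", 1000L, 1060L),
    seg_row("c", 100L, 160L, "chrB", 2000L, 2060L)
  )
  expect_identical(nrow(call_candidates(apart)), 0L)
})

test_that("microhomology overlap shifts the 3' breakpoint inward", {
  segs <- dplyr::bind_rows(
    seg_row("c", 0L, 83L, "chrA", 1000L, 1083L), # 3 bases past the junction
    seg_row("c", 80L, 160L, "chrB", 2000L, 2080L)
  )
  cand <- call_candidates(segs)
  expect_identical(cand$pos5, 1083L)
  expect_identical(cand$pos3, 2004L) # 2001 + 3-base overlap
})

test_that("redundant candidates collapse within the merge window", {
  base <- tibble::tibble(
    contig_id = c("long", "short", "far"),
    junction_offset = c(80L, 70L, 60L),
    chrom5 = "chrA", pos5 = c(1000L, 1003L, 1050L), strand5 = "+",
    chrom3 = "chrB", pos3 = c(2000L, 1998L, 2050L), strand3 = "+",
    contig_length = c(200L, 150L, 120L)
  )
  out <- collapse_redundant(base, merge_window = 5)
  expect_identical(nrow(out), 2L)
  merged <- out[out$contig_id == "long", ]
  expect_identical(merged$n_contigs, 2L)
  expect_setequal(merged$member_contigs[[1]], c("long", "short"))
  expect_true("far" %in% out$contig_id)

  # identical breakpoints always merge
  two <- base[c(1, 1), ]
  two$contig_id <- c("a", "b")
  expect_identical(nrow(collapse_redundant(two)), 1L)
})

test_that("simulated fusion breakpoints are recovered within 2 bases", {
  s <- small_sim(n_genes = 5, n_fusions = 2, sim_seed = 29, n_molecules = 20)
  res <- run_fusion_pipeline(
    s$sim$reads, s$panel$genome, s$panel$transcripts
  )
  m <- match_truth(res$calls, s$sim$truth, window = 10)
  expect_true(all(m$detected))
  for (i in seq_len(nrow(m))) {
    call <- res$calls[m$matched_call[i], ]
    expect_lte(abs(call$pos5 - m$pos5[i]), 2)
    # the 3' breakpoint absorbs any microhomology shift on both sides
    expect_lte(abs(call$pos3 - m$pos3[i]), 4)
  }
})

test_that("the junction sequence re-derived from the genome matches the contig", {
  s <- small_sim(n_genes = 4, n_fusions = 1, sim_seed = 31, n_molecules = 20)
  res <- run_fusion_pipeline(s$sim$reads, s$panel$genome, s$panel$transcripts)
  expect_gte(nrow(res$calls), 1)
  cc <- res$calls[1, ]
  g <- s$panel$genome
  win <- 20
  derived <- paste0(
    substring(g[[cc$chrom5]], cc$pos5 - win + 1, cc$pos5),
    substring(g[[cc$chrom3]], cc$pos3, cc$pos3 + win - 1)
  )
  contig_win <- substring(
    cc$contig_seq, cc$junction_offset - win + 1, cc$junction_offset + win
  )
  mism <- sum(utf8ToInt(derived) != utf8ToInt(contig_win))
  expect_lte(mism / nchar(derived), 0.1)
})
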