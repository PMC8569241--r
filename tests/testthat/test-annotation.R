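# uniform exon grid: n exons of width `w` every `gap` bases from `start`
grid_tx <- function(gene, tx, chrom, strand, n, start = 1001L, w = 90L,
                    gap = 200L, cds_start = NA, cds_end = NA) {
  starts <- start + (seq_len(n) - 1L) * gap
  tx_model(gene, tx, chrom, strand, starts, starts + w - 1L,
    cds_start = cds_start, cds_end = cds_end
  )
}

test_that("breakpoints at and near exon boundaries snap correctly", {
  m <- grid_tx("G1", "T1", "chr1", "+", 6, cds_start = 1031, cds_end = 2080)
  e5_end <- m$end[m$exon == 5]
  loc <- locate_breakpoint("chr1", e5_end, m)
  expect_identical(loc$boundary, "End")
  expect_identical(loc$exon, 5L)
  expect_identical(loc$location_class, "Exon-exon_boundary")

  # 2 bases inside the exon, tolerance 3: snapped to the boundary
  loc2 <- locate_breakpoint("chr1", e5_end - 2L, m, tolerance = 3)
  expect_identical(loc2$location_class, "Exon-exon_boundary")
  expect_identical(loc2$snapped_pos, e5_end)

  # mid-exon beyond tolerance
  loc3 <- locate_breakpoint("chr1", e5_end - 40L, m, tolerance = 3)
  expect_identical(loc3$location_class, "Mid-exon")

  # intronic
  loc4 <- locate_breakpoint("chr1", e5_end + 50L, m, tolerance = 3)
  expect_identical(loc4$location_class, "Intronic")

  # outside every locus
  loc5 <- locate_breakpoint("chr9", 100L, m)
  expect_identical(loc5$gene, NA_character_)
  expect_identical(loc5$location_class, "Intronic")
})

test_that("on the minus strand the genomic-left exon edge is the transcription end", {
  m <- grid_tx("G2", "T2", "chr2", "-", 4)
  # transcription order is reversed: the genomically last exon is E1
  e2_left <- m$start[m$exon == 2]
  loc <- locate_breakpoint("chr2", e2_left, m)
  expect_identical(loc$exon, 2L)
  expect_identical(loc$boundary, "End")
})

test_that("frame status follows the CDS phase arithmetic", {
  # 5' gene: CDS starts 30 bases into exon 1 of 90-base exons: through exon k
  # the retained CDS is 60 + (k-1)*90, which is divisible by 3 for every k
  m5 <- grid_tx("A", "TA", "chr1", "+", 6, cds_start = 1031, cds_end = 2090)
  m3 <- grid_tx("B", "TB", "chr2", "+", 6, cds_start = 1031, cds_end = 2090)
  expect_identical(frame_status(dplyr::bind_rows(m5, m3), "TA", 3, "TB", 2), "In-frame")

  # shift the 3' CDS start by one base: phase 2 at every later exon start
  m3b <- grid_tx("B", "TB", "chr2", "+", 6, cds_start = 1032, cds_end = 2090)
  expect_identical(
    frame_status(dplyr::bind_rows(m5, m3b), "TA", 3, "TB", 2), "Out-of-frame"
  )

  # non-coding 3' transcript: Indeterminate
  m3n <- grid_tx("B", "NR_1", "chr2", "+", 6)
  expect_identical(
    frame_status(dplyr::bind_rows(m5, m3n), "TA", 3, "NR_1", 2),
    "Indeterminate"
  )
  expect_identical(
    frame_status(dplyr::bind_rows(m5, m3), NA, NA, "TB", 2), "Indeterminate"
  )
})

test_that("a documented-style exon-boundary fusion annotates end to end", {
  # FGFR3-like 17-exon 5' model and TACC3-like 11+-exon 3' model, CDS phases
  # arranged so the junction preserves the 3' reading frame
  fgfr3 <- grid_tx("FGFR3", "NM_001163213", "chr4", "+", 17,
    cds_start = 1031, cds_end = 1001 + 16 * 200 + 80
  )
  tacc3 <- grid_tx("TACC3", "NM_006342", "chr4b", "+", 14,
    cds_start = 1031, cds_end = 1001 + 13 * 200 + 80
  )
  models <- dplyr::bind_rows(fgfr3, tacc3)
  cand <- tibble::tibble(
    contig_id = "c1", junction_offset = 100L,
    chrom5 = "chr4", pos5 = fgfr3$end[fgfr3$exon == 17],
    strand5 = "+",
    chrom3 = "chr4b", pos3 = tacc3$start[tacc3$exon == 11],
    strand3 = "+"
  )
  ann <- annotate_candidates(cand, models)
  expect_identical(ann$exon5_label, "+|End_E17|FGFR3|NM_001163213")
  expect_identical(ann$exon3_label, "+|Start_E11|TACC3|NM_006342")
  expect_identical(ann$location_class, "Exon-exon_boundary")
  expect_identical(ann$frame, "In-frame")
})

test_that("side labels round-trip through parsing", {
  lab <- format_side_label("+", "End", 17L, "FGFR3", "NM_001163213")
  expect_identical(lab, "+|End_E17|FGFR3|NM_001163213")
  p <- parse_side_label(lab)
  expect_identical(
    format_side_label(p$strand, p$boundary, p$exon, p$gene, p$transcript_id),
    lab
  )
  p2 <- parse_side_label("-|Start_E5|FGFR1|NM_023110")
  expect_identical(p2$strand, "-")
  expect_identical(p2$exon, 5L)
})

test_that("frame status is invariant under genomic translation", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    off5 <- sample(c(30, 31, 32), 1)
    off3 <- sample(c(30, 31, 32), 1)
    m5 <- grid_tx("A", "TA", "c1", "+", n,
      cds_start = 1001 + off5, cds_end = 1001 + (n - 1) * 200 + 80
    )
    m3 <- grid_tx("B", "TB", "c2", "+", n,
      cds_start = 1001 + off3, cds_end = 1001 + (n - 1) * 200 + 80
    )
    e5 <- sample(2:(n - 1), 1)
    e3 <- sample(2:(n - 1), 1)
    f0 <- frame_status(dplyr::bind_rows(m5, m3), "TA", e5, "TB", e3)
    shift <- function(m, by) {
      dplyr::mutate(m,
        start = start + by, end = end + by,
        cds_start = cds_start + by, cds_end = cds_end + by
      )
    }
    f1 <- frame_status(
      dplyr::bind_rows(shift(m5, 5000L), shift(m3, 5000L)), "TA", e5, "TB", e3
    )
    expect_identical(f0, f1)
  }
})

test_that("fusions planted at phase-matched boundaries annotate In-frame", {
  set.seed(57)
  for (i in 1:8) {
    n <- 5
    m5 <- grid_tx("A", "TA", "c1", "+", n,
      cds_start = 1001 + 30, cds_end = 1001 + (n - 1) * 200 + 80
    )
    # choose a 3' acceptor phase equal to the 5' retained length mod 3 (zero
    # for the 90-base grid)
    m3 <- grid_tx("B", "TB", "c2", "+", n,
      cds_start = 1001 + 30, cds_end = 1001 + (n - 1) * 200 + 80
    )
    e5 <- sample(2:(n - 1), 1)
    e3 <- sample(2:(n - 1), 1)
    expect_identical(
      frame_status(dplyr::bind_rows(m5, m3), "TA", e5, "TB", e3), "In-frame"
    )
  }
})

test_that("annotation attaches gene context and exon skips to candidates", {
  m <- grid_tx("G1", "T1", "chr1", "+", 8, cds_start = 1031, cds_end = 2480)
  cand <- tibble::tibble(
    contig_id = "c1", junction_offset = 50L,
    chrom5 = "chr1", pos5 = m$end[m$exon == 2], strand5 = "+",
    chrom3 = "chr1", pos3 = m$start[m$exon == 7], strand3 = "+"
  )
  ann <- annotate_candidates(cand, m)
  expect_identical(ann$gene5, "G1")
  expect_identical(ann$gene3, "G1")
  expect_identical(ann$exon_skip, 4L)
})
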