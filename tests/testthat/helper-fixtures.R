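# Shared fixtures, built in code at test time.

tiny_panel <- function(n_genes = 4, seed = 42) {
  make_panel(n_genes, seed = seed)
}

# spliced transcript sequence computed independently of the package internals
splice_oracle <- function(panel, gene) {
  ex <- panel$transcripts[panel$transcripts$gene == gene, ]
  ex <- ex[order(ex$exon), ]
  pieces <- substring(panel$genome[[ex$chrom[1]]], ex$start, ex$end)
  if (ex$strand[1] == "-") {
    pieces <- rev(vapply(pieces, function(p) {
      intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", p))))
    }, "", USE.NAMES = FALSE))
  }
  paste(pieces, collapse = "")
}

# brute-force Bayesian posterior over the four bases (independent oracle)
bayes_oracle <- function(bases, quals, prior = rep(0.25, 4)) {
  nts <- c("A", "C", "G", "T")
  e <- 10^(-quals / 10)
  lik <- vapply(nts, function(b) {
    prod(ifelse(bases == b, 1 - e, e / 3))
  }, 0)
  post <- prior * lik
  post / sum(post)
}

# a hand-built exon tibble row set for one transcript
tx_model <- function(gene, transcript_id, chrom, strand, starts, ends,
                     cds_start = NA_integer_, cds_end = NA_integer_,
                     canonical = TRUE) {
  n <- length(starts)
  exon <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  tibble::tibble(
    gene = gene, transcript_id = transcript_id, chrom = chrom,
    strand = strand, exon = exon, start = starts, end = ends,
    cds_start = cds_start, cds_end = cds_end, canonical = canonical
  )
}

# random DNA string with a local RNG seed
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small positive simulation reused by several files
small_sim <- function(n_genes = 5, n_fusions = 2, n_molecules = 15,
                      panel_seed = 7, sim_seed = 11, error_rate = 0.01,
                      duplicate_rate = 3, n_background = 50) {
  panel <- make_panel(n_genes, seed = panel_seed)
  combos <- utils::combn(panel$genes, 2)
  truths <- dplyr::bind_rows(lapply(seq_len(n_fusions), function(i) {
    plant_fusion(panel, combos[1, i], combos[2, i], 2, 2,
      n_molecules = n_molecules
    )
  }))
  sim <- simulate_reads(panel, truths, sim_config(
    seed = sim_seed, error_rate = error_rate,
    duplicate_rate = duplicate_rate, n_background_molecules = n_background
  ))
  list(panel = panel, truths = truths, sim = sim)
}
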