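# Deterministic amplicon read simulator: synthetic gene panels, planted
# fusions, and UMI-tagged paired reads with PCR duplicates and substitution
# errors. The simulator is the package's source of truth-labelled data; all
# downstream stages are exercised against it.

# run code under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults describe the emulated chemistry: a 12-base UMI at the start of R1,
#' 100-base reads, 1% per-base substitution error, an average of 3 PCR copies
#' per molecule, and uniform background expression across the panel.
#'
#' @param seed Integer seed; fully determines the simulation output.
#' @param umi_length UMI length in bases (<= 16, the k-mer encoding limit).
#' @param umi_read Which mate carries the UMI ("R1" or "R2").
#' @param umi_offset 0-based offset of the UMI within that mate.
#' @param read_length Read length in bases (UMI included on the UMI mate).
#' @param error_rate Per-base substitution probability in [0, 0.25).
#' @param duplicate_rate Mean number of PCR copies per molecule (>= 1).
#' @param n_background_molecules Unfused molecules drawn uniformly from panel
#'   transcripts.
#' @param fragment_range Min/max amplicon fragment length in bases.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       umi_length = 12L,
                       umi_read = "R1",
                       umi_offset = 0L,
                       read_length = 100L,
                       error_rate = 0.01,
                       duplicate_rate = 3,
                       n_background_molecules = 300L,
                       fragment_range = c(150L, 260L)) {
  stopifnot(
    error_rate >= 0, error_rate < 0.25,
    umi_length >= 1L, umi_length <= 16L,
    umi_read %in% c("R1", "R2"),
    duplicate_rate >= 1,
    read_length > umi_length + 20L,
    length(fragment_range) == 2L, fragment_range[1] <= fragment_range[2]
  )
  structure(
    list(
      seed = as.integer(seed), umi_length = as.integer(umi_length),
      umi_read = umi_read, umi_offset = as.integer(umi_offset),
      read_length = as.integer(read_length), error_rate = error_rate,
      duplicate_rate = duplicate_rate,
      n_background_molecules = as.integer(n_background_molecules),
      fragment_range = as.integer(fragment_range)
    ),
    class = "sim_config"
  )
}

#' Generate a synthetic gene panel
#'
#' Builds a toy genome with one multi-exon, CDS-annotated transcript per gene,
#' each gene on its own synthetic chromosome on the plus strand. Exons are
#' 160-240 bases so a 150-base genomic flank at an exon boundary stays exonic,
#' and introns are 150-400 bases.
#'
#' @param n_genes Number of genes (>= 2, so an inter-gene fusion can be
#'   planted).
#' @param seed Integer seed; the panel is deterministic given the seed.
#' @param n_exons_range,exon_length_range,intron_length_range Integer ranges
#'   sampled per gene.
#' @param flank Bases of intergenic sequence on either side of each gene.
#' @return A list of class `fusion_panel` with elements `genome` (named
#'   character vector of chromosome sequences), `transcripts` (exon-level
#'   tibble: gene, transcript_id, chrom, strand, exon, start, end, cds_start,
#'   cds_end, canonical) and `genes`.
#' @export
#' @examples
#' panel <- make_panel(3, seed = 7)
#' panel$genes
make_panel <- function(n_genes, seed = 1L,
                       n_exons_range = c(4L, 6L),
                       exon_length_range = c(160L, 240L),
                       intron_length_range = c(150L, 400L),
                       flank = 400L) {
  if (n_genes < 2) {
    stop("a panel needs at least 2 genes to plant an inter-gene fusion",
      call. = FALSE
    )
  }
  with_seed(seed, {
    genome <- character(0)
    tx <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      gene <- sprintf("GENE%03d", i)
      chrom <- sprintf("chr%d", i)
      n_ex <- sample(n_exons_range[1]:n_exons_range[2], 1)
      ex_len <- sample(exon_length_range[1]:exon_length_range[2], n_ex,
        replace = TRUE
      )
      in_len <- sample(intron_length_range[1]:intron_length_range[2],
        max(n_ex - 1, 0),
        replace = TRUE
      )
      starts <- integer(n_ex)
      ends <- integer(n_ex)
      pos <- flank + 1L
      for (e in seq_len(n_ex)) {
        starts[e] <- pos
        ends[e] <- pos + ex_len[e] - 1L
        pos <- ends[e] + 1L + if (e < n_ex) in_len[e] else 0L
      }
      chrom_len <- ends[n_ex] + flank
      genome[chrom] <- random_dna(chrom_len)
      cds_start <- starts[1] + sample(10:60, 1)
      cds_end <- starts[n_ex] + sample(40:100, 1)
      tx[[i]] <- tibble(
        gene = gene,
        transcript_id = sprintf("TX%03d.1", i),
        chrom = chrom, strand = "+",
        exon = seq_len(n_ex),
        start = starts, end = ends,
        cds_start = cds_start, cds_end = cds_end,
        canonical = TRUE
      )
    }
    structure(
      list(
        genome = genome,
        transcripts = dplyr::bind_rows(tx),
        genes = sprintf("GENE%03d", seq_len(n_genes))
      ),
      class = "fusion_panel"
    )
  })
}

# spliced transcript sequence and exon offsets within the mature transcript
spliced_transcript <- function(panel, gene) {
  ex <- panel$transcripts[panel$transcripts$gene == gene, , drop = FALSE]
  if (nrow(ex) == 0) stop("unknown gene: ", gene, call. = FALSE)
  ex <- ex[order(ex$exon), , drop = FALSE]
  chrom_seq <- panel$genome[[ex$chrom[1]]]
  pieces <- substring(chrom_seq, ex$start, ex$end)
  if (ex$strand[1] == "-") {
    pieces <- revcomp(pieces) # exons are already in transcription order
  }
  seq <- paste(pieces, collapse = "")
  len <- ex$end - ex$start + 1L
  offs <- cumsum(c(0L, head(len[order(ex$exon)], -1)))
  list(seq = seq, exons = ex, exon_offset = offs, exon_len = len)
}

#' Plant a fusion event in a synthetic panel
#'
#' Joins the transcription-order end of `exon5` of `gene5` to the start of
#' `exon3` of `gene3`. With `gene5 == gene3` and `exon3 > exon5 + 1` this
#' produces an intragenic deletion event that skips interior exons
#' (EGFRvIII-class).
#'
#' @param panel A `fusion_panel`.
#' @param gene5,gene3 Gene names present in the panel.
#' @param exon5,exon3 1-based exon indices in transcription order.
#' @param fusion_id Optional identifier; defaults to "GENEA-GENEB".
#' @param n_molecules Number of distinct molecules to simulate for this event.
#' @return One-row truth tibble: fusion_id, gene5, gene3, chrom/pos/strand for
#'   both breakpoints (1-based), exon indices, n_molecules, junction_offset
#'   (bases of 5' sequence) and fusion_seq (the full chimeric transcript).
#' @export
plant_fusion <- function(panel, gene5, gene3, exon5, exon3,
                         fusion_id = NULL, n_molecules = 50L) {
  t5 <- spliced_transcript(panel, gene5)
  t3 <- spliced_transcript(panel, gene3)
  if (exon5 < 1 || exon5 > nrow(t5$exons)) {
    stop("exon5 index out of range for ", gene5, call. = FALSE)
  }
  if (exon3 < 1 || exon3 > nrow(t3$exons)) {
    stop("exon3 index out of range for ", gene3, call. = FALSE)
  }
  if (gene5 == gene3 && exon3 <= exon5 + 1) {
    stop("an intragenic event must skip at least one interior exon",
      call. = FALSE
    )
  }
  j5 <- t5$exon_offset[exon5] + t5$exon_len[exon5] # transcript bases retained
  seq5 <- substring(t5$seq, 1, j5)
  seq3 <- substring(t3$seq, t3$exon_offset[exon3] + 1L, nchar(t3$seq))
  e5 <- t5$exons[exon5, ]
  e3 <- t3$exons[exon3, ]
  # genomic breakpoints, strand-aware: transcription end of exon5, start of
  # exon3
  bp5 <- if (e5$strand == "+") e5$end else e5$start
  bp3 <- if (e3$strand == "+") e3$start else e3$end
  tibble(
    fusion_id = fusion_id %||% paste0(gene5, "-", gene3),
    gene5 = gene5, gene3 = gene3,
    chrom5 = e5$chrom, pos5 = bp5, strand5 = e5$strand,
    chrom3 = e3$chrom, pos3 = bp3, strand3 = e3$strand,
    exon5 = as.integer(exon5), exon3 = as.integer(exon3),
    n_molecules = as.integer(n_molecules),
    junction_offset = j5,
    fusion_seq = paste0(seq5, seq3)
  )
}

# substitution errors at `rate` per base; returns the mutated strings
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0) {
    return(seqs)
  }
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0) {
      return(s)
    }
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1), "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate UMI-tagged paired-end amplicon reads
#'
#' Every molecule receives a unique UMI; PCR copies share the UMI and differ
#' only by substitution errors. Fusion molecules are positioned so the R1
#' insert always spans the junction by at least 15 bases on both sides;
#' background molecules are drawn uniformly from unfused panel transcripts.
#'
#' @param panel A `fusion_panel`.
#' @param truths Truth tibble from [plant_fusion()] (zero rows for a
#'   fusion-negative sample).
#' @param config A [sim_config()].
#' @return A list of class `fusion_sim`: `reads` (tibble: read_id, mate, seq,
#'   qual), `truth` (the input truths plus planted molecule ids), and
#'   `molecules` (tibble: mol_id, source, umi, frag_start, frag_len).
#' @export
simulate_reads <- function(panel, truths, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    rl <- config$read_length
    ul <- config$umi_length
    ins_len <- rl - ul # R1 template bases after the UMI
    frng <- config$fragment_range

    # molecule plan: fusions first, then background
    mol <- list()
    if (nrow(truths) > 0) {
      for (i in seq_len(nrow(truths))) {
        tr <- truths[i, ]
        J <- tr$junction_offset
        L <- nchar(tr$fusion_seq)
        lo <- max(1L, J - ins_len + 16L)
        hi <- max(lo, min(J - 15L, L - frng[1] + 1L))
        n <- tr$n_molecules
        mol[[length(mol) + 1L]] <- tibble(
          source = tr$fusion_id,
          template = tr$fusion_seq,
          frag_start = sample(lo:hi, n, replace = TRUE)
        )
      }
    }
    if (config$n_background_molecules > 0) {
      tx_seq <- vapply(panel$genes, function(g) spliced_transcript(panel, g)$seq, "")
      g <- sample(panel$genes, config$n_background_molecules, replace = TRUE)
      mol[[length(mol) + 1L]] <- tibble(
        source = g,
        template = unname(tx_seq[g]),
        frag_start = vapply(tx_seq[g], function(s) {
          sample.int(max(1L, nchar(s) - frng[1] + 1L), 1)
        }, 1L)
      )
    }
    mol <- dplyr::bind_rows(mol)
    n_mol <- nrow(mol)
    if (n_mol == 0) {
      return(structure(
        list(
          reads = tibble(
            read_id = character(0), mate = character(0),
            seq = character(0), qual = character(0)
          ),
          truth = truths, molecules = tibble()
        ),
        class = "fusion_sim"
      ))
    }
    mol$mol_id <- sprintf("m%05d", seq_len(n_mol))
    mol$frag_len <- pmin(
      sample(frng[1]:frng[2], n_mol, replace = TRUE),
      nchar(mol$template) - mol$frag_start + 1L
    )
    # unique UMIs by rejection (collision probability ~ n^2/4^len)
    umis <- character(0)
    while (length(umis) < n_mol) {
      need <- n_mol - length(umis)
      umis <- unique(c(umis, vapply(seq_len(need), function(i) {
        random_dna(ul)
      }, "")))
    }
    mol$umi <- umis[seq_len(n_mol)]
    mol$insert <- substring(mol$template, mol$frag_start,
      mol$frag_start + mol$frag_len - 1L)

    n_copies <- 1L + rpois(n_mol, config$duplicate_rate - 1)
    idx <- rep(seq_len(n_mol), n_copies)
    copy_no <- sequence(n_copies)

    if (config$umi_read == "R1") {
      r1_tpl <- paste0(mol$umi[idx], substring(mol$insert[idx], 1L, ins_len))
      r2_tpl <- revcomp(substring(
        mol$insert[idx],
        pmax(1L, mol$frag_len[idx] - rl + 1L),
        mol$frag_len[idx]
      ))
    } else {
      r1_tpl <- substring(mol$insert[idx], 1L, rl)
      r2_tpl <- paste0(mol$umi[idx], revcomp(substring(
        mol$insert[idx],
        pmax(1L, mol$frag_len[idx] - ins_len + 1L),
        mol$frag_len[idx]
      )))
    }
    r1 <- mutate_seqs(r1_tpl, config$error_rate)
    r2 <- mutate_seqs(r2_tpl, config$error_rate)
    qual_of <- function(seqs) {
      vapply(nchar(seqs), function(n) phred_to_chr(sample(30:40, n, replace = TRUE)), "")
    }
    ids <- sprintf("%s:%s:c%d", mol$source[idx], mol$mol_id[idx], copy_no)
    reads <- dplyr::bind_rows(
      tibble(read_id = ids, mate = "R1", seq = r1, qual = qual_of(r1)),
      tibble(read_id = ids, mate = "R2", seq = r2, qual = qual_of(r2))
    )
    truth <- truths
    if (nrow(truth) > 0) {
      planted <- split(mol$mol_id, mol$source)
      truth$planted_molecules <- lapply(truth$fusion_id, function(f) {
        planted[[f]] %||% character(0)
      })
    }
    structure(
      list(
        reads = reads,
        truth = truth,
        molecules = mol[, c("mol_id", "source", "umi", "frag_start", "frag_len", "insert")]
      ),
      class = "fusion_sim"
    )
  })
}

#' Write simulated data to disk
#'
#' Writes R1/R2 FASTQ, the genome FASTA, transcript models as GTF, and the
#' truth table as TSV.
#'
#' @param sim A `fusion_sim` from [simulate_reads()].
#' @param panel The `fusion_panel` used for simulation.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
sim_write <- function(sim, panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fastq(sim$reads, file.path(dir, "reads_R1.fastq"), mate = "R1")
  write_fastq(sim$reads, file.path(dir, "reads_R2.fastq"), mate = "R2")
  write_fasta(panel$genome, file.path(dir, "genome.fa"))
  write_transcript_gtf(panel$transcripts, file.path(dir, "transcripts.gtf"))
  truth <- sim$truth
  if (nrow(truth) > 0) {
    truth <- truth[, c(
      "fusion_id", "gene5", "gene3", "chrom5", "pos5", "strand5",
      "chrom3", "pos3", "strand3", "n_molecules"
    )]
  }
  utils::write.table(truth, file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}
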