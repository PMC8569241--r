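test_that("hamming distance counts mismatching positions", {
  expect_identical(umi_hamming("ACGT", "ACGT"), 0L)
  expect_identical(umi_hamming("ACGT", "ACGA"), 1L)
  expect_identical(umi_hamming("AAAA", "TTTT"), 4L)
  expect_error(umi_hamming("AC", "ACG"), "equal-length")
})

test_that("2-bit UMI encoding is the A<C<G<T map and round-trips", {
  expect_identical(encode_umi("A"), 0)
  expect_identical(encode_umi("C"), 1)
  expect_identical(encode_umi("G"), 2)
  expect_identical(encode_umi("T"), 3)
  set.seed(11)
  for (i in 1:20) {
    u <- rand_dna(12)
    expect_identical(decode_umi(encode_umi(u), 12), u)
  }
  expect_error(encode_umi("ACGTACGTACGTACGTA"), "longer than 16")
  expect_error(encode_umi("ACGN"), "non-ACGT")
})

# union-find closure over all pairs within the hamming tolerance: the
# independent clustering oracle
cluster_oracle <- function(umis, max_hamming) {
  n <- length(umis)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && umi_hamming(umis[i], umis[j]) <= max_hamming) {
        parent[find(i)] <- find(j)
      }
    }
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

test_that("UMI clustering matches expectations and partitions the input", {
  cl <- cluster_umis(rep("ACGT", 5), max_hamming = 1)
  expect_identical(length(unique(cl)), 1L)

  umis <- c(rep("AAAA", 3), "AAAT")
  cl <- cluster_umis(umis, max_hamming = 1)
  expect_identical(length(unique(cl)), 1L)
  expect_identical(length(unique(cl)), cluster_oracle(unique(umis), 1))

  cl <- cluster_umis(c("AAAA", "TTTT"), max_hamming = 1)
  expect_identical(length(unique(cl)), 2L)

  # every read lands in exactly one cluster
  set.seed(4)
  umis <- replicate(40, rand_dna(6))
  cl <- cluster_umis(umis, max_hamming = 1)
  expect_identical(length(cl), 40L)
  expect_true(all(cl >= 1))

  # N-containing UMIs become their own singleton clusters
  cl <- cluster_umis(c("AANA", "AANA", "AAAA"), max_hamming = 1)
  expect_identical(length(unique(cl)), 3L)
})

test_that("single-observation consensus reproduces the input call", {
  r <- consensus_base("C", 20L)
  expect_identical(r$base, "C")
  expect_identical(r$qual, 20L)
  expect_equal(unname(r$posterior["C"]), 0.99, tolerance = 1e-12)
})

test_that("consensus posterior equals the brute-force Bayes oracle", {
  r <- consensus_base(c("A", "A", "A"), c(30L, 30L, 30L))
  oracle <- bayes_oracle(c("A", "A", "A"), c(30, 30, 30))
  expect_identical(r$base, "A")
  expect_equal(unname(r$posterior), unname(oracle), tolerance = 1e-9)
  q_oracle <- min(round(-10 * log10(1 - max(oracle))), 60)
  expect_identical(r$qual, as.integer(q_oracle))
  expect_gt(r$qual, 30)

  set.seed(21)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    quals <- sample(5:40, n, replace = TRUE)
    r <- consensus_base(bases, quals)
    o <- bayes_oracle(bases, quals)
    expect_equal(unname(r$posterior), unname(o), tolerance = 1e-9)
    expect_equal(sum(r$posterior), 1, tolerance = 1e-9)
    expect_identical(r$base, c("A", "C", "G", "T")[which.max(o)])
  }
})

test_that("tied observations break lexicographically and symmetrically", {
  r <- consensus_base(c("A", "G"), c(25L, 25L))
  expect_equal(unname(r$posterior["A"]), unname(r$posterior["G"]))
  expect_identical(r$base, "A")
  expect_error(consensus_base(character(0), integer(0)), "at least one")
})

test_that("an agreeing observation never decreases the consensus posterior", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    quals <- sample(5:40, n, replace = TRUE)
    r0 <- consensus_base(bases, quals)
    r1 <- consensus_base(c(bases, r0$base), c(quals, 20L))
    expect_gte(
      unname(r1$posterior[r0$base]) + 1e-12,
      unname(r0$posterior[r0$base])
    )
  }
})

make_pairs <- function(r1_seqs, r2_seqs, umis, qual = 35L) {
  n <- length(r1_seqs)
  q <- function(s) vapply(nchar(s), function(k) phred_to_chr(rep(qual, k)), "")
  tibble::tibble(
    read_id = rep(sprintf("p%03d", seq_len(n)), 2),
    mate = rep(c("R1", "R2"), each = n),
    seq = c(paste0(umis, r1_seqs), r2_seqs),
    qual = c(q(paste0(umis, r1_seqs)), q(r2_seqs))
  )
}

test_that("exact duplicate pairs collapse to one consensus pair", {
  reads <- make_pairs(
    rep("ACGTACGTACGTACGTACGTACGT", 10),
    rep("TTTTGGGGCCCCAAAATTTTGGGG", 10),
    rep("AAACCCGGGTTT", 10)
  )
  res <- dedupe_reads(reads)
  expect_identical(nrow(res$reads), 2L)
  expect_identical(unique(res$reads$duplicate_count), 10L)
  expect_identical(res$reads$seq[res$reads$mate == "R1"], "ACGTACGTACGTACGTACGTACGT")
  expect_identical(res$stats$clusters, 1L)
})

test_that("single-read clusters pass through bases and qualities unchanged", {
  set.seed(8)
  r1 <- rand_dna(40)
  r2 <- rand_dna(40)
  q1 <- phred_to_chr(sample(5:40, 52, replace = TRUE))
  q2 <- phred_to_chr(sample(5:40, 40, replace = TRUE))
  reads <- tibble::tibble(
    read_id = c("x", "x"), mate = c("R1", "R2"),
    seq = c(paste0("ACGTACGTACGT", r1), r2), qual = c(q1, q2)
  )
  res <- dedupe_reads(reads)
  out1 <- res$reads[res$reads$mate == "R1", ]
  expect_identical(out1$seq, r1)
  expect_identical(out1$qual, substring(q1, 13))
  out2 <- res$reads[res$reads$mate == "R2", ]
  expect_identical(out2$seq, r2)
  expect_identical(out2$qual, q2)
})

test_that("noise-free simulation dedupes to exactly one pair per molecule", {
  s <- small_sim(error_rate = 0, duplicate_rate = 3, sim_seed = 13)
  res <- dedupe_reads(s$sim$reads)
  expect_identical(res$stats$clusters, nrow(s$sim$molecules))
})

test_that("dedupe is idempotent on consensus output", {
  s <- small_sim(sim_seed = 17, n_background = 20)
  once <- dedupe_reads(s$sim$reads)$reads
  # re-attach each consensus pair's UMI so the read structure is unchanged
  again_in <- once
  is_r1 <- again_in$mate == "R1"
  again_in$seq[is_r1] <- paste0(again_in$umi[is_r1], again_in$seq[is_r1])
  again_in$qual[is_r1] <- paste0(
    strrep(rawToChar(as.raw(33 + 40)), 12), again_in$qual[is_r1]
  )
  twice <- dedupe_reads(again_in)$reads
  expect_identical(twice$seq, once$seq)
  expect_identical(twice$qual, once$qual)
  expect_identical(twice$umi, once$umi)
})

test_that("cluster consensus equals a per-position brute-force oracle", {
  set.seed(51)
  for (rep_i in 1:5) {
    n <- sample(2:6, 1)
    L <- sample(4:8, 1)
    tmpl <- rand_dna(L)
    seqs <- vapply(seq_len(n), function(i) {
      ch <- strsplit(tmpl, "")[[1]]
      flip <- runif(L) < 0.2
      ch[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
      paste(ch, collapse = "")
    }, "")
    quals <- matrix(sample(10:40, n * L, replace = TRUE), n, L)
    umi <- "ACGTACGTACGT"
    reads <- tibble::tibble(
      read_id = rep(sprintf("r%d", 1:n), 2),
      mate = rep(c("R1", "R2"), each = n),
      seq = c(paste0(umi, seqs), seqs),
      qual = c(
        vapply(1:n, function(i) phred_to_chr(c(rep(40, 12), quals[i, ])), ""),
        vapply(1:n, function(i) phred_to_chr(quals[i, ]), "")
      )
    )
    out <- dedupe_reads(reads)$reads
    got <- out$seq[out$mate == "R1"]
    expected <- paste(vapply(seq_len(L), function(p) {
      o <- bayes_oracle(substring(seqs, p, p), quals[, p])
      c("A", "C", "G", "T")[which.max(o)]
    }, ""), collapse = "")
    expect_identical(got, expected)
  }
})

test_that("desynchronized mates raise an error naming the read", {
  reads <- tibble::tibble(
    read_id = c("a", "b"), mate = c("R1", "R2"),
    seq = c("ACGTACGTACGTACGT", "ACGT"), qual = c(strrep("I", 16), "IIII")
  )
  expect_error(dedupe_reads(reads), "desynchronized.*a|b")
})
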