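# Low-level sequence helpers shared across the pipeline stages. Sequences are
# plain uppercase character scalars over {A,C,G,T,N}; qualities are Phred+33
# encoded character strings kept in lockstep with the bases.

BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA sequences
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) {
      return(NA_character_)
    }
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  }, "", USE.NAMES = FALSE)
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Convert between Phred integer scores and Phred+33 strings
#'
#' @param q Integer vector of Phred scores (0-93).
#' @param s A single Phred+33 encoded character string.
#' @return `phred_to_chr()` a character scalar; `chr_to_phred()` an integer
#'   vector.
#' @export
phred_to_chr <- function(q) {
  intToUtf8(pmin(pmax(as.integer(q), 0L), 93L) + 33L)
}

#' @rdname phred_to_chr
#' @export
chr_to_phred <- function(s) {
  utf8ToInt(s) - 33L
}

# integer codes 0..3 for A,C,G,T; NA for anything else
base_codes <- function(seq) {
  code <- integer(256)
  code[] <- NA_integer_
  code[utf8ToInt("A")] <- 0L
  code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L
  code[utf8ToInt("T")] <- 3L
  code[utf8ToInt(seq)]
}

codes_to_seq <- function(codes) {
  paste(BASES[codes + 1L], collapse = "")
}

# All k-mer codes of a sequence as doubles (exact up to 4^26); positions are
# 1-based start positions. k-mers containing N get NA.
kmer_codes <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) {
    return(numeric(0))
  }
  m <- as.numeric(base_codes(seq))
  n <- L - k + 1L
  acc <- numeric(n)
  for (j in 0:(k - 1L)) {
    acc <- acc * 4 + m[(1L + j):(n + j)]
  }
  acc
}

# character-level match vector of two equal-length strings
char_matches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) {
    return(logical(0))
  }
  utf8ToInt(a) == utf8ToInt(b)
}

#' Read and write FASTQ as a reads tibble
#'
#' Reads are represented throughout the package as a tibble with one row per
#' read: `read_id`, `mate` ("R1"/"R2"), `seq`, and `qual` (Phred+33 string).
#' Mates of a pair share a `read_id`.
#'
#' @param r1,r2 Paths to the R1 and R2 FASTQ files (plain or gzipped).
#' @param reads A reads tibble.
#' @param path Output path for one mate's FASTQ.
#' @return `read_fastq_pair()` returns a reads tibble; `write_fastq()` returns
#'   `path` invisibly.
#' @export
read_fastq_pair <- function(r1, r2) {
  dplyr::bind_rows(
    read_fastq_one(r1, "R1"),
    read_fastq_one(r2, "R2")
  )
}

read_fastq_one <- function(path, mate) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    mate = mate,
    seq = unname(as.character(x)),
    qual = unname(as.character(Biostrings::quality(x)))
  )
}

#' @rdname read_fastq_pair
#' @param mate Which mate to write ("R1" or "R2").
#' @export
write_fastq <- function(reads, path, mate = "R1") {
  rd <- reads[reads$mate == mate, , drop = FALSE]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nrow(rd) > 0) {
    rec <- paste0("@", rd$read_id, "\n", rd$seq, "\n+\n", rd$qual)
    writeLines(rec, con)
  }
  invisible(path)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

stage_abort <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
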