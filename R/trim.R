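# 3' adapter trimming. A read is trimmed when a suffix of the read matches a
# prefix of an adapter with at least `min_overlap` bases and a mismatch rate
# at or below `max_mismatch_rate`; qualities are trimmed in lockstep.

#' Define an adapter set
#'
#' @param adapters Named character vector of adapter sequences (uppercase
#'   ACGT).
#' @param min_overlap Minimum read-suffix / adapter-prefix overlap.
#' @param max_mismatch_rate Maximum fraction of mismatches in the overlap.
#' @return A list of class `adapter_set`.
#' @export
adapter_set <- function(adapters, min_overlap = 4L, max_mismatch_rate = 0.2) {
  stopifnot(length(adapters) > 0, all(nchar(adapters) > 0))
  if (any(grepl("[^ACGT]", adapters))) {
    stop("adapters must be uppercase ACGT", call. = FALSE)
  }
  structure(
    list(
      adapters = adapters,
      min_overlap = as.integer(min_overlap),
      max_mismatch_rate = max_mismatch_rate
    ),
    class = "adapter_set"
  )
}

#' @rdname adapter_set
#' @param path A FASTA file of adapter sequences.
#' @param ... Passed to [adapter_set()].
#' @export
read_adapters <- function(path, ...) {
  adapter_set(read_fasta(path), ...)
}

# longest trimmed length for one read against one adapter (0 if none)
trim_length_one <- function(seq, adapter, min_overlap, max_mismatch_rate) {
  L <- nchar(seq)
  la <- nchar(adapter)
  best <- 0L
  hi <- min(L, la)
  if (hi < min_overlap) {
    return(best)
  }
  for (ov in seq(hi, min_overlap)) {
    m <- char_matches(substring(seq, L - ov + 1L, L), substring(adapter, 1L, ov))
    if (sum(!m) <= max_mismatch_rate * ov) {
      best <- ov
      break # scanning from longest overlap down: first hit is the longest
    }
  }
  best
}

#' Trim adapters from reads
#'
#' Removes the longest read suffix matching an adapter prefix subject to the
#' adapter set's overlap and mismatch constraints. Reads shorter than
#' `min_length` after trimming are dropped (both mates of a dropped pair are
#' removed when `drop_pairs` is TRUE).
#'
#' @param reads A reads tibble.
#' @param adapters An [adapter_set()].
#' @param min_length Minimum post-trim read length to keep.
#' @param drop_pairs Drop both mates when either falls below `min_length`.
#' @return The trimmed reads tibble.
#' @export
trim_reads <- function(reads, adapters, min_length = 30L, drop_pairs = TRUE) {
  stopifnot(inherits(adapters, "adapter_set"))
  if (nrow(reads) == 0) {
    return(reads)
  }
  cut <- vapply(reads$seq, function(s) {
    max(vapply(adapters$adapters, function(a) {
      trim_length_one(s, a, adapters$min_overlap, adapters$max_mismatch_rate)
    }, 0L))
  }, 0L, USE.NAMES = FALSE)
  keep_len <- nchar(reads$seq) - cut
  reads$seq <- substring(reads$seq, 1L, keep_len)
  reads$qual <- substring(reads$qual, 1L, keep_len)
  short <- nchar(reads$seq) < min_length
  if (drop_pairs) {
    bad_ids <- unique(reads$read_id[short])
    reads <- reads[!(reads$read_id %in% bad_ids), , drop = FALSE]
  } else {
    reads <- reads[!short, , drop = FALSE]
  }
  reads
}
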