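# Candidate-level false-positive filters: mononucleotide repeat content
# around the junction (MRR), a panel blocklist of recurrent artifact pairs or
# regions, and removal of single-transcript events with an allowlist for
# clinically relevant intragenic deletions. Each filter is evaluated on the
# unfiltered candidate and contributes a flag; the kept set is exactly the
# candidates with no dropping flag.

#' Filter configuration
#'
#' @param mrr_window Bases examined on each side of the junction.
#' @param mrr_threshold Drop when either side's MRR is at or above this.
#' @param blocklist Tibble of blocklist entries: either gene pairs (columns
#'   gene_a, gene_b) or regions (chrom, start, end; 1-based inclusive). NULL
#'   for none.
#' @param allowlist Tibble of single-transcript allowlist entries: gene,
#'   min_exon_skip (an intragenic candidate qualifies when it skips at least
#'   this many annotated exons). NULL for none.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(mrr_window = 20L, mrr_threshold = 0.6,
                          blocklist = NULL, allowlist = NULL) {
  stopifnot(mrr_threshold > 0, mrr_threshold <= 1, mrr_window >= 4)
  structure(
    list(
      mrr_window = as.integer(mrr_window), mrr_threshold = mrr_threshold,
      blocklist = blocklist, allowlist = allowlist
    ),
    class = "filter_config"
  )
}

#' Mononucleotide repeat ratio of a sequence window
#'
#' MRR is the length of the longest single-nucleotide run divided by the
#' window length, in (0, 1]. It is invariant under reversal and
#' complementation of the window.
#'
#' @param window Non-empty sequence window.
#' @return The MRR fraction.
#' @export
#' @examples
#' mrr("AACCCCGGTT")
mrr <- function(window) {
  if (is.na(window) || nchar(window) == 0) {
    stop("MRR needs a non-empty window", call. = FALSE)
  }
  r <- rle(strsplit(window, "", fixed = TRUE)[[1]])
  max(r$lengths) / nchar(window)
}

# MRR of the two contig flanks around the junction; windows truncated at the
# contig ends, NA when fewer than 4 bases are available
junction_mrr <- function(contig_seq, junction_offset, window) {
  L <- nchar(contig_seq)
  left <- substring(contig_seq, max(1L, junction_offset - window + 1L), junction_offset)
  right <- substring(contig_seq, junction_offset + 1L, min(L, junction_offset + window))
  list(
    mrr5 = if (nchar(left) >= 4) mrr(left) else NA_real_,
    mrr3 = if (nchar(right) >= 4) mrr(right) else NA_real_
  )
}

in_blocked_region <- function(blocklist, chrom, pos) {
  if (is.null(blocklist) || !"chrom" %in% names(blocklist)) {
    return(FALSE)
  }
  reg <- blocklist[!is.na(blocklist$chrom), , drop = FALSE]
  any(reg$chrom == chrom & reg$start <= pos & pos <= reg$end)
}

blocked_pair <- function(blocklist, g5, g3) {
  if (is.null(blocklist) || !"gene_a" %in% names(blocklist)) {
    return(FALSE)
  }
  bp <- blocklist[!is.na(blocklist$gene_a), , drop = FALSE]
  any((bp$gene_a == g5 & bp$gene_b == g3) |
    (bp$gene_a == g3 & bp$gene_b == g5))
}

allowlisted <- function(allowlist, gene, exon_skip) {
  if (is.null(allowlist) || nrow(allowlist) == 0 || is.na(gene)) {
    return(FALSE)
  }
  any(allowlist$gene == gene & exon_skip >= allowlist$min_exon_skip)
}

#' Apply artifact filters to annotated candidates
#'
#' Adds `mrr5`/`mrr3` and a `flags` column (comma-separated among "MRR",
#' "BLOCKLIST", "SINGLE_TX", "SHORT_WINDOW") plus a logical `keep`.
#' "SHORT_WINDOW" marks junctions too close to a contig edge to measure MRR;
#' such candidates are kept. Single-transcript candidates (gene5 == gene3)
#' are dropped unless the event skips enough exons of an allowlisted gene.
#'
#' @param candidates Annotated candidate tibble with contig sequences in a
#'   `contig_seq` column and gene assignments in `gene5`/`gene3` columns.
#' @param config A [filter_config()].
#' @return The candidate tibble with filter columns added.
#' @export
filter_candidates <- function(candidates, config = filter_config()) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates,
      mrr5 = numeric(0), mrr3 = numeric(0),
      flags = character(0), keep = logical(0)
    ))
  }
  n <- nrow(candidates)
  flags <- vector("list", n)
  m5 <- numeric(n)
  m3 <- numeric(n)
  for (i in seq_len(n)) {
    cc <- candidates[i, ]
    fl <- character(0)
    mm <- junction_mrr(cc$contig_seq, cc$junction_offset, config$mrr_window)
    m5[i] <- mm$mrr5
    m3[i] <- mm$mrr3
    if (is.na(mm$mrr5) || is.na(mm$mrr3)) {
      fl <- c(fl, "SHORT_WINDOW")
    } else if (mm$mrr5 >= config$mrr_threshold ||
      mm$mrr3 >= config$mrr_threshold) {
      fl <- c(fl, "MRR")
    }
    if (blocked_pair(config$blocklist, cc$gene5, cc$gene3) ||
      in_blocked_region(config$blocklist, cc$chrom5, cc$pos5) ||
      in_blocked_region(config$blocklist, cc$chrom3, cc$pos3)) {
      fl <- c(fl, "BLOCKLIST")
    }
    if (!is.na(cc$gene5) && !is.na(cc$gene3) && cc$gene5 == cc$gene3) {
      skip <- if ("exon_skip" %in% names(cc)) cc$exon_skip else 0L
      if (!allowlisted(config$allowlist, cc$gene5, skip %||% 0L)) {
        fl <- c(fl, "SINGLE_TX")
      }
    }
    flags[[i]] <- fl
  }
  dropping <- c("MRR", "BLOCKLIST", "SINGLE_TX")
  candidates$mrr5 <- m5
  candidates$mrr3 <- m3
  candidates$flags <- vapply(flags, paste, "", collapse = ",")
  candidates$keep <- !vapply(flags, function(f) any(f %in% dropping), TRUE)
  candidates
}

#' Read a blocklist or allowlist TSV
#'
#' Blocklists accept two-column `gene_a gene_b` rows or three-column
#' `chrom start end` rows (1-based inclusive); allowlists are
#' `gene min_exon_skip` rows.
#'
#' @param path TSV path.
#' @param type "blocklist" or "allowlist".
#' @return A tibble in the layout [filter_config()] expects.
#' @export
read_filter_table <- function(path, type = c("blocklist", "allowlist")) {
  type <- match.arg(type)
  raw <- utils::read.table(path,
    sep = "\t", header = FALSE,
    stringsAsFactors = FALSE, fill = TRUE
  )
  if (type == "allowlist") {
    return(tibble(gene = raw[[1]], min_exon_skip = as.integer(raw[[2]])))
  }
  is_region <- suppressWarnings(!is.na(as.integer(raw[[2]])))
  tibble(
    gene_a = ifelse(is_region, NA_character_, raw[[1]]),
    gene_b = ifelse(is_region, NA_character_, as.character(raw[[2]])),
    chrom = ifelse(is_region, raw[[1]], NA_character_),
    start = ifelse(is_region, suppressWarnings(as.integer(raw[[2]])), NA_integer_),
    end = ifelse(is_region, suppressWarnings(as.integer(raw[[3]])), NA_integer_)
  )
}
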