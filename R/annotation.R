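# Exon and reading-frame annotation of breakpoint candidates against
# transcript models. Breakpoints near an exon boundary (within a snapping
# tolerance) are classified Exon-exon_boundary and labelled
# "strand|End_Ek|gene|transcript" on the 5' side / "strand|Start_Ek|..." on
# the 3' side, with exon numbers in transcription order. A fusion is In-frame
# when the coding bases retained from the 5' transcript up to the junction,
# modulo 3, equal the CDS phase at the 3' acceptor exon start.

# choose the annotating transcript for a breakpoint: canonical first, then
# longest CDS; returns NULL when no transcript locus contains the position
pick_transcript <- function(models, chrom, pos, tolerance) {
  if (!"canonical" %in% names(models)) {
    models$canonical <- FALSE
  }
  if (!any(models$chrom == chrom)) {
    return(NULL)
  }
  tx <- dplyr::summarise(
    dplyr::group_by(
      models[models$chrom == chrom, , drop = FALSE],
      .data$gene, .data$transcript_id
    ),
    span_start = min(.data$start), span_end = max(.data$end),
    canonical = isTRUE(.data$canonical[1]),
    cds_len = if (all(is.na(.data$cds_start))) {
      0L
    } else {
      sum(pmax(
        0L,
        pmin(.data$end, .data$cds_end) - pmax(.data$start, .data$cds_start) + 1L
      ))
    },
    .groups = "drop"
  )
  tx <- tx[tx$span_start - tolerance <= pos & pos <= tx$span_end + tolerance, ,
    drop = FALSE
  ]
  if (nrow(tx) == 0) {
    return(NULL)
  }
  tx <- dplyr::arrange(
    tx, dplyr::desc(.data$canonical), dplyr::desc(.data$cds_len),
    .data$transcript_id
  )
  tx$transcript_id[1]
}

#' Locate a breakpoint on the transcript models
#'
#' @param chrom,pos Breakpoint position (1-based genomic).
#' @param models Exon-level transcript tibble (gene, transcript_id, chrom,
#'   strand, exon, start, end, cds_start, cds_end, optional canonical).
#' @param tolerance Breakpoints within this many bases of an exon boundary
#'   snap to it.
#' @return A list: gene, transcript_id, strand, exon (transcription-order
#'   index), boundary ("End"/"Start"/NA), location_class
#'   ("Exon-exon_boundary", "Mid-exon", "Intronic"), snapped_pos.
#'   Breakpoints outside every locus return gene NA with class "Intronic".
#' @export
locate_breakpoint <- function(chrom, pos, models, tolerance = 3L) {
  tid <- pick_transcript(models, chrom, pos, tolerance)
  if (is.null(tid)) {
    return(list(
      gene = NA_character_, transcript_id = NA_character_,
      strand = NA_character_, exon = NA_integer_, boundary = NA_character_,
      location_class = "Intronic", snapped_pos = pos
    ))
  }
  ex <- models[models$transcript_id == tid, , drop = FALSE]
  ex <- ex[order(ex$exon), , drop = FALSE]
  strand <- ex$strand[1]
  # nearest exon boundary; genomic left/right edges map to transcription
  # Start/End by strand
  bnd <- dplyr::bind_rows(
    tibble(
      exon = ex$exon, gpos = ex$start,
      kind = if (strand == "+") "Start" else "End"
    ),
    tibble(
      exon = ex$exon, gpos = ex$end,
      kind = if (strand == "+") "End" else "Start"
    )
  )
  d <- abs(bnd$gpos - pos)
  near <- which.min(d)
  if (d[near] <= tolerance) {
    return(list(
      gene = ex$gene[1], transcript_id = tid, strand = strand,
      exon = bnd$exon[near], boundary = bnd$kind[near],
      location_class = "Exon-exon_boundary", snapped_pos = bnd$gpos[near]
    ))
  }
  inside <- which(ex$start <= pos & pos <= ex$end)
  list(
    gene = ex$gene[1], transcript_id = tid, strand = strand,
    exon = if (length(inside)) ex$exon[inside[1]] else NA_integer_,
    boundary = NA_character_,
    location_class = if (length(inside)) "Mid-exon" else "Intronic",
    snapped_pos = pos
  )
}

# CDS bases of a transcript from the CDS start through the transcription-order
# end of exon `upto`
cds_bases_through_exon <- function(ex, upto) {
  ex <- ex[order(ex$exon), , drop = FALSE]
  keep <- ex[ex$exon <= upto, , drop = FALSE]
  sum(pmax(
    0L,
    pmin(keep$end, keep$cds_end) - pmax(keep$start, keep$cds_start) + 1L
  ))
}

# CDS phase at the transcription-order start of exon `at` (CDS bases from the
# CDS start up to that exon start, mod 3); NA when the transcript is
# non-coding or the CDS has already ended upstream of that exon
cds_phase_at_exon_start <- function(ex, at) {
  if (all(is.na(ex$cds_start))) {
    return(NA_integer_)
  }
  ex <- ex[order(ex$exon), , drop = FALSE]
  cds_exons <- which(ex$end >= ex$cds_start & ex$start <= ex$cds_end)
  if (length(cds_exons) == 0 || max(cds_exons) < at) {
    return(NA_integer_) # CDS entirely upstream: no reading frame to preserve
  }
  as.integer(cds_bases_through_exon(ex, at - 1L) %% 3)
}

#' Reading-frame status of a fusion junction
#'
#' @param models Transcript models tibble.
#' @param tx5,exon5 5' transcript id and the transcription-order exon whose
#'   end is the junction.
#' @param tx3,exon3 3' transcript id and the exon whose start is the
#'   junction.
#' @return "In-frame", "Out-of-frame", or "Indeterminate" (either side
#'   non-coding or without CDS context at the junction).
#' @export
frame_status <- function(models, tx5, exon5, tx3, exon3) {
  if (is.na(tx5) || is.na(tx3) || is.na(exon5) || is.na(exon3)) {
    return("Indeterminate")
  }
  ex5 <- models[models$transcript_id == tx5, , drop = FALSE]
  ex3 <- models[models$transcript_id == tx3, , drop = FALSE]
  if (all(is.na(ex5$cds_start)) || all(is.na(ex3$cds_start))) {
    return("Indeterminate")
  }
  l5 <- cds_bases_through_exon(ex5, exon5)
  p3 <- cds_phase_at_exon_start(ex3, exon3)
  if (l5 == 0 || is.na(p3)) {
    return("Indeterminate")
  }
  if (l5 %% 3 == p3) "In-frame" else "Out-of-frame"
}

#' Format / parse side annotation labels
#'
#' Labels follow the "strand|End_Ek|gene|transcript" convention, e.g.
#' `"+|End_E17|FGFR3|NM_001163213"`.
#'
#' @param strand,boundary,exon,gene,transcript_id Label components.
#' @param label A formatted label.
#' @return `format_side_label()` a string; `parse_side_label()` a list of the
#'   components.
#' @export
format_side_label <- function(strand, boundary, exon, gene, transcript_id) {
  if (is.na(gene)) {
    return(NA_character_)
  }
  sprintf("%s|%s_E%d|%s|%s", strand, boundary, exon, gene, transcript_id)
}

#' @rdname format_side_label
#' @export
parse_side_label <- function(label) {
  parts <- strsplit(label, "|", fixed = TRUE)[[1]]
  stopifnot(length(parts) == 4)
  be <- strsplit(parts[2], "_E", fixed = TRUE)[[1]]
  list(
    strand = parts[1], boundary = be[1], exon = as.integer(be[2]),
    gene = parts[3], transcript_id = parts[4]
  )
}

#' Annotate breakpoint candidates with gene, exon and frame context
#'
#' @param candidates Candidate tibble (see [call_candidates()]).
#' @param models Transcript models tibble.
#' @param tolerance Exon-boundary snapping tolerance (bases).
#' @return The candidates with columns gene5, gene3, tx5, tx3, exon5_label,
#'   exon3_label, location_class, frame, exon5, exon3 and exon_skip (for
#'   intragenic events, exons skipped between the two sides).
#' @export
annotate_candidates <- function(candidates, models, tolerance = 3L) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates,
      gene5 = character(0), gene3 = character(0),
      tx5 = character(0), tx3 = character(0),
      exon5 = integer(0), exon3 = integer(0),
      exon5_label = character(0), exon3_label = character(0),
      location_class = character(0), frame = character(0),
      exon_skip = integer(0)
    ))
  }
  n <- nrow(candidates)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    cc <- candidates[i, ]
    l5 <- locate_breakpoint(cc$chrom5, cc$pos5, models, tolerance)
    l3 <- locate_breakpoint(cc$chrom3, cc$pos3, models, tolerance)
    # junction microhomology leaves the split point ambiguous; when both
    # sides sit within tolerance of exon boundaries and agree on the same
    # junction shift, snap the breakpoints to the annotated boundaries
    if (l5$location_class == "Exon-exon_boundary" &&
      l3$location_class == "Exon-exon_boundary") {
      d5 <- (l5$snapped_pos - cc$pos5) * (if (cc$strand5 == "+") 1L else -1L)
      d3 <- (l3$snapped_pos - cc$pos3) * (if (cc$strand3 == "+") 1L else -1L)
      if (d5 == d3 && d5 != 0L) {
        candidates$pos5[i] <- l5$snapped_pos
        candidates$pos3[i] <- l3$snapped_pos
        if ("junction_offset" %in% names(candidates)) {
          candidates$junction_offset[i] <- cc$junction_offset + d5
        }
      }
    }
    loc <- if (l5$location_class == "Exon-exon_boundary" &&
      l3$location_class == "Exon-exon_boundary") {
      "Exon-exon_boundary"
    } else if (l5$location_class == "Mid-exon" ||
      l3$location_class == "Mid-exon") {
      "Mid-exon"
    } else {
      "Intronic"
    }
    fr <- if (loc == "Exon-exon_boundary") {
      frame_status(models, l5$transcript_id, l5$exon, l3$transcript_id, l3$exon)
    } else {
      "Indeterminate"
    }
    skip <- NA_integer_
    if (!is.na(l5$gene) && !is.na(l3$gene) && l5$gene == l3$gene &&
      !is.na(l5$exon) && !is.na(l3$exon)) {
      skip <- max(0L, l3$exon - l5$exon - 1L)
    }
    res[[i]] <- tibble(
      gene5 = l5$gene, gene3 = l3$gene,
      tx5 = l5$transcript_id, tx3 = l3$transcript_id,
      exon5 = l5$exon, exon3 = l3$exon,
      exon5_label = format_side_label(
        l5$strand, if (is.na(l5$boundary)) "End" else l5$boundary,
        l5$exon, l5$gene, l5$transcript_id
      ),
      exon3_label = format_side_label(
        l3$strand, if (is.na(l3$boundary)) "Start" else l3$boundary,
        l3$exon, l3$gene, l3$transcript_id
      ),
      location_class = loc, frame = fr, exon_skip = skip
    )
  }
  dplyr::bind_cols(candidates, dplyr::bind_rows(res))
}
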