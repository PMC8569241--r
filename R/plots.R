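# ggplot2 views of pipeline results and broom-style accessors.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the confirmed calls of a pipeline run
#'
#' @param x A `fusion_result`.
#' @param ... Unused.
#' @return One row per confirmed call.
#' @method tidy fusion_result
#' @export
tidy.fusion_result <- function(x, ...) {
  if (nrow(x$calls) == 0) {
    return(tibble(
      call_id = character(0), gene5 = character(0), gene3 = character(0),
      chrom5 = character(0), pos5 = integer(0),
      chrom3 = character(0), pos3 = integer(0),
      location_class = character(0), frame = character(0),
      supporting_reads = integer(0), contig_id = character(0)
    ))
  }
  as_tibble(x$calls[, c(
    "call_id", "gene5", "gene3", "chrom5", "pos5", "chrom3", "pos3",
    "location_class", "frame", "supporting_reads", "contig_id"
  )])
}

#' One-row summary of a pipeline run
#'
#' @param x A `fusion_result`.
#' @param ... Unused.
#' @return A one-row tibble of stage counts.
#' @method glance fusion_result
#' @export
glance.fusion_result <- function(x, ...) {
  tibble(
    input_reads = x$manifest$input_reads,
    consensus_pairs = x$dedup_stats$clusters,
    mean_duplicates = x$dedup_stats$mean_duplicates,
    contigs = x$manifest$contigs,
    candidates = x$manifest$collapsed_candidates,
    kept_candidates = x$manifest$kept_candidates,
    calls = nrow(x$calls)
  )
}

#' @method tidy fusion_sweep
#' @export
tidy.fusion_sweep <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Plot supporting reads per confirmed call
#'
#' @param object A `fusion_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fusion_result
#' @export
autoplot.fusion_result <- function(object, ...) {
  d <- tidy(object)
  d$fusion <- paste0(d$gene5, "-", d$gene3)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$fusion, .data$supporting_reads),
    y = .data$supporting_reads, fill = .data$frame
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Supporting consensus reads", fill = "Frame",
      title = "Confirmed fusion calls"
    ) +
    ggplot2::theme_minimal()
}

#' Plot accuracy and TPR across read-support cutoffs
#'
#' @param object A `fusion_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fusion_sweep
#' @export
autoplot.fusion_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(tidy(object),
    cols = c("accuracy", "tpr"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$cutoff, y = .data$value, colour = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Read-support cutoff", y = NULL, colour = NULL,
      title = "Caller performance vs read-support threshold"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fusion_result
#' @param result A `fusion_result`.
#' @export
plot_support <- function(result, ...) autoplot(result, ...)

#' @rdname autoplot.fusion_sweep
#' @param sweep A `fusion_sweep`.
#' @export
plot_threshold_sweep <- function(sweep, ...) autoplot(sweep, ...)
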