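# ggplot2 views of the standard result types. Each takes the tidy tibble
# the analysis functions emit and returns a ggplot object.

#' Histogram of distances to the nearest TSS
#'
#' Log10-binned distances with the proximal/distal threshold marked, the
#' view used to stratify peak-proximal from distal (intergenic) regulatory
#' elements.
#'
#' @param distances tibble from [tss_distance()].
#' @param threshold proximity threshold in bp (vertical line); default 10 kb.
#' @return a ggplot.
#' @export
plot_tss_distance <- function(distances, threshold = 10000) {
  d <- dplyr::filter(distances, .data$tss_available)
  ggplot2::ggplot(d, ggplot2::aes(x = pmax(.data$tss_distance, 1))) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_log10(labels = function(x) format(x, big.mark = ",",
                                                       scientific = FALSE)) +
    ggplot2::labs(x = "distance to nearest TSS (bp)", y = "features") +
    ggplot2::theme_minimal()
}

#' Replicate concordance scatter
#'
#' Per-guide log2 fold changes of one replicate against another, one panel
#' per replicate pair, annotated with the correlation coefficient.
#'
#' @param fit a `screen_fit` (or the long lfc tibble from
#'   [guide_log2fc()]).
#' @param condition condition to plot; first condition when `NULL`.
#' @return a ggplot.
#' @export
plot_replicate_scatter <- function(fit, condition = NULL) {
  lfc <- if (inherits(fit, "screen_fit")) fit$lfc else fit
  if (is.null(condition)) condition <- lfc$condition[1]
  w <- tidyr::pivot_wider(
    lfc[lfc$condition == condition, c("guide_id", "replicate", "lfc")],
    names_from = "replicate", values_from = "lfc", names_prefix = "rep")
  reps <- setdiff(names(w), "guide_id")
  pairs <- utils::combn(reps, 2, simplify = FALSE)
  long <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(pair = paste(p[1], "vs", p[2]),
                   x = w[[p[1]]], y = w[[p[2]]])
  })
  labels <- long |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(r = stats::cor(.data$x, .data$y), .groups = "drop") |>
    dplyr::mutate(label = sprintf("r = %.2f", .data$r))
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_text(data = labels, ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                       inherit.aes = FALSE) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "log2FC (first replicate)",
                  y = "log2FC (second replicate)",
                  title = condition) +
    ggplot2::theme_minimal()
}

#' Peak-level volcano plot
#'
#' Median log2 fold change against -log10 FDR, with significant peaks
#' highlighted.
#'
#' @param peak_stats tibble from [aggregate_peaks()] (or `tidy(fit)`).
#' @param fdr_threshold highlight threshold; default 0.05.
#' @return a ggplot.
#' @export
plot_peak_volcano <- function(peak_stats, fdr_threshold = 0.05) {
  d <- dplyr::mutate(peak_stats,
                     status = dplyr::case_when(
                       .data$fdr < fdr_threshold & .data$median_lfc > 0 ~
                         "enriched",
                       .data$fdr < fdr_threshold & .data$median_lfc < 0 ~
                         "depleted",
                       TRUE ~ "ns"))
  ggplot2::ggplot(d, ggplot2::aes(.data$median_lfc, -log10(.data$fdr),
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::scale_colour_manual(values = c(enriched = "firebrick",
                                            depleted = "steelblue",
                                            ns = "grey60")) +
    ggplot2::geom_hline(yintercept = -log10(fdr_threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "peak median log2FC (vs pDNA)", y = "-log10 FDR",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Guides-per-peak histogram
#'
#' Distribution of the number of sgRNA designs per peak (or per motif).
#'
#' @param summary a `library_summary` from [summarize_library()].
#' @param by `"peak"` or `"motif"`.
#' @return a ggplot.
#' @export
plot_guides_per_target <- function(summary, by = c("peak", "motif")) {
  by <- match.arg(by)
  h <- if (by == "peak") {
    dplyr::rename(summary$peak_histogram, n = "n_peaks")
  } else {
    dplyr::rename(summary$motif_histogram, n = "n_motifs")
  }
  ggplot2::ggplot(h, ggplot2::aes(factor(.data$n_guides), .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = paste0("sgRNAs per ", by), y = paste0(by, "s")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_peak_volcano
#' @param object a `screen_fit`.
#' @param ... passed to [plot_peak_volcano()].
#' @method autoplot screen_fit
#' @export
autoplot.screen_fit <- function(object, ...) {
  plot_peak_volcano(object$peak_stats, ...)
}
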