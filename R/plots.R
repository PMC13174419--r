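#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of a differential result
#'
#' @param object a `diff_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot diff_result
#' @export
autoplot.diff_result <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat <- dat[!is.na(dat$p_value), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$delta,
                                    y = -log10(pmax(.data$p_value, 1e-300)),
                                    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2471a3", ns = "grey60")) +
    ggplot2::labs(x = sprintf("mean difference (%s - %s)",
                              attr(object, "treatment"),
                              attr(object, "reference")),
                  y = expression(-log[10]~p), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of pathway enrichment
#'
#' @param object an `enrichment_result`.
#' @param top_k how many top pathways to show (default 16).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, top_k = 16, ...) {
  dat <- utils::head(tibble::as_tibble(object), top_k)
  dat$pathway <- factor(dat$pathway, levels = rev(dat$pathway))
  ggplot2::ggplot(dat, ggplot2::aes(x = -log10(pmax(.data$p_value, 1e-300)),
                                    y = .data$pathway,
                                    size = .data$enrichment_ratio)) +
    ggplot2::geom_point(colour = "#c0392b") +
    ggplot2::labs(x = expression(-log[10]~p), y = NULL,
                  size = "enrichment\nratio") +
    ggplot2::theme_minimal()
}

#' Diverging bar plot of pathway DA scores
#'
#' @param object a `da_score`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot da_score
#' @export
autoplot.da_score <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat <- dat[!dat$undefined, ]
  dat <- dat[order(dat$score), ]
  dat$pathway <- factor(dat$pathway, levels = dat$pathway)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, y = .data$pathway,
                                    fill = .data$score > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "#2471a3")) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "DA score (U - D) / T", y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked isotopologue fraction plot
#'
#' @param object a `fractional_labeling` table.
#' @param metabolites which metabolites to show (default: all).
#' @param ... unused.
#' @return a ggplot of per-sample stacked isotopologue fractions.
#' @method autoplot fractional_labeling
#' @export
autoplot.fractional_labeling <- function(object, metabolites = NULL, ...) {
  dat <- tibble::as_tibble(object)
  if (!is.null(metabolites)) dat <- dat[dat$metabolite %in% metabolites, ]
  dat <- dat[dat$defined, ]
  dat$isotopologue <- factor(paste0("M+", dat$mass_shift),
                             levels = paste0("M+", sort(unique(dat$mass_shift))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_id, y = .data$frac,
                                    fill = .data$isotopologue)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metabolite) +
    ggplot2::labs(x = NULL, y = "fraction of pool", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Mean enrichment along a pathway chain
#'
#' @param disc result of [enrichment_discontinuity()].
#' @return a ggplot of replicate-mean enrichment per chain position, with the
#'   candidate discontinuity edge marked.
#' @export
plot_chain_enrichment <- function(disc) {
  e <- disc$mean_enrichment
  dat <- tibble::tibble(position = seq_along(e),
                        metabolite = factor(names(e), levels = names(e)),
                        enrichment = unname(e))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$metabolite,
                                         y = .data$enrichment, group = 1)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = NULL, y = "mean enrichment E") +
    ggplot2::theme_minimal()
  if (!is.na(disc$candidate_edge)) {
    p <- p + ggplot2::geom_vline(xintercept = disc$candidate_edge + 0.5,
                                 linetype = "dashed", colour = "#c0392b")
  }
  p
}

#' Row-scaled heatmap of an intensity matrix
#'
#' Z-scores each metabolite across samples (via [row_zscore()]) and draws a
#' tile heatmap, the display convention for relative-abundance figures.
#'
#' @param x an [intensity_matrix] with no missing values.
#' @return a ggplot.
#' @export
plot_heatmap <- function(x) {
  z <- if (im_scale(x) == "zscore") x else row_zscore(x)
  long <- tidy(z)
  long$metabolite_id <- factor(long$metabolite_id,
                               levels = rev(unique(long$metabolite_id)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$metabolite_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2471a3", mid = "white",
                                  high = "#c0392b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "row z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
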