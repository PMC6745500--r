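#' Volcano plot of scored interactions
#'
#' BFDR against average fold change over controls (both log-scaled), the
#' standard per-bait view of an AP-MS score table. Pairs below the BFDR
#' and above the fold-change thresholds are highlighted.
#'
#' @param scores Tibble from [score_interactions()].
#' @param bfdr_max,fc_min Highlight thresholds (defaults 0.01 and 2).
#' @return A ggplot object.
#' @export
plot_volcano <- function(scores, bfdr_max = 0.01, fc_min = 2) {
  d <- scores |>
    filter(!is.na(.data$bfdr)) |>
    mutate(hit = .data$bfdr < bfdr_max & .data$avg_fc > fc_min)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc,
                                  y = -log10(pmax(.data$bfdr, 1e-6)),
                                  colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change over controls",
                  y = "-log10 BFDR")
}

#' @describeIn interactome_correlation Heatmap of the bait-bait Pearson
#'   matrix in clustering order.
#' @param object A `kzfp_correlation` object.
#' @param ... Unused.
#' @method autoplot kzfp_correlation
#' @export
autoplot.kzfp_correlation <- function(object, ...) {
  ord <- object$order
  d <- tidy(object) |>
    filter(.data$bait_a %in% ord, .data$bait_b %in% ord) |>
    mutate(bait_a = factor(.data$bait_a, levels = ord),
           bait_b = factor(.data$bait_b, levels = ord))
  ggplot2::ggplot(d, ggplot2::aes(.data$bait_a, .data$bait_b,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @describeIn consensus_logo Stacked-letter logo scaled by information
#'   content.
#' @param object A `consensus_logo` object.
#' @param ... Unused.
#' @method autoplot consensus_logo
#' @export
autoplot.consensus_logo <- function(object, ...) {
  d <- tidy(object) |>
    group_by(.data$column) |>
    arrange(.data$prob, .by_group = TRUE) |>
    mutate(height = .data$prob * .data$ic,
           ymax = cumsum(.data$height),
           ymin = .data$ymax - .data$height,
           ymid = (.data$ymin + .data$ymax) / 2) |>
    ungroup()
  ggplot2::ggplot(d) +
    ggplot2::geom_text(ggplot2::aes(x = .data$column, y = .data$ymid,
                                    label = .data$residue,
                                    size = .data$height),
                       show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 6)) +
    ggplot2::labs(x = "alignment column", y = "information content (bits)")
}

#' @describeIn fit_mixture EM log-likelihood trace.
#' @param object A `mixture_fit` object.
#' @param ... Unused.
#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, ...) {
  d <- tibble(iteration = seq_along(object$loglik), logLik = object$loglik)
  ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$logLik)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "log-likelihood")
}

#' Distribution of loss-of-function constraint Z-scores
#'
#' @param constraints Tibble from [z_scores()].
#' @param highlight Optional gene ids drawn as rug marks.
#' @return A ggplot object.
#' @export
plot_constraint <- function(constraints, highlight = NULL) {
  p <- ggplot2::ggplot(constraints, ggplot2::aes(.data$z)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "LoF constraint Z-score", y = "genes")
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_rug(
      data = filter(constraints, .data$gene_id %in% highlight),
      colour = "firebrick"
    )
  }
  p
}
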