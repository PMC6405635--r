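#' Plot a discovered signature
#'
#' Bar chart of the gilded-set frequency of each signature gene, one panel
#' per voter.
#'
#' @param object An `mss_signature`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mss_signature <- function(object, ...) {
  tab <- as_tibble(object) %>%
    mutate(voter = paste0(.data$category, ifelse(.data$list_id > 1,
                                                 paste0("#", .data$list_id),
                                                 "")))
  ggplot2::ggplot(tab, ggplot2::aes(
    x = stats::reorder(.data$gene_id, .data$frequency),
    y = .data$frequency)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~voter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "gilded-set frequency",
                  title = "Signature gene frequencies")
}

#' Plot per-sample voting margins
#'
#' Summed fuzzy margins (cosine distance to the CR centroid minus distance
#' to the RD centroid) per sample, coloured by the predicted label.
#'
#' @param object An `mss_prediction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mss_prediction <- function(object, ...) {
  tab <- as_tibble(object)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = stats::reorder(.data$sample_id, .data$margin_sum),
    y = .data$margin_sum, fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "summed margin (RD leaning > 0)",
                  fill = "call") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Plot a combination-search report
#'
#' Mean precision against mean recall for every evaluated signature
#' combination, sized by combination size.
#'
#' @param object An `mss_combination_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mss_combination_report <- function(object, ...) {
  tab <- as_tibble(object) %>%
    mutate(best = .data$combination == attr(object, "best"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mean_recall,
                                    y = .data$mean_precision,
                                    size = factor(.data$k),
                                    colour = .data$best)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "mean recall (RD)", y = "mean precision (RD)",
                  size = "k", colour = "best balanced")
}

#' Plot relative contribution scores
#'
#' @param object An `mss_rcs`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mss_rcs <- function(object, ...) {
  tab <- as_tibble(object)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = stats::reorder(.data$gene_id, .data$rcs), y = .data$rcs,
    fill = .data$in_signature)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "relative contribution score",
                  fill = "signature gene")
}

#' Plot cross-validation metrics per fold
#'
#' @param object An `mss_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mss_cv <- function(object, ...) {
  tab <- as_tibble(object) %>%
    tidyr::pivot_longer(c("precision", "recall"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$fold), y = .data$value,
                                    fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "fold", y = NULL, fill = NULL)
}
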