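#' Plot a manifold embedding of LI profiles
#'
#' Scatter of the 2-D embedding, one point per participant; an optional
#' continuous `colour_by` vector (e.g. the LI of one feature) is mapped
#' to colour to show how lateralisation varies over the manifold.
#'
#' @param object An `li_embedding`.
#' @param colour_by Optional numeric vector, one value per participant.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.li_embedding <- function(object, colour_by = NULL, ...) {
  p <- object
  if (!is.null(colour_by)) p$colour_by <- colour_by
  g <- ggplot2::ggplot(p, ggplot2::aes(x = .data$umap1, y = .data$umap2)) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2",
                  title = "Manifold of lateralisation profiles") +
    ggplot2::theme_minimal()
  if (is.null(colour_by)) {
    g + ggplot2::geom_point(alpha = 0.7)
  } else {
    g + ggplot2::geom_point(ggplot2::aes(colour = .data$colour_by),
                            alpha = 0.8) +
      ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey85",
                                      high = "#b2182b", midpoint = 0,
                                      name = "LI")
  }
}

#' Plot a sample-size stability simulation
#'
#' Fraction of replicates with conclusive evidence (BF10 above the
#' threshold, and below its reciprocal) as a function of sample size.
#'
#' @param object An `li_stability`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.li_stability <- function(object, ...) {
  s <- tidy(object) |>
    tidyr::pivot_longer(c("prop_conclusive", "prop_null"),
                        names_to = "direction", values_to = "prop") |>
    dplyr::mutate(direction = dplyr::recode(
      .data$direction,
      prop_conclusive = paste0("BF10 > ", object$threshold),
      prop_null = paste0("BF10 < 1/", object$threshold)))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$n, y = .data$prop,
                                  colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "sample size", y = "fraction of replicates",
                  colour = NULL,
                  title = "Bayes-factor stability by sample size") +
    ggplot2::theme_minimal()
}

#' Plot per-feature LI distributions
#'
#' Histograms of the lateralisation index across participants, faceted
#' by tract and metric; negative values indicate leftward asymmetry.
#'
#' @param data A cohort table or [li_table()] output.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_li_distributions <- function(data, bins = 30) {
  if (!"li" %in% names(data)) data <- li_table(data)
  ggplot2::ggplot(dplyr::filter(data, !is.na(.data$li)),
                  ggplot2::aes(x = .data$li)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_grid(metric ~ tract) +
    ggplot2::labs(x = "lateralisation index", y = "participants") +
    ggplot2::theme_minimal()
}

#' Plot the variability-test family
#'
#' Observed VI per tract and metric with Bonferroni-significant tests
#' highlighted; negative VI means greater left-hemisphere variability.
#'
#' @param results Output of [vi_family_analysis()].
#' @return A ggplot object.
#' @export
plot_vi_family <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$tract, y = .data$vi,
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "grey70"),
                               na.value = "grey90",
                               name = "Bonferroni\nsignificant") +
    ggplot2::labs(x = NULL, y = "variability index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
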