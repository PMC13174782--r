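#' Tidy a Bayesian lateralisation fit
#'
#' @param x An `li_bf` object from [bf_li()].
#' @param ... Unused.
#' @return One-row tibble: posterior summary, Bayes factor, prior
#'   settings and the quadrature error estimate.
#' @export
tidy.li_bf <- function(x, ...) {
  tibble::tibble(
    n = x$n, est_mean = x$post_mean, est_error = x$post_sd,
    ci_low = x$ci95[1], ci_high = x$ci95[2],
    bf10 = x$bf10, log10_bf10 = x$log_bf10 / log(10),
    prior_scale = x$prior_scale, numerical_error = x$numerical_error)
}

#' @rdname tidy.li_bf
#' @export
glance.li_bf <- function(x, ...) {
  tibble::tibble(
    bf10 = x$bf10,
    evidence = dplyr::case_when(
      x$bf10 >= 100 ~ "extreme for lateralisation",
      x$bf10 >= 10 ~ "strong for lateralisation",
      x$bf10 >= 3 ~ "moderate for lateralisation",
      x$bf10 > 1 / 3 ~ "anecdotal",
      x$bf10 > 1 / 10 ~ "moderate for bilaterality",
      TRUE ~ "strong for bilaterality"),
    parameterisation = x$parameterisation,
    nodes = x$nodes)
}

#' Tidy a VI permutation test
#'
#' @param x A `vi_test` object from [permutation_test_vi()].
#' @param ... Unused.
#' @export
tidy.vi_test <- function(x, ...) {
  dplyr::bind_cols(
    x$observation,
    tibble::tibble(p_value = x$p_value, p_is_floor = x$p_is_floor,
                   n_perm = x$n_perm, significant = x$significant))
}

#' @rdname tidy.vi_test
#' @export
glance.vi_test <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, n_perm = x$n_perm,
                 alpha = x$alpha, significant = x$significant,
                 estimator = x$estimator)
}

#' Tidy a sample-size stability simulation
#'
#' `tidy()` summarises each sample size: the median and quartiles of
#' log10 BF10, the fraction of replicates with conclusive evidence for
#' lateralisation (`BF10 > threshold`) and for bilaterality
#' (`BF10 < 1/threshold`). `glance()` reports the smallest n, if any,
#' at which the conclusive fraction reaches 0.9.
#'
#' @param x An `li_stability` object.
#' @param ... Unused.
#' @export
tidy.li_stability <- function(x, ...) {
  thr <- log10(x$threshold)
  x$cells |>
    dplyr::group_by(n = .data$n) |>
    dplyr::summarise(
      median_log10_bf = median(.data$log10_bf10),
      q25_log10_bf = quantile(.data$log10_bf10, 0.25),
      q75_log10_bf = quantile(.data$log10_bf10, 0.75),
      prop_conclusive = mean(.data$log10_bf10 > thr),
      prop_null = mean(.data$log10_bf10 < -thr),
      .groups = "drop")
}

#' @rdname tidy.li_stability
#' @export
glance.li_stability <- function(x, ...) {
  s <- tidy(x)
  hit <- s$n[s$prop_conclusive >= 0.9]
  tibble::tibble(
    threshold = x$threshold, reps = x$reps, mode = x$mode,
    n_conclusive_090 = if (length(hit)) min(hit) else NA_integer_)
}

#' Tidy clusterability diagnostics
#'
#' @param x An `li_clusterability` object.
#' @param ... Unused.
#' @export
tidy.li_clusterability <- function(x, ...) {
  x$silhouette
}

#' @rdname tidy.li_clusterability
#' @export
glance.li_clusterability <- function(x, ...) {
  tibble::tibble(hopkins = x$hopkins,
                 silhouette_best = x$silhouette_best,
                 best_k = x$best_k, n = x$n)
}
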