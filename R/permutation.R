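#' One hemisphere-swap permutation draw
#'
#' Swaps each participant's left and right values independently with
#' probability 0.5 (pairing is never broken across participants) and
#' returns the VI of the permuted sample. Advances R's RNG; seed with
#' `set.seed()` for reproducibility.
#'
#' @inheritParams compute_vi
#' @return A single permuted VI.
#' @export
permute_vi_once <- function(left, right) {
  if (length(left) != length(right)) abort("left/right must be paired")
  if (length(left) < 2) abort("need at least 2 pairs to permute")
  drop(perm_vi_cpp(as.numeric(left), as.numeric(right), 1L))
}

#' Paired hemisphere-swap permutation test for the VI
#'
#' Monte-Carlo test of equal interhemispheric variability. The null
#' distribution is generated by swapping left and right within each
#' participant with 50% probability and recomputing the VI; the p-value
#' is the proportion of permuted VIs at least as extreme (in absolute
#' value, inclusive of ties) as the observed VI. When no permuted value
#' is as extreme, the p-value is reported at its floor `1 / n_perm` and
#' flagged with `p_is_floor`. The smoothed estimator
#' `(count + 1) / (n_perm + 1)` is available for conservative use.
#'
#' @inheritParams compute_vi
#' @param n_perm Number of permutations (default 100,000).
#' @param seed Integer seed; identical seed and inputs give a
#'   bit-identical result.
#' @param estimator `"raw"` proportion (default) or `"smoothed"`.
#' @param alpha Significance threshold recorded in the result (default
#'   the 24-test Bonferroni threshold, 0.05/24).
#' @return An object of class `vi_test`: the observed VI observation
#'   plus `p_value`, `p_is_floor`, `n_perm`, `null_quantiles`, `seed`,
#'   `alpha` and `significant`. Use [tidy()] for a one-row tibble.
#' @export
permutation_test_vi <- function(left, right, n_perm = 100000L, seed = NULL,
                                estimator = c("raw", "smoothed"),
                                alpha = bonferroni_alpha(0.05, 24L),
                                tract = NA_character_,
                                metric = NA_character_) {
  estimator <- match.arg(estimator)
  if (length(left) < 2) abort("need at least 2 pairs")
  if (n_perm < 1) abort("n_perm must be at least 1")
  obs <- compute_vi(left, right, tract = tract, metric = metric)

  draw <- function() perm_vi_cpp(as.numeric(left), as.numeric(right),
                                 as.integer(n_perm))
  null_vi <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  count <- sum(abs(null_vi) >= abs(obs$vi), na.rm = TRUE)
  if (estimator == "raw") {
    p_is_floor <- count == 0
    p <- max(count, 1L) / n_perm
  } else {
    p_is_floor <- FALSE
    p <- (count + 1) / (n_perm + 1)
  }

  structure(
    list(
      observation = obs,
      p_value = p,
      p_is_floor = p_is_floor,
      n_perm = as.integer(n_perm),
      estimator = estimator,
      null_quantiles = stats::quantile(
        null_vi, c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE),
      seed = seed,
      alpha = alpha,
      significant = p < alpha
    ),
    class = "vi_test"
  )
}

#' @exportS3Method base::print
print.vi_test <- function(x, ...) {
  o <- x$observation
  cat("Hemisphere-swap permutation test for the variability index\n")
  if (!is.na(o$tract)) cat("  tract x metric: ", o$tract, " x ", o$metric, "\n", sep = "")
  cat(sprintf("  VI = %.3f (MAD left %.4g, right %.4g; %d pairs)\n",
              o$vi, o$mad_left, o$mad_right, o$n_pairs))
  cat(sprintf("  p %s %.2g  (%d permutations%s)\n",
              if (x$p_is_floor) "<" else "=", x$p_value, x$n_perm,
              if (x$p_is_floor) ", floored" else ""))
  cat(sprintf("  %ssignificant at Bonferroni alpha = %.4g\n",
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Exact hemisphere-swap permutation p-value
#'
#' Enumerates all `2^n` within-participant swap patterns with equal
#' weight and returns the exact two-sided p-value
#' `#{|VI_perm| >= |VI_obs|} / 2^n`. Guarded at 16 pairs; beyond that
#' use the Monte-Carlo test.
#'
#' @inheritParams compute_vi
#' @return Exact p-value in (0, 1].
#' @export
exact_permutation_vi <- function(left, right) {
  if (length(left) != length(right)) abort("left/right must be paired")
  if (length(left) > 16) {
    abort("exact enumeration refuses more than 16 pairs (2^n patterns)")
  }
  obs <- vi_stat_cpp(as.numeric(left), as.numeric(right))
  if (is.na(obs)) abort("undefined variability index: both MADs are zero")
  null_vi <- exact_vi_cpp(as.numeric(left), as.numeric(right))
  mean(abs(null_vi) >= abs(obs), na.rm = TRUE)
}

#' Family of variability tests across tracts and metrics
#'
#' Runs the 21 tract-level VI permutation tests (7 tracts x 3 metrics)
#' plus the 3 hemisphere-averaged global tests, and applies the
#' Bonferroni correction for the 24-test family. Each test draws from
#' its own RNG substream derived deterministically from the master seed
#' and the (tract, metric) label, so results are independent of test
#' order. Tests with fewer than 2 complete pairs are reported with `NA`
#' p-values.
#'
#' @param data A cohort table.
#' @param n_perm Permutations per test.
#' @param seed Master seed.
#' @param family_alpha Family-wise alpha (default 0.05).
#' @param estimator Passed to [permutation_test_vi()].
#' @return Tibble with one row per test: `tract` (`"ALL"` for the
#'   hemisphere-averaged tests), `metric`, `n_pairs`, `mad_left`,
#'   `mad_right`, `vi`, `p_value`, `p_is_floor`, `n_perm`,
#'   `alpha_bonferroni`, `significant`.
#' @export
vi_family_analysis <- function(data, n_perm = 100000L, seed = 1L,
                               family_alpha = 0.05,
                               estimator = c("raw", "smoothed")) {
  estimator <- match.arg(estimator)
  data <- validate_cohort(data)
  alpha <- bonferroni_alpha(family_alpha, 24L)

  wide <- data |>
    tidyr::pivot_wider(names_from = "hemisphere", values_from = "value")

  one_test <- function(left, right, tract, metric) {
    complete <- !is.na(left) & !is.na(right)
    left <- left[complete]
    right <- right[complete]
    if (length(left) < 2) {
      warn(paste0("fewer than 2 complete pairs for ", tract, " x ", metric,
                  "; test reported as missing"))
      return(tibble::tibble(
        tract = tract, metric = metric, n_pairs = length(left),
        mad_left = NA_real_, mad_right = NA_real_, vi = NA_real_,
        p_value = NA_real_, p_is_floor = NA, n_perm = as.integer(n_perm),
        alpha_bonferroni = alpha, significant = NA))
    }
    res <- permutation_test_vi(
      left, right, n_perm = n_perm,
      seed = derive_seed(seed, c(tract, metric)),
      estimator = estimator, alpha = alpha, tract = tract, metric = metric)
    tibble::tibble(
      tract = tract, metric = metric, n_pairs = res$observation$n_pairs,
      mad_left = res$observation$mad_left,
      mad_right = res$observation$mad_right,
      vi = res$observation$vi, p_value = res$p_value,
      p_is_floor = res$p_is_floor, n_perm = res$n_perm,
      alpha_bonferroni = alpha, significant = res$significant)
  }

  tract_rows <- purrr::pmap(
    expand.grid(tract = .TRACTS, metric = .METRICS,
                stringsAsFactors = FALSE),
    function(tract, metric) {
      sub <- wide[wide$tract == tract & wide$metric == metric, ]
      one_test(sub$L, sub$R, tract, metric)
    })

  global_rows <- purrr::map(.METRICS, function(metric) {
    pairs <- tryCatch(hemisphere_average(data, metric),
                      error = function(e) NULL)
    if (is.null(pairs)) {
      return(one_test(numeric(0), numeric(0), "ALL", metric))
    }
    one_test(pairs$left, pairs$right, "ALL", metric)
  })

  dplyr::bind_rows(tract_rows, global_rows)
}
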