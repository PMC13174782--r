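#' Lateralisation index
#'
#' LI = (right - left) / (right + left) for a paired bilateral
#' measurement. Negative values indicate left lateralisation, positive
#' values right lateralisation, and values near zero a bilateral
#' distribution; the index is confined to \[-1, 1\], is antisymmetric
#' under swapping the hemispheres, and is invariant to a common positive
#' rescaling of both sides.
#'
#' @param left,right Non-negative measurement(s); vectors are paired
#'   elementwise.
#' @param on_zero What to do when `left + right == 0`: `"error"`
#'   (default, the pair is degenerate) or `"na"` (return `NA` with a
#'   warning, the pipeline's missing-data convention).
#' @return Numeric vector of LI values in \[-1, 1\].
#' @examples
#' compute_li(100, 150)  # 0.2, rightward
#' @export
compute_li <- function(left, right, on_zero = c("error", "na")) {
  on_zero <- match.arg(on_zero)
  if (any(left < 0, na.rm = TRUE) || any(right < 0, na.rm = TRUE)) {
    abort("left and right values must be non-negative")
  }
  denom <- left + right
  zero <- !is.na(denom) & denom == 0
  if (any(zero)) {
    if (on_zero == "error") {
      abort("undefined lateralisation index: left + right is zero")
    }
    warn("zero denominator in LI; reporting NA for the degenerate pair(s)")
  }
  out <- (right - left) / denom
  out[zero] <- NA_real_
  out
}

#' Median absolute deviation (raw)
#'
#' Median of absolute deviations from the sample median, with no
#' consistency constant: a robust dispersion measure that is
#' translation-invariant and scales linearly under positive scaling.
#' Even-length medians are the mean of the two central order statistics.
#'
#' @param x Numeric vector without missing values.
#' @return Non-negative scalar.
#' @export
compute_mad <- function(x) {
  if (length(x) < 1) abort("compute_mad() needs at least one value")
  if (anyNA(x)) abort("compute_mad() does not accept missing values")
  stats::mad(x, constant = 1)
}

#' Variability index
#'
#' VI = (MAD_right - MAD_left) / (MAD_right + MAD_left), where MAD is
#' the raw median absolute deviation of each hemisphere's values across
#' participants. The VI captures asymmetry in interindividual dispersion
#' rather than in magnitude: negative values mean the left hemisphere is
#' more variable across individuals, positive values the right, zero
#' equal variability. Swapping the two inputs flips the sign exactly.
#'
#' @param left,right Per-participant values for one tract x metric,
#'   restricted to participants with both hemispheres present.
#' @param tract,metric Optional labels carried into the result.
#' @param on_zero `"error"` (default) or `"na"` when both hemispheres
#'   have zero MAD.
#' @return One-row tibble: `tract`, `metric`, `mad_left`, `mad_right`,
#'   `vi`, `n_pairs`.
#' @export
compute_vi <- function(left, right, tract = NA_character_,
                       metric = NA_character_, on_zero = c("error", "na")) {
  on_zero <- match.arg(on_zero)
  if (!length(left) || !length(right)) abort("empty hemisphere sample")
  if (length(left) != length(right)) {
    abort("left and right must be paired (equal length)")
  }
  if (anyNA(left) || anyNA(right)) {
    abort("compute_vi() expects complete pairs; drop missing participants first")
  }
  ml <- compute_mad(left)
  mr <- compute_mad(right)
  denom <- ml + mr
  vi <- if (denom > 0) {
    (mr - ml) / denom
  } else if (on_zero == "error") {
    abort("undefined variability index: both hemispheres have zero MAD")
  } else {
    warn("zero MAD in both hemispheres; reporting NA for VI")
    NA_real_
  }
  tibble::tibble(tract = tract, metric = metric, mad_left = ml,
                 mad_right = mr, vi = vi, n_pairs = length(left))
}

#' Per-participant LI table
#'
#' Computes one lateralisation index per participant x tract x metric
#' wherever both hemispheres are present; pairs with a missing
#' hemisphere, or a zero denominator, yield `NA`.
#'
#' @param data A cohort table (see [validate_cohort()]).
#' @return Tibble with columns `participant_id`, `tract`, `metric`, `li`.
#' @export
li_table <- function(data) {
  data <- validate_cohort(data)
  wide <- data |>
    tidyr::pivot_wider(names_from = "hemisphere", values_from = "value")
  if (!all(c("L", "R") %in% names(wide))) {
    abort("cohort table must contain both hemispheres")
  }
  wide |>
    dplyr::mutate(
      li = dplyr::if_else(
        is.na(.data$L) | is.na(.data$R) | (.data$L + .data$R) == 0,
        NA_real_,
        (.data$R - .data$L) / (.data$R + .data$L)
      )
    ) |>
    dplyr::select("participant_id", "tract", "metric", "li") |>
    dplyr::arrange(.data$participant_id, .data$tract, .data$metric)
}

#' Participants x features LI matrix
#'
#' Reshapes the per-participant LI table into a wide matrix with one
#' column per tract x metric feature (up to 21), the input to the Bayes
#' tests and the manifold stage. Under the default listwise policy a
#' participant with any missing feature is dropped entirely (the
#' whole-cohort exclusion used for failed reconstructions); the pairwise
#' policy keeps all participants with `NA` cells.
#'
#' @param data A cohort table or a tibble already shaped like
#'   [li_table()] output.
#' @param exclusion `"listwise"` (default) or `"pairwise"`.
#' @return Wide tibble: `participant_id` plus `<tract>_<metric>`
#'   columns; dropped participants are recorded in the
#'   `"dropped_participants"` attribute.
#' @export
li_matrix <- function(data, exclusion = c("listwise", "pairwise")) {
  exclusion <- match.arg(exclusion)
  if (!"li" %in% names(data)) data <- li_table(data)
  wide <- data |>
    dplyr::mutate(feature = paste(.data$tract, .data$metric, sep = "_")) |>
    dplyr::select("participant_id", "feature", "li") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "li")
  dropped <- character(0)
  if (exclusion == "listwise") {
    complete <- stats::complete.cases(wide[-1])
    dropped <- wide$participant_id[!complete]
    wide <- wide[complete, , drop = FALSE]
  }
  if (!nrow(wide)) abort("all participants excluded; no complete LI profiles")
  attr(wide, "dropped_participants") <- dropped
  wide
}

#' Hemisphere-averaged paired values
#'
#' For each participant with all seven tracts reconstructed bilaterally,
#' the arithmetic mean of the tract values per hemisphere for one
#' metric. The output feeds the hemisphere-level (global) variability
#' tests.
#'
#' @param data A cohort table.
#' @param metric One of `"HMOA"`, `"TC"`, `"VC"`.
#' @return Tibble `participant_id`, `left`, `right` (complete
#'   participants only).
#' @export
hemisphere_average <- function(data, metric) {
  metric <- match.arg(metric, .METRICS)
  data <- validate_cohort(data)
  m <- metric
  out <- data |>
    dplyr::filter(.data$metric == m) |>
    dplyr::group_by(.data$participant_id, .data$hemisphere) |>
    dplyr::summarise(mean_value = mean(.data$value),
                     n_tracts = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "hemisphere",
                       values_from = c("mean_value", "n_tracts")) |>
    dplyr::filter(!is.na(.data$mean_value_L), !is.na(.data$mean_value_R),
                  .data$n_tracts_L == length(.TRACTS),
                  .data$n_tracts_R == length(.TRACTS)) |>
    dplyr::transmute(participant_id = .data$participant_id,
                     left = .data$mean_value_L, right = .data$mean_value_R)
  if (!nrow(out)) abort("no participants with all tracts present bilaterally")
  out
}

#' Reconstruction success percentage
#'
#' @param n_success Number of successful reconstructions.
#' @param n_participants Cohort size (> 0).
#' @return `100 * n_success / n_participants`.
#' @export
success_percentage <- function(n_success, n_participants) {
  if (any(n_participants <= 0)) abort("n_participants must be positive")
  if (any(n_success < 0) || any(n_success > n_participants)) {
    abort("n_success must lie in [0, n_participants]")
  }
  100 * n_success / n_participants
}

#' Bonferroni-corrected alpha
#'
#' Family-wise threshold `family_alpha / n_tests`. The default
#' variability-test family has 24 members (7 tracts x 3 metrics plus 3
#' hemisphere-averaged comparisons), giving 0.05 / 24 = 0.0021 (4 d.p.).
#'
#' @param family_alpha Family-wise error rate in (0, 1].
#' @param n_tests Number of tests (>= 1).
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_tests = 24L) {
  if (family_alpha <= 0 || family_alpha > 1) {
    abort("family_alpha must be in (0, 1]")
  }
  if (n_tests < 1) abort("n_tests must be at least 1")
  family_alpha / n_tests
}
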