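# Shared fixtures and independent oracles.

# Small complete cohort, built in code: values drawn once per call from
# the supplied seed.
make_cohort <- function(n = 10, seed = 1, tracts = tract_levels(),
                        metrics = metric_levels()) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      participant_id = sprintf("S%02d", seq_len(n)),
      tract = tracts, metric = metrics, hemisphere = c("L", "R"))
    grid$value <- exp(rnorm(nrow(grid), meanlog_for(grid$metric), 0.3))
    grid
  })
}

meanlog_for <- function(metric) {
  ifelse(metric == "HMOA", log(0.07),
         ifelse(metric == "TC", log(1000), log(5000)))
}

# Drop a whole tract x hemisphere for given participants (failed
# reconstruction semantics: all metrics go missing together).
fail_tract <- function(cohort, participants, tract, hemisphere = "L") {
  hit <- cohort$participant_id %in% participants &
    cohort$tract == tract & cohort$hemisphere == hemisphere
  cohort$value[hit] <- NA_real_
  cohort
}

# Brute-force median-of-absolute-deviations oracle, independent of
# stats::mad: medians via explicit order statistics.
mad_oracle <- function(x) {
  med <- function(v) {
    v <- sort(v)
    n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  med(abs(x - med(x)))
}

vi_oracle <- function(left, right) {
  (mad_oracle(right) - mad_oracle(left)) /
    (mad_oracle(right) + mad_oracle(left))
}

# Exhaustive swap-pattern enumeration in plain R (oracle for the C++
# enumeration and the Monte-Carlo test).
exact_p_oracle <- function(left, right) {
  n <- length(left)
  obs <- vi_oracle(left, right)
  vals <- vapply(0:(2^n - 1), function(mask) {
    sw <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    l <- ifelse(sw, right, left)
    r <- ifelse(sw, left, right)
    vi_oracle(l, r)
  }, numeric(1))
  mean(abs(vals) >= abs(obs))
}

# Standard JZS one-sample Bayes factor via single-variable quadrature
# on the effect size (noncentral-t marginal likelihood under a Jeffreys
# sigma prior).
jzs_oracle <- function(t_stat, n, scale = 0.707) {
  nu <- n - 1
  f <- function(d) suppressWarnings(   # dt(ncp) precision notes
    dt(t_stat, nu, ncp = d * sqrt(n)) * dcauchy(d, 0, scale))
  centre <- t_stat / sqrt(n)
  width <- 10 * sqrt(1 / n + centre^2 / (2 * n)) + 2
  num <- integrate(f, -Inf, centre - width, rel.tol = 1e-10)$value +
    integrate(f, centre - width, centre + width, rel.tol = 1e-10)$value +
    integrate(f, centre + width, Inf, rel.tol = 1e-10)$value
  num / dt(t_stat, nu)
}

rtrunc_norm <- function(n, mean, sd, lower = -1, upper = 1) {
  u <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(u, mean, sd)
}
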