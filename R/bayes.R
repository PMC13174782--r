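#' Bayesian one-sample test for a lateralisation index distribution
#'
#' Compares an intercept model (group mean mu free) against a null model
#' (mu fixed at 0) for a sample of LI values, the Bayesian analogue of a
#' one-sample t-test. The likelihood is Gaussian with unknown mean and
#' dispersion. Under the default `"mean"` parameterisation the prior on
#' mu is a Cauchy(0, `prior_scale`) truncated to the LI range \[-1, 1\]
#' (scale 0.707 is the conventional medium-effect default) and the
#' residual scale sigma carries a half-Student-t prior in both models.
#' The `"effect_size"` parameterisation places the Cauchy prior on the
#' standardised effect delta = mu / sigma with a Jeffreys prior on
#' sigma; with a wide truncation this reproduces the standard JZS
#' one-sample Bayes factor.
#'
#' Marginal likelihoods and the posterior of mu are computed by
#' deterministic tensor-product Gauss-Legendre quadrature (mu, or delta,
#' on panels covering the truncation interval; sigma on the log scale
#' over an adaptive range around the sample estimate), refined by
#' doubling the grid until successive log Bayes factors agree to `tol`;
#' the final disagreement is reported as `numerical_error`. Identical
#' inputs give identical results — no Monte Carlo is involved.
#'
#' @param x Numeric sample of LI values (length >= 3, not constant;
#'   under the `"mean"` parameterisation all values must lie inside the
#'   truncation interval).
#' @param prior_scale Cauchy scale of the location prior (default
#'   0.707).
#' @param truncation Length-2 interval restricting the location prior
#'   (default `c(-1, 1)`; widen it, e.g. `c(-1e6, 1e6)`, together with
#'   `parameterisation = "effect_size"` for the untruncated JZS limit).
#' @param sigma_prior List with `df` and `scale` of the half-Student-t
#'   prior on sigma (default df 3, scale 2.5); ignored under the
#'   Jeffreys sigma prior of the effect-size parameterisation.
#' @param parameterisation `"mean"` (default) or `"effect_size"`.
#' @param interval `"central"` (default) equal-tail 95% credible
#'   interval or `"hdi"` highest-density interval.
#' @param tol Relative agreement required between successive quadrature
#'   refinements of the log Bayes factor.
#' @param base_nodes Gauss-Legendre nodes per panel at the coarsest
#'   refinement level.
#' @return Object of class `li_bf` with elements `bf10`, `log_bf10`,
#'   `post_mean`, `post_sd`, `ci95`, `n`, `log_ml_h1`, `log_ml_h0`,
#'   `numerical_error` and the prior settings. [tidy()] and [glance()]
#'   methods are provided.
#' @export
bf_li <- function(x, prior_scale = 0.707, truncation = c(-1, 1),
                  sigma_prior = list(df = 3, scale = 2.5),
                  parameterisation = c("mean", "effect_size"),
                  interval = c("central", "hdi"),
                  tol = 1e-6, base_nodes = 48L) {
  parameterisation <- match.arg(parameterisation)
  interval <- match.arg(interval)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) abort("need at least 3 values")
  if (anyNA(x)) abort("missing values are not allowed; drop them first")
  if (sd(x) == 0) abort("degenerate likelihood: the sample is constant")
  if (prior_scale <= 0) abort("prior_scale must be positive")
  if (truncation[1] >= truncation[2]) abort("invalid truncation interval")
  if (parameterisation == "mean" &&
      (any(x < truncation[1]) || any(x > truncation[2]))) {
    abort("values outside the truncation interval; LI must lie in [-1, 1]")
  }

  fit <- NULL
  prev_log_bf <- NA_real_
  err <- Inf
  k <- as.integer(base_nodes)
  for (level in 1:4) {
    fit <- bf_li_quadrature(x, prior_scale, truncation, sigma_prior,
                            parameterisation, k)
    log_bf <- fit$log_ml_h1 - fit$log_ml_h0
    if (!is.na(prev_log_bf)) {
      err <- abs(log_bf - prev_log_bf)
      if (err <= tol * max(1, abs(log_bf))) break
    }
    prev_log_bf <- log_bf
    k <- k * 2L
  }

  ci <- if (interval == "central") {
    posterior_central_ci(fit$grid)
  } else {
    posterior_hdi(fit$grid)
  }

  structure(
    list(
      n = n,
      log_bf10 = fit$log_ml_h1 - fit$log_ml_h0,
      bf10 = exp(fit$log_ml_h1 - fit$log_ml_h0),
      post_mean = fit$post_mean,
      post_sd = fit$post_sd,
      ci95 = ci,
      log_ml_h1 = fit$log_ml_h1,
      log_ml_h0 = fit$log_ml_h0,
      numerical_error = err,
      prior_scale = prior_scale,
      truncation = truncation,
      sigma_prior = sigma_prior,
      parameterisation = parameterisation,
      interval_type = interval,
      nodes = k
    ),
    class = "li_bf"
  )
}

# One quadrature pass at k nodes per panel. Returns log marginal
# likelihoods for H1 and H0 and posterior summaries of the location.
bf_li_quadrature <- function(x, prior_scale, truncation, sigma_prior,
                             parameterisation, k) {
  n <- length(x)
  ybar <- mean(x)
  ss <- sum((x - ybar)^2)
  s1 <- sqrt(ss / (n - 1))              # sigma scale under H1
  s0 <- sqrt((ss + n * ybar^2) / n)     # sigma scale under H0

  # sigma integrated on the log scale over a range covering both models.
  u_lo <- log(min(s1, s0)) - 4
  u_hi <- log(max(s1, s0)) + 4
  gs <- pracma::gaussLegendre(k, u_lo, u_hi)
  sig <- exp(gs$x)
  log_sig_prior <- if (parameterisation == "effect_size") {
    -log(sig)  # Jeffreys, unnormalised; the constant cancels in the BF
  } else {
    log(2) - log(sigma_prior$scale) +
      dt(sig / sigma_prior$scale, df = sigma_prior$df, log = TRUE)
  }
  log_wsig <- log(gs$w) + log_sig_prior + gs$x  # + Jacobian d sigma/d log sigma

  loglik <- function(loc, sig) {
    # loc is mu ("mean") or delta ("effect_size", mean = delta * sigma)
    if (parameterisation == "effect_size") {
      -n / 2 * log(2 * pi) - n * log(sig) -
        (ss + n * (ybar - loc * sig)^2) / (2 * sig^2)
    } else {
      -n / 2 * log(2 * pi) - n * log(sig) -
        (ss + n * (ybar - loc)^2) / (2 * sig^2)
    }
  }

  # H0: location fixed at zero.
  log_ml_h0 <- logsumexp(loglik(0, sig) + log_wsig)

  # Location grid: a fine panel over the likelihood region flanked by
  # panels covering the rest of the (possibly truncated) prior support.
  if (parameterisation == "effect_size") {
    center <- ybar / s1
    half_width <- 15 * sqrt(1 / n + center^2 / (2 * n))
    lo <- max(truncation[1], min(0, center) - 3 * half_width)
    hi <- min(truncation[2], max(0, center) + 3 * half_width)
  } else {
    center <- ybar
    half_width <- 12 * max(s1, s0) / sqrt(n)
    lo <- truncation[1]
    hi <- truncation[2]
  }
  center <- min(max(center, lo), hi)
  # Panel breakpoints from both regions the integrand can concentrate
  # in: the likelihood region around the sample mean and the prior core
  # (quantiles of the Cauchy, which resolve arbitrarily narrow scales).
  qs <- qcauchy(c(0.001, 0.005, 0.025, 0.1, 0.25,
                  0.75, 0.9, 0.975, 0.995, 0.999), 0, prior_scale)
  brk <- sort(unique(pmin(pmax(
    c(lo, hi, center - half_width, center + half_width, qs), lo), hi)))
  brk <- brk[c(TRUE, diff(brk) > 1e-14)]
  if (length(brk) < 2) brk <- c(lo, hi)
  panels <- Map(c, brk[-length(brk)], brk[-1])

  nodes <- lapply(panels, function(p) pracma::gaussLegendre(k, p[1], p[2]))
  loc <- unlist(lapply(nodes, `[[`, "x"))
  wloc <- unlist(lapply(nodes, `[[`, "w"))

  # log f(loc) = log integral over sigma of lik * prior(sigma)
  ll_mat <- outer(loc, sig, loglik) +
    matrix(log_wsig, nrow = length(loc), ncol = k, byrow = TRUE)
  log_f <- row_logsumexp(ll_mat)

  trunc_mass <- pcauchy(truncation[2], 0, prior_scale) -
    pcauchy(truncation[1], 0, prior_scale)
  log_prior_loc <- dcauchy(loc, 0, prior_scale, log = TRUE) - log(trunc_mass)

  log_terms <- log_f + log_prior_loc + log(wloc)
  log_ml_h1 <- logsumexp(log_terms)

  # Posterior of the location on the same grid.
  w_post <- exp(log_terms - max(log_terms))
  w_post <- w_post / sum(w_post)
  post_mean_loc <- sum(w_post * loc)
  post_sd_loc <- sqrt(max(0, sum(w_post * loc^2) - post_mean_loc^2))

  if (parameterisation == "effect_size") {
    # Report the location on the mean scale (mu = delta * E[sigma | delta]);
    # posterior moments of mu via the joint grid.
    p_joint <- exp(ll_mat + log_prior_loc + log(wloc) -
                     max(ll_mat + log_prior_loc + log(wloc)))
    p_joint <- p_joint / sum(p_joint)
    mu_grid <- outer(loc, sig)
    post_mean <- sum(p_joint * mu_grid)
    post_sd <- sqrt(max(0, sum(p_joint * mu_grid^2) - post_mean^2))
    ord <- order(loc)
    grid <- list(loc = loc[ord], w = w_post[ord], wloc = wloc[ord],
                 scale = "effect")
  } else {
    post_mean <- post_mean_loc
    post_sd <- post_sd_loc
    ord <- order(loc)
    grid <- list(loc = loc[ord], w = w_post[ord], wloc = wloc[ord],
                 scale = "mean")
  }

  list(log_ml_h1 = log_ml_h1, log_ml_h0 = log_ml_h0,
       post_mean = post_mean, post_sd = post_sd, grid = grid)
}

posterior_central_ci <- function(grid) {
  cw <- cumsum(grid$w)
  # strictly increasing support for inversion
  keep <- c(TRUE, diff(cw) > 0)
  ci <- approx(cw[keep], grid$loc[keep], xout = c(0.025, 0.975),
               rule = 2, ties = "ordered")$y
  sort(ci)
}

posterior_hdi <- function(grid, level = 0.95) {
  dens <- grid$w / grid$wloc
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(grid$w[ord])
  inside <- ord[seq_len(which(cum >= level)[1])]
  range(grid$loc[inside])
}

#' @exportS3Method base::print
print.li_bf <- function(x, ...) {
  cat("Bayesian one-sample lateralisation test (quadrature)\n")
  cat(sprintf("  n = %d, prior Cauchy(0, %.3g) on [%g, %g] (%s)\n",
              x$n, x$prior_scale, x$truncation[1], x$truncation[2],
              x$parameterisation))
  cat(sprintf("  BF10 = %.4g (log BF = %.4g)\n", x$bf10, x$log_bf10))
  cat(sprintf("  posterior mean %.4f (sd %.4f), 95%% CI [%.3f, %.3f]\n",
              x$post_mean, x$post_sd, x$ci95[1], x$ci95[2]))
  cat(sprintf("  quadrature error on log BF: %.2g\n", x$numerical_error))
  invisible(x)
}

#' Monte-Carlo marginal-likelihood cross-check
#'
#' Estimates the same Bayes factor as [bf_li()] (default `"mean"`
#' parameterisation) by brute-force prior sampling: draws the location
#' from the truncated Cauchy prior and sigma from its half-Student-t
#' prior, and averages the likelihood. Slow and noisy by construction —
#' intended as an independent check of the quadrature, not for use.
#'
#' @inheritParams bf_li
#' @param n_draws Number of prior draws (default 1e6).
#' @param seed RNG seed.
#' @return List with `bf10`, `log_bf10`, `log_ml_h1`, `log_ml_h0`.
#' @export
bf_li_mc <- function(x, prior_scale = 0.707, truncation = c(-1, 1),
                     sigma_prior = list(df = 3, scale = 2.5),
                     n_draws = 1e6, seed = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  ybar <- mean(x)
  ss <- sum((x - ybar)^2)
  loglik <- function(mu, sig) {
    -n / 2 * log(2 * pi) - n * log(sig) -
      (ss + n * (ybar - mu)^2) / (2 * sig^2)
  }
  withr::with_seed(seed, {
    u <- runif(n_draws, pcauchy(truncation[1], 0, prior_scale),
               pcauchy(truncation[2], 0, prior_scale))
    mu <- qcauchy(u, 0, prior_scale)
    sig <- abs(rt(n_draws, df = sigma_prior$df)) * sigma_prior$scale
    log_ml_h1 <- logsumexp(loglik(mu, sig)) - log(n_draws)
    log_ml_h0 <- logsumexp(loglik(0, sig)) - log(n_draws)
  })
  list(bf10 = exp(log_ml_h1 - log_ml_h0),
       log_bf10 = log_ml_h1 - log_ml_h0,
       log_ml_h1 = log_ml_h1, log_ml_h0 = log_ml_h0)
}

#' Table of Bayesian lateralisation results per tract and metric
#'
#' Applies [bf_li()] to each tract x metric LI sample of a cohort,
#' mirroring the shape of a population-lateralisation results table:
#' posterior mean and SD of the group mean LI, 95% credible interval,
#' and the Bayes factor for lateralisation versus bilaterality.
#'
#' @param data A cohort table or a [li_table()]-shaped tibble.
#' @param ... Passed to [bf_li()].
#' @return Tibble: `tract`, `metric`, `n`, `est_mean`, `est_error`,
#'   `ci_low`, `ci_high`, `bf10`, `log10_bf10`.
#' @export
bayes_li <- function(data, ...) {
  if (!"li" %in% names(data)) data <- li_table(data)
  data |>
    dplyr::filter(!is.na(.data$li)) |>
    dplyr::group_by(.data$tract, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      fit <- bf_li(d$li, ...)
      tibble::tibble(
        n = fit$n, est_mean = fit$post_mean, est_error = fit$post_sd,
        ci_low = fit$ci95[1], ci_high = fit$ci95[2],
        bf10 = fit$bf10, log10_bf10 = fit$log_bf10 / log(10))
    }) |>
    dplyr::ungroup()
}

#' Prior-robustness sweep
#'
#' Re-runs the Bayes test across a grid of Cauchy prior widths
#' (conventionally 0.01 to 1) and reports whether the qualitative
#' direction of evidence — Bayes factor above or below 1, sign of the
#' posterior mean — is stable across the grid.
#'
#' @inheritParams bf_li
#' @param scales Numeric grid of prior scales (>= 2 values).
#' @param ... Passed to [bf_li()].
#' @return Tibble `prior_scale`, `bf10`, `log10_bf10`, `post_mean`,
#'   `post_sd`, with attributes `direction_stable` and `sign_stable`.
#' @export
prior_sweep <- function(x, scales = seq(0.01, 1, length.out = 25), ...) {
  if (length(scales) < 2) abort("need at least 2 prior scales")
  out <- purrr::map_dfr(scales, function(sc) {
    fit <- bf_li(x, prior_scale = sc, ...)
    tibble::tibble(prior_scale = sc, bf10 = fit$bf10,
                   log10_bf10 = fit$log_bf10 / log(10),
                   post_mean = fit$post_mean, post_sd = fit$post_sd)
  })
  attr(out, "direction_stable") <- length(unique(out$bf10 > 1)) == 1
  attr(out, "sign_stable") <- length(unique(sign(out$post_mean))) == 1
  out
}

#' Sensitivity of the Bayes factor to the sigma prior
#'
#' Companion sweep over the half-Student-t scale of the dispersion
#' prior, reported alongside the location-prior sweep because the
#' marginal likelihoods (though largely not their ratio) depend on it.
#'
#' @inheritParams bf_li
#' @param sigma_scales Grid of half-t scale values.
#' @param ... Passed to [bf_li()].
#' @return Tibble `sigma_scale`, `bf10`, `post_mean`.
#' @export
sigma_prior_sweep <- function(x, sigma_scales = c(0.5, 1, 2.5, 5, 10), ...) {
  purrr::map_dfr(sigma_scales, function(sc) {
    fit <- bf_li(x, sigma_prior = list(df = 3, scale = sc), ...)
    tibble::tibble(sigma_scale = sc, bf10 = fit$bf10,
                   post_mean = fit$post_mean)
  })
}

#' Frequentist one-sample cross-check
#'
#' Classical one-sample t-test of the LI sample against zero, used as
#' an internal consistency check on the Bayesian results (a large |t|
#' should accompany a Bayes factor favouring lateralisation).
#'
#' @param x Numeric LI sample (n >= 2, not constant).
#' @return Tibble `statistic`, `df`, `p_value`, `estimate`.
#' @export
t_test_li <- function(x) {
  if (length(x) < 2) abort("need at least 2 values")
  if (sd(x) == 0) abort("constant sample")
  ht <- t.test(x, mu = 0)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 estimate = unname(ht$estimate))
}
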