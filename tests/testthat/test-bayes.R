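test_that("a vanishing prior scale collapses H1 onto H0 (BF -> 1)", {
  withr::with_seed(2, x <- rnorm(40, 0.04, 0.2))
  fit <- bf_li(x, prior_scale = 1e-6)
  expect_equal(fit$bf10, 1, tolerance = 0.01)
  # even for a strongly asymmetric sample the residual Cauchy-tail
  # contribution vanishes linearly with the scale
  withr::with_seed(1, y <- rnorm(40, 0.15, 0.2))
  expect_equal(bf_li(y, prior_scale = 1e-9)$bf10, 1, tolerance = 0.01)
})

test_that("quadrature agrees with the prior-sampling Monte-Carlo estimator", {
  withr::with_seed(2, {
    for (i in 1:5) {
      n <- sample(20:60, 1)
      x <- rnorm(n, runif(1, -0.3, 0.3), runif(1, 0.1, 0.3))
      x <- pmin(pmax(x, -0.99), 0.99)
      fit <- bf_li(x)
      mc <- bf_li_mc(x, n_draws = 2e5, seed = i)
      expect_lt(abs(fit$log_bf10 - mc$log_bf10), 0.1)
    }
  })
})

test_that("a symmetric sample yields evidence for bilaterality", {
  withr::with_seed(3, x <- rnorm(60, 0, 0.2))
  x <- (x - mean(x)) / sd(x) * 0.2          # exactly mean 0
  fit <- bf_li(x)
  expect_lt(fit$bf10, 1)
  mc <- bf_li_mc(x, n_draws = 2e5, seed = 9)
  expect_lt(abs(fit$log_bf10 - mc$log_bf10), 0.1)
})

test_that("the untruncated effect-size configuration matches the JZS oracle", {
  withr::with_seed(4, {
    for (n in c(10, 50, 164)) {
      for (target_t in c(0, 1.5, 4, 6)) {
        base <- rnorm(n)
        base <- (base - mean(base)) / sd(base)
        x <- 0.2 * base + target_t * 0.2 / sqrt(n)  # sample t == target_t
        t_emp <- mean(x) / (sd(x) / sqrt(n))
        expect_equal(t_emp, target_t, tolerance = 1e-8)
        fit <- bf_li(x, parameterisation = "effect_size",
                     truncation = c(-1e6, 1e6))
        expect_equal(fit$bf10, jzs_oracle(t_emp, n), tolerance = 0.02)
      }
    }
  })
})

test_that("posterior summaries are coherent and evidence follows the mean", {
  withr::with_seed(5, {
    for (i in 1:6) {
      mu <- runif(1, -0.4, 0.4)
      x <- rtrunc_norm(80, mu, 0.2)
      fit <- bf_li(x)
      expect_lte(fit$ci95[1], fit$post_mean)
      expect_gte(fit$ci95[2], fit$post_mean)
      expect_gte(fit$post_mean, -1)
      expect_lte(fit$post_mean, 1)
      expect_equal(sign(fit$post_mean), sign(mean(x)))
      expect_equal(fit$bf10, exp(fit$log_ml_h1 - fit$log_ml_h0))
      # mirrored sample: symmetric prior => identical BF
      mir <- bf_li(-x)
      expect_equal(mir$log_bf10, fit$log_bf10, tolerance = 1e-6)
      expect_equal(mir$post_mean, -fit$post_mean, tolerance = 1e-6)
    }
  })
})

test_that("bf_li is deterministic and reports its numerical error", {
  withr::with_seed(6, x <- rtrunc_norm(50, 0.1, 0.25))
  f1 <- bf_li(x)
  f2 <- bf_li(x)
  expect_identical(f1$log_bf10, f2$log_bf10)
  expect_identical(f1$ci95, f2$ci95)
  expect_lt(f1$numerical_error, 1e-4)
  # hdi option returns a valid interval containing the posterior mean
  f3 <- bf_li(x, interval = "hdi")
  expect_lte(f3$ci95[1], f3$post_mean)
  expect_gte(f3$ci95[2], f3$post_mean)
})

test_that("bf_li validates its input", {
  expect_error(bf_li(c(0.1, 0.2)), "at least 3")
  expect_error(bf_li(rep(0.2, 10)), "constant")
  expect_error(bf_li(c(0.1, 0.5, 1.2)), "truncation")
  expect_error(bf_li(c(0.1, NA, 0.3, 0.2)), "missing")
})

test_that("bayes_li produces one posterior summary per feature", {
  coh <- make_cohort(n = 25, seed = 41)
  tab <- bayes_li(coh, base_nodes = 24L)
  expect_equal(nrow(tab), 21)
  expect_true(all(tab$ci_low <= tab$est_mean & tab$est_mean <= tab$ci_high))
  expect_true(all(tab$bf10 > 0))
  expect_equal(tab$log10_bf10, log10(tab$bf10))
})

test_that("prior sweep shows the Jeffreys-Lindley narrowing toward BF = 1", {
  withr::with_seed(7, x <- rtrunc_norm(60, 0.25, 0.2))
  sw <- prior_sweep(x, scales = c(0.01, 0.1, 0.3, 0.707, 1))
  expect_equal(nrow(sw), 5)
  # at a tiny prior scale the BF sits closer to 1 than at 0.707
  expect_lt(abs(log(sw$bf10[sw$prior_scale == 0.01])),
            abs(log(sw$bf10[sw$prior_scale == 0.707])))
  expect_true(attr(sw, "sign_stable"))
  # posterior mean stable within one posterior SD across the sweep
  expect_lt(diff(range(sw$post_mean)), max(sw$post_sd))
  sw2 <- prior_sweep(x, scales = c(0.01, 0.1, 0.3, 0.707, 1))
  expect_identical(sw$bf10, sw2$bf10)
})

test_that("sigma-prior sweep leaves the Bayes factor nearly unchanged", {
  withr::with_seed(8, x <- rtrunc_norm(50, 0.15, 0.2))
  sw <- sigma_prior_sweep(x, sigma_scales = c(1, 2.5, 5))
  expect_lt(diff(range(log(sw$bf10))), 0.2)
})

test_that("frequentist cross-check matches hand computation", {
  expect_equal(t_test_li(c(0.1, 0.2, 0.3))$statistic, 3.464, tolerance = 1e-3)
  sym <- c(-0.2, -0.1, 0, 0.1, 0.2)
  res <- t_test_li(sym)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  flip <- t_test_li(-c(0.1, 0.2, 0.3))
  expect_equal(flip$statistic, -3.464, tolerance = 1e-3)
  expect_equal(flip$p_value, t_test_li(c(0.1, 0.2, 0.3))$p_value)
  expect_error(t_test_li(rep(0.1, 5)), "constant")
  # consistency: larger |t| keeps company with a BF favouring H1
  withr::with_seed(9, strong <- rtrunc_norm(80, 0.3, 0.15))
  expect_gt(abs(t_test_li(strong)$statistic), 10)
  expect_gt(bf_li(strong)$bf10, 100)
})

test_that("tidy and glance summarise a fit", {
  withr::with_seed(10, x <- rtrunc_norm(40, 0.3, 0.2))
  fit <- bf_li(x)
  td <- tidy(fit)
  expect_equal(td$n, 40)
  expect_equal(td$bf10, fit$bf10)
  gl <- glance(fit)
  expect_match(gl$evidence, "lateralisation")
})
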