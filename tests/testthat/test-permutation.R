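test_that("permute_vi_once preserves pairing and realises both extremes", {
  left <- c(1, 2, 3, 4)
  right <- c(10, 20, 30, 40)
  obs <- compute_vi(left, right)$vi
  draws <- withr::with_seed(1, replicate(300, permute_vi_once(left, right)))
  # every permuted VI must equal the VI of some swap pattern
  patterns <- exact_vi_values <- vapply(0:15, function(mask) {
    sw <- bitwAnd(bitwShiftR(mask, 0:3), 1L) == 1L
    vi_oracle(ifelse(sw, right, left), ifelse(sw, left, right))
  }, numeric(1))
  expect_true(all(vapply(draws, function(d)
    any(abs(d - patterns) < 1e-12), logical(1))))
  # both the identity and the full swap (-obs) appear among the draws
  expect_true(any(abs(draws - obs) < 1e-12))
  expect_true(any(abs(draws + obs) < 1e-12))
  expect_error(permute_vi_once(1, 2), "at least 2")
})

test_that("permuted VI distribution is symmetric for exchangeable data", {
  withr::with_seed(3, {
    left <- rlnorm(40)
    right <- rlnorm(40)
    set.seed(99)
    draws <- replicate(4000, permute_vi_once(left, right))
  })
  expect_lt(abs(mean(draws)), 3 * sd(draws) / sqrt(length(draws)))
})

test_that("identical hemispheres give VI 0 and p = 1", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  res <- permutation_test_vi(x, x, n_perm = 500, seed = 1)
  expect_equal(res$observation$vi, 0)
  expect_equal(res$p_value, 1)   # every permuted |VI| >= 0
  expect_false(res$p_is_floor)
})

test_that("Monte-Carlo p is reproducible and respects the 1/n_perm floor", {
  # many pairs + a moderate dispersion ratio: the observed VI sits far
  # outside the tight permutation null, so no permuted value reaches it
  withr::with_seed(5, {
    left <- rnorm(100, sd = 1)
    right <- rnorm(100, sd = 4)
  })
  r1 <- permutation_test_vi(left, right, n_perm = 2000, seed = 42)
  r2 <- permutation_test_vi(left, right, n_perm = 2000, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$null_quantiles, r2$null_quantiles)
  expect_true(r1$p_is_floor)
  expect_equal(r1$p_value, 1 / 2000)
  r3 <- permutation_test_vi(left, right, n_perm = 2000, seed = 43,
                            estimator = "smoothed")
  expect_equal(r3$p_value, 1 / 2001, tolerance = 1e-12)
  expect_false(r3$p_is_floor)
})

test_that("exact enumeration matches hand computation and the R oracle", {
  # pairs {(1,3), (2,2)}: all 4 patterns give |VI| = |VI_obs|, so p = 1
  expect_equal(exact_permutation_vi(c(1, 2), c(3, 2)), 1)
  expect_equal(exact_permutation_vi(c(1, 2), c(3, 2)),
               exact_p_oracle(c(1, 2), c(3, 2)))
  expect_error(exact_permutation_vi(rnorm(17), rnorm(17)), "16")
  withr::with_seed(8, {
    for (n in c(3, 5, 8, 10)) {
      l <- rlnorm(n)
      r <- rlnorm(n)
      expect_equal(exact_permutation_vi(l, r), exact_p_oracle(l, r))
    }
  })
})

test_that("Monte-Carlo p converges to the exact enumeration p", {
  withr::with_seed(21, {
    for (n in c(2, 4, 7, 12)) {
      l <- rlnorm(n, sdlog = 0.5)
      r <- rlnorm(n, sdlog = 1)
      p_exact <- exact_permutation_vi(l, r)
      n_perm <- 4000
      p_mc <- permutation_test_vi(l, r, n_perm = n_perm, seed = n)$p_value
      se <- sqrt(p_exact * (1 - p_exact) / n_perm)
      expect_lt(abs(p_mc - p_exact), max(3 * se, 3 / n_perm))
    }
  })
})

test_that("relabelling hemispheres flips VI and leaves p unchanged", {
  withr::with_seed(13, {
    left <- rlnorm(30)
    right <- rlnorm(30, sdlog = 1.6)
  })
  a <- permutation_test_vi(left, right, n_perm = 3000, seed = 7)
  b <- permutation_test_vi(right, left, n_perm = 3000, seed = 7)
  expect_equal(a$observation$vi, -b$observation$vi)
  # swap symmetry of the null: |VI| distribution identical, so p equal
  expect_equal(a$p_value, b$p_value, tolerance = 0.02)
})

test_that("vi_family_analysis returns the 24-test family with substreams", {
  coh <- make_cohort(n = 12, seed = 30)
  fam <- vi_family_analysis(coh, n_perm = 300, seed = 10)
  expect_equal(nrow(fam), 24)
  expect_equal(sum(fam$tract == "ALL"), 3)
  expect_true(all(fam$alpha_bonferroni == 0.05 / 24))
  # deterministic under the same master seed
  fam2 <- vi_family_analysis(coh, n_perm = 300, seed = 10)
  expect_identical(fam$p_value, fam2$p_value)
  # a tract without complete pairs is reported missing, not dropped;
  # the 3 hemisphere-averaged tests also lose their complete cases
  coh2 <- fail_tract(coh, sprintf("S%02d", 1:12), "UF", "L")
  fam3 <- suppressWarnings(vi_family_analysis(coh2, n_perm = 300, seed = 10))
  expect_equal(sum(is.na(fam3$p_value)), 6)
  expect_equal(nrow(fam3), 24)
  w <- testthat::capture_warnings(
    vi_family_analysis(coh2, n_perm = 300, seed = 10))
  expect_match(w, "fewer than 2", all = FALSE)
})
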