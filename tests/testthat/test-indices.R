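test_that("compute_li matches the definition and its boundary behaviour", {
  expect_equal(compute_li(5, 5), 0)
  expect_equal(compute_li(2, 0), -1)
  expect_equal(compute_li(0, 2), 1)
  expect_equal(compute_li(100, 150), 0.2)
  expect_error(compute_li(0, 0), "undefined")
  expect_error(compute_li(-1, 2), "non-negative")
  expect_warning(out <- compute_li(c(1, 0), c(3, 0), on_zero = "na"),
                 "degenerate")
  expect_equal(out, c(0.5, NA))
})

test_that("LI is antisymmetric, scale-invariant and bounded", {
  withr::with_seed(42, {
    for (i in 1:50) {
      a <- runif(1, 0.001, 100)
      b <- runif(1, 0.001, 100)
      c_scale <- runif(1, 0.01, 50)
      li <- compute_li(a, b)
      expect_equal(li, -compute_li(b, a))
      expect_equal(li, compute_li(c_scale * a, c_scale * b))
      expect_lt(abs(li), 1)
    }
  })
})

test_that("compute_mad matches hand enumeration and the brute-force oracle", {
  expect_equal(compute_mad(c(7, 7, 7)), 0)
  expect_equal(compute_mad(c(1, 2, 3, 4, 5)), 1)
  # sorted deviations {0, 0, 0, 99}: even-length median is (0 + 0)/2
  expect_equal(compute_mad(c(1, 1, 1, 100)), 0)
  expect_equal(compute_mad(c(1, 1, 1, 100)), mad_oracle(c(1, 1, 1, 100)))
  expect_error(compute_mad(numeric(0)))
  withr::with_seed(7, {
    for (i in 1:200) {
      x <- rnorm(sample(1:25, 1), sd = runif(1, 0.1, 10))
      expect_equal(compute_mad(x), mad_oracle(x))
    }
  })
  # translation invariance and linear scaling
  x <- rlnorm(20)
  expect_equal(compute_mad(x + 3), compute_mad(x))
  expect_equal(compute_mad(2.5 * x), 2.5 * compute_mad(x))
})

test_that("compute_vi matches the definition, flips sign under swap, bounded", {
  same <- c(1, 5, 2, 8, 3)
  expect_equal(compute_vi(same, same)$vi, 0)
  # constructed MADs 1 and 2 -> VI = 1/3
  left <- c(1, 2, 3, 4, 5)        # MAD 1
  right <- c(2, 4, 6, 8, 10)      # MAD 2
  expect_equal(compute_vi(left, right)$vi, 1 / 3)
  expect_lt(compute_vi(c(0, 10, 20, 30), c(14, 15, 16, 17))$vi, 0)
  expect_error(compute_vi(c(1, 1), c(2, 2)), "zero MAD")
  withr::with_seed(11, {
    for (i in 1:30) {
      l <- rnorm(12, sd = runif(1, 0.5, 3))
      r <- rnorm(12, sd = runif(1, 0.5, 3))
      vi <- compute_vi(l, r)$vi
      expect_equal(vi, -compute_vi(r, l)$vi)
      expect_equal(vi, compute_vi(3 * l, 3 * r)$vi)
      expect_lte(abs(vi), 1)
      expect_equal(vi, vi_oracle(l, r))
    }
  })
})

test_that("hemisphere_average pools the seven tracts per participant", {
  coh <- make_cohort(n = 6, seed = 3)
  # deterministic check: participant S01, metric TC
  manual <- coh |>
    dplyr::filter(participant_id == "S01", metric == "TC") |>
    dplyr::group_by(hemisphere) |>
    dplyr::summarise(m = mean(value))
  got <- hemisphere_average(coh, "TC")
  expect_equal(got$left[got$participant_id == "S01"],
               manual$m[manual$hemisphere == "L"])
  expect_equal(got$right[got$participant_id == "S01"],
               manual$m[manual$hemisphere == "R"])
  # participants with a failed tract are excluded
  coh2 <- fail_tract(coh, "S02", "UF", "R")
  expect_false("S02" %in% hemisphere_average(coh2, "TC")$participant_id)
  # every tract failed -> no complete participants
  coh3 <- coh
  coh3$value[coh3$hemisphere == "L"] <- NA
  expect_error(hemisphere_average(coh3, "TC"), "no participants")
})

test_that("success_percentage and bonferroni_alpha match printed values", {
  expect_equal(success_percentage(172, 172), 100)
  expect_equal(round(success_percentage(164, 172), 2), 95.35)
  expect_equal(success_percentage(0, 10), 0)
  expect_error(success_percentage(1, 0))
  expect_equal(round(bonferroni_alpha(0.05, 24), 4), 0.0021)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(round(bonferroni_alpha(0.05, 21), 5), 0.00238)
  expect_error(bonferroni_alpha(0.05, 0))
})

test_that("li_table computes one LI per complete pair and NA otherwise", {
  coh <- make_cohort(n = 4, seed = 5)
  li <- li_table(coh)
  expect_equal(nrow(li), 4 * 21)
  expect_true(all(abs(li$li) <= 1))
  # spot-check one value against the raw table
  v <- coh |>
    dplyr::filter(participant_id == "S03", tract == "ILF", metric == "VC")
  expected <- (v$value[v$hemisphere == "R"] - v$value[v$hemisphere == "L"]) /
    sum(v$value)
  expect_equal(li$li[li$participant_id == "S03" & li$tract == "ILF" &
                       li$metric == "VC"], expected)
  li2 <- li_table(fail_tract(coh, "S01", "AFl", "L"))
  expect_true(all(is.na(
    li2$li[li2$participant_id == "S01" & li2$tract == "AFl"])))
})

test_that("li_matrix applies listwise and pairwise exclusion policies", {
  coh <- make_cohort(n = 10, seed = 6)
  m <- li_matrix(coh)
  expect_equal(dim(m), c(10, 22))
  coh2 <- fail_tract(coh, c("S02", "S07"), "FAT", "R")
  m_list <- li_matrix(coh2, exclusion = "listwise")
  expect_equal(nrow(m_list), 8)
  expect_setequal(attr(m_list, "dropped_participants"), c("S02", "S07"))
  m_pair <- li_matrix(coh2, exclusion = "pairwise")
  expect_equal(nrow(m_pair), 10)
  expect_equal(sum(is.na(m_pair$FAT_TC)), 2)
  # everyone failing -> error
  coh3 <- coh
  coh3$value[coh3$hemisphere == "R"] <- NA
  expect_error(li_matrix(coh3), "excluded")
})
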