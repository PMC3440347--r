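test_that("single-pass exclusion agrees with a brute-force filter", {
  set.seed(16)
  cases <- list(
    c(rep(1, 9), 100),                       # borderline outlier, oracle decides
    rlnorm(500, log(2000), 1),
    c(rep(5, 50)),                           # all equal: nothing excluded
    rnorm(200, 100, 30)
  )
  for (x in cases) {
    got <- pool_and_exclude(x, k = 3)
    want <- brute_force_exclude(x, k = 3)
    expect_equal(as.numeric(got), as.numeric(want))
    expect_equal(attr(got, "n_excluded"), length(x) - length(want))
  }
  expect_error(pool_and_exclude(c(1), k = 3), "at least 2")
  expect_error(pool_and_exclude(1:10, k = 0), "k must be")

  # pooling across replicate samples
  s1 <- receptor_sample(c(1, 2, 3))
  s2 <- receptor_sample(c(4, 5))
  expect_length(pool_and_exclude(list(s1, s2), k = 10), 5)
})

test_that("3-SD exclusion removes the expected normal tail mass", {
  set.seed(17)
  x <- rnorm(1e5)
  kept <- pool_and_exclude(x, k = 3)
  frac <- attr(kept, "n_excluded") / attr(kept, "n_total")
  expect_lt(abs(frac - 2 * pnorm(-3)), 0.001)  # 0.27% +/- 0.1% absolute

  # re-running on its own output may exclude a little more (single-pass
  # semantics); the fraction is logged, not zero by fiat
  again <- pool_and_exclude(as.numeric(kept), k = 3)
  expect_lt(attr(again, "n_excluded") / attr(again, "n_total"), 0.005)
})

test_that("distribution summary matches hand-computed moments and bins", {
  s <- summarize_distribution(c(1, 3), bin_width = 500)
  expect_equal(s$median, 2)
  expect_equal(s$cv_percent, 100 * sqrt(2) / 2, tolerance = 1e-12)  # sd(1,3)=sqrt 2
  expect_equal(s$skewness, 0)
  expect_equal(s$kurtosis, -2)   # two-point distribution, excess convention

  h <- summarize_distribution(c(100, 499, 500, 1200), bin_width = 500)$histogram
  expect_equal(h$count, c(2, 1, 1))
  expect_equal(h$bin_lo, c(0, 500, 1000))
  expect_equal(h$bin_hi, c(500, 1000, 1500))

  # raw-kurtosis convention differs by exactly 3
  expect_equal(summarize_distribution(c(1, 3), excess = FALSE)$kurtosis, 1)
  expect_error(summarize_distribution(c(1)), "at least 2")
  expect_warning(summarize_distribution(c(0, 0, 0)), "CV undefined")
})

test_that("moment estimators agree with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(18)
  x <- rlnorm(5000, log(1000), 0.8)
  s <- summarize_distribution(x)
  expect_equal(s$skewness, e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(s$kurtosis, e1071::kurtosis(x, type = 1), tolerance = 1e-12)
})

test_that("summary statistics recover closed-form log-normal CV and skewness", {
  set.seed(19)
  cv <- 0.5
  x <- rlnorm(1e5, log(2000), sqrt(log(1 + cv^2)))
  s <- summarize_distribution(x)
  expect_equal(s$cv_percent, 100 * cv, tolerance = 0.02)
  expect_equal(s$skewness, cv^3 + 3 * cv, tolerance = 0.1)
  expect_equal(s$median, 2000, tolerance = 0.02)
})

test_that("histogram counts plus exclusions conserve the pooled total", {
  set.seed(20)
  for (i in 1:5) {
    x <- rlnorm(2000, log(3000), runif(1, 0.5, 1.2))
    kept <- pool_and_exclude(x, k = 3)
    s <- summarize_distribution(kept)
    expect_equal(sum(s$histogram$count), s$n_cells)
    expect_equal(s$n_cells + s$n_excluded, length(x))
  }
})

test_that("K-S comparison behaves at the identity and disjoint extremes", {
  x <- c(1, 2, 3, 4, 5)
  same <- ks_two_sample(x, x)
  expect_equal(same$D, 0)
  expect_gt(same$p, 0.999)
  disjoint <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(disjoint$D, 1)
  expect_error(ks_two_sample(numeric(0), x), "at least 2")
  expect_equal(ks_two_sample(x, c(7, 8))$n_effective, 5 * 2 / 7)
})

test_that("K-S type-I error at alpha 0.001 stays below 0.5% over 1000 trials", {
  set.seed(22)
  rejections <- 0
  for (i in 1:1000) {
    a <- rnorm(100)
    b <- rnorm(100)
    if (ks_two_sample(a, b)$p < 0.001) rejections <- rejections + 1
  }
  expect_lte(rejections / 1000, 0.005)
})

test_that("pooled distributions of distinct receptor scenarios are separable", {
  set.seed(23)
  r1 <- draw_receptor_counts(scenario("c57bl6_gastrocnemius_vegfr1"), 1e4)
  r2 <- draw_receptor_counts(scenario("c57bl6_gastrocnemius_vegfr2"), 1e4)
  ks <- ks_two_sample(pool_and_exclude(r1), pool_and_exclude(r2))
  expect_lt(ks$p, 0.001)
})
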