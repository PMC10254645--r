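test_that("lognormal fitting handles point masses and recovers parameters", {
  fit <- fit_lognormal(rep(59, 40))
  expect_equal(fit$lognormal_median, 59)
  expect_equal(fit$lognormal_gsd, 1)

  withr::local_seed(71)
  d <- rlnorm(5000, log(59), log(1.4))
  fit <- fit_lognormal(d)
  expect_lt(abs(fit$lognormal_median - 59) / 59, 0.02)
  expect_lt(abs(fit$lognormal_gsd - 1.4) / 1.4, 0.02)
  expect_equal(sum(fit$histogram$count), 5000)

  expect_error(fit_lognormal(numeric(0)), "at least one")
  expect_error(fit_lognormal(c(10, -1)), "> 0")
})

test_that("median recovery is unbiased across sample sizes", {
  withr::local_seed(72)
  for (n in c(300, 1000, 5000)) {
    meds <- vapply(1:40, function(i) {
      fit_lognormal(rlnorm(n, log(59), log(1.3)))$lognormal_median
    }, numeric(1))
    expect_lt(abs(mean(meds) - 59) / 59, 0.02)
    # spread consistent with n: SE of the log-median is log(gsd)/sqrt(n)
    expect_lt(sd(log(meds)), 2 * log(1.3) / sqrt(n))
    expect_gt(sd(log(meds)), 0.5 * log(1.3) / sqrt(n))
  }
})

test_that("mixture selection separates unimodal from bimodal populations", {
  withr::local_seed(73)
  uni <- rlnorm(1000, log(59), log(1.3))
  fit <- fit_mixture(uni)
  expect_equal(fit$k, 1L)

  bi <- c(rlnorm(700, log(55), log(1.25)), rlnorm(300, log(140), log(1.25)))
  fit <- fit_mixture(bi)
  expect_equal(fit$k, 2L)
  expect_lt(abs(fit$components$median_nm[1] - 55) / 55, 0.10)
  expect_lt(abs(fit$components$median_nm[2] - 140) / 140, 0.10)
  expect_lt(abs(fit$components$weight[2] - 0.3), 0.05)

  small <- fit_mixture(rlnorm(20, log(59), log(1.3)))
  expect_equal(small$k, 1L)
  expect_match(small$note, "min_n")
})

test_that("mixture selection rates hold over repeated seeds", {
  withr::local_seed(74)
  k_uni <- vapply(1:100, function(i) {
    fit_mixture(rlnorm(300, log(59), log(1.3)))$k
  }, integer(1))
  k_bi <- vapply(1:100, function(i) {
    fit_mixture(c(rlnorm(210, log(55), log(1.25)),
                  rlnorm(90, log(140), log(1.25))))$k
  }, integer(1))
  expect_gte(mean(k_uni == 1L), 0.95)
  expect_gte(mean(k_bi == 2L), 0.95)
})

test_that("mixture fitting is deterministic", {
  withr::local_seed(75)
  d <- c(rlnorm(150, log(55), log(1.3)), rlnorm(150, log(150), log(1.25)))
  a <- fit_mixture(d)
  b <- fit_mixture(d)
  expect_identical(a$components, b$components)
  expect_identical(a$bic, b$bic)
})

test_that("identical fresh and aged samples classify as stable", {
  withr::local_seed(76)
  sim <- std_sim(lambda = 300, total_time = 20)
  res <- analyze_timescan(sim$scan, std_cal(1e6), std_flow(), std_eta())
  v <- classify_transformation(res, res)
  expect_identical(v$flags, "stable")
  expect_equal(v$evidence$median_shift, 0)
  expect_equal(v$evidence$count_ratio, 1)
})

test_that("classification rules fire on the designed evidence", {
  withr::local_seed(77)
  fresh_sim <- std_sim(lambda = 300, total_time = 20, dissolved = 0.05,
                       size_median = 55)
  aged_sim <- std_sim(lambda = 200, total_time = 20, dissolved = 0.05,
                      size_median = 55,
                      second_mode = list(median = 150, gsd = 1.25,
                                        fraction = 0.45))
  fresh <- analyze_timescan(fresh_sim$scan, std_cal(), std_flow(), std_eta())
  aged <- analyze_timescan(aged_sim$scan, std_cal(), std_flow(), std_eta())
  v <- classify_transformation(fresh, aged)
  expect_true("agglomeration" %in% v$flags)
  expect_gt(v$evidence$heavy_mode_weight, 0.10)
  expect_false("stable" %in% v$flags)
})

test_that("one-way ANOVA matches its classical oracles", {
  # identical groups: no between-group variance
  cmp <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(cmp$F_statistic, 0)
  expect_false(cmp$significant)

  # two groups: F equals the square of the pooled t statistic
  withr::local_seed(78)
  g1 <- rnorm(3, 10, 1)
  g2 <- rnorm(3, 12, 1)
  cmp <- compare_groups(list(a = g1, b = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(cmp$F_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(cmp$p_value, tt$p.value, tolerance = 1e-10)

  # extreme separation is significant
  cmp <- compare_groups(list(a = rnorm(5, 0, 1), b = rnorm(5, 20, 1)))
  expect_true(cmp$significant)

  expect_error(compare_groups(list(a = 1:3)), "two groups")
  expect_error(compare_groups(list(a = 1, b = 1:3)), "at least two values")
  expect_error(compare_groups(list(a = c(2, 2), b = c(2, 2))), "degenerate")
})

test_that("ANOVA p-values are calibrated under the null", {
  withr::local_seed(79)
  rejections <- vapply(1:1000, function(i) {
    compare_groups(list(a = rnorm(3), b = rnorm(3), c = rnorm(3)))$significant
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("filtration recovery reproduces the reported arithmetic", {
  expect_equal(recovery_after_filtration(2.5e7, 1.1e7), 44)
  expect_equal(recovery_after_filtration(2.1e7, 1.1e7), 52.38095,
               tolerance = 1e-6)
  expect_equal(recovery_after_filtration(3e6, 3e6), 100)
  expect_error(recovery_after_filtration(0, 1), "> 0")
})
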