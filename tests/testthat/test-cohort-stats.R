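# Validation statistics: CVs, normality, comparisons, correlation, stability.

test_that("coefficient of variation matches hand-computed values", {
  expect_equal(coefficient_of_variation(c(2, 2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), 100 * sqrt(2) / 2,
               tolerance = 1e-10) # 70.71%
  expect_error(coefficient_of_variation(5), class = "eak_domain_error")
  expect_error(coefficient_of_variation(c(-2, 0)), class = "eak_domain_error")
  set.seed(31)
  x <- rnorm(1e5, 2.51, 0.38)
  expect_equal(coefficient_of_variation(x), 100 * 0.38 / 2.51, tolerance = 0.02)
})

test_that("summary CVs reproduce the reference group table", {
  cv <- cv_from_summary(c(2.51, 1.73, 1.70, 1.76), c(0.38, 0.34, 0.17, 0.44))
  expect_equal(round(cv), c(15, 20, 10, 25))
  expect_equal(cv_from_summary(1.70, 0.17), 10)
  expect_equal(cv_from_summary(1.76, 0.44), 25)
  expect_equal(cv_from_summary(3, 0), 0)
  expect_error(cv_from_summary(0, 1), class = "eak_domain_error")
})

test_that("two-sample t-test handles identical and degenerate groups", {
  x <- c(1.2, 1.4, 1.6, 1.8)
  tt <- t_test_two_sample(x, x)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  z <- rep(2, 4)
  expect_equal(t_test_two_sample(z, z)$p_value, 1) # convention
  expect_error(t_test_two_sample(z, rep(3, 4)), class = "eak_degenerate_test")
  expect_error(t_test_two_sample(1, x), class = "eak_domain_error")
})

test_that("summary and raw-data pooled t-tests agree to numerical precision", {
  set.seed(32)
  for (i in 1:10) {
    a <- rnorm(sample(5:40, 1), mean = runif(1, 1, 3), sd = runif(1, 0.1, 0.6))
    b <- rnorm(sample(5:40, 1), mean = runif(1, 1, 3), sd = runif(1, 0.1, 0.6))
    t_raw <- t_test_two_sample(a, b)
    t_sum <- t_test_from_summary(length(a), mean(a), sd(a),
                                 length(b), mean(b), sd(b))
    expect_equal(t_sum$statistic, t_raw$statistic, tolerance = 1e-10)
    expect_equal(t_sum$df, t_raw$df)
    expect_equal(t_sum$p_value, t_raw$p_value, tolerance = 1e-10)
  }
})

test_that("published group summaries reproduce the reported significance pattern", {
  healthy_vs_cardio <- t_test_from_summary(51, 2.51, 0.38, 14, 1.73, 0.34)
  expect_equal(healthy_vs_cardio$statistic, 6.95, tolerance = 1e-3)
  expect_equal(healthy_vs_cardio$df, 63)
  expect_lt(healthy_vs_cardio$p_value, 1e-4)
  acs_vs_non <- t_test_from_summary(6, 1.70, 0.17, 8, 1.76, 0.44)
  expect_gt(acs_vs_non$p_value, 0.05)
  eq <- t_test_from_summary(10, 2, 0.3, 10, 2, 0.3)
  expect_equal(eq$p_value, 1)
})

test_that("pooled test flags strongly unequal spreads", {
  set.seed(33)
  a <- rnorm(30, 2, 0.1); b <- rnorm(30, 2, 0.9)
  tt <- t_test_two_sample(a, b)
  expect_match(tt$note, "welch")
  tw <- t_test_two_sample(a, b, variant = "welch")
  expect_equal(tw$method, "welch-t")
  expect_null(tw$note)
})

test_that("Shapiro-Wilk wrapper behaves on normal, skewed and constant input", {
  set.seed(34)
  norm_p <- shapiro_wilk(rnorm(51, 2.51, 0.38))
  expect_true(norm_p$statistic > 0 && norm_p$statistic <= 1)
  expect_gt(norm_p$p_value, 0.05)
  skew_p <- shapiro_wilk(rexp(100))
  expect_lt(skew_p$p_value, 0.05)
  expect_error(shapiro_wilk(rep(1, 10)), class = "eak_degenerate_test")
  expect_error(shapiro_wilk(c(1, 2)), class = "eak_domain_error")
})

test_that("Pearson correlation returns r as the statistic", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$statistic, 1.0)
  expect_equal(pearson_correlation(x, -x)$statistic, -1.0)
  expect_error(pearson_correlation(x, rep(2, 5)), class = "eak_degenerate_test")
  tab <- simulate_hematocrit_pairs(138, target_r = 0.26, seed = 11)
  r <- pearson_correlation(tab$hematocrit_pct, tab$eak5s)$statistic
  expect_lt(abs(r - 0.26), 0.25) # one draw; distribution centred on 0.26
})

test_that("p-values are invariant under a common unit change", {
  set.seed(35)
  a <- rnorm(20, 2.5, 0.4); b <- rnorm(15, 1.8, 0.3)
  p1 <- t_test_two_sample(a, b)$p_value
  p2 <- t_test_two_sample(1000 * a, 1000 * b)$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(shapiro_wilk(a)$p_value, shapiro_wilk(1000 * a)$p_value,
               tolerance = 1e-9)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(pearson_correlation(x, y)$p_value,
               pearson_correlation(10 * x, 10 * y)$p_value, tolerance = 1e-12)
})

test_that("stability analysis summarises repeats and compares blocks", {
  set.seed(36)
  m <- do.call(rbind, lapply(1:6, function(id) {
    data.frame(subject_id = id,
               minutes_after_draw = seq(0, 70, length.out = 10),
               eak5s = rnorm(10, 2.5, 2.5 * 0.026))
  }))
  res <- stability_analysis(m)
  expect_gt(res$cv_pct, 0.5); expect_lt(res$cv_pct, 6)
  expect_s3_class(res$first_vs_hour, "eak_test")
  expect_length(res$per_subject_cv, 6)
  # paired variant runs on the same data
  resp <- stability_analysis(m, paired = TRUE)
  expect_equal(resp$first_vs_hour$method, "paired-t-two-tailed")
})

test_that("a strong drift over the hour is detected", {
  set.seed(37)
  hits <- replicate(40, {
    minutes <- seq(0, 70, length.out = 12)
    drift <- 2.5 * (1 + 0.10 * minutes / 60) # +10% per hour
    m <- data.frame(minutes_after_draw = minutes,
                    eak5s = rnorm(12, drift, 2.5 * 0.026))
    stability_analysis(m)$first_vs_hour$p_value < 0.05
  })
  expect_gt(mean(hits), 0.6)
})

test_that("stability analysis requires a late measurement block", {
  m <- data.frame(minutes_after_draw = c(0, 5, 10, 20),
                  eak5s = c(2.5, 2.4, 2.55, 2.45))
  expect_error(stability_analysis(m), "insufficient time span",
               class = "eak_insufficient_span")
  expect_error(stability_analysis(m[1, ]), class = "eak_domain_error")
})
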