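# Segment extraction and parameter estimation.

test_that("extract_segment keeps the closed initial interval and metadata", {
  s <- mono_syl(duration = 20)
  seg <- extract_segment(s, 5)
  expect_equal(syl_duration(seg), 5)          # endpoint included
  expect_true(all(seg$times <= 5))
  expect_equal(length(seg$times), 501L)
  full <- extract_segment(s, 20)
  expect_equal(full$times, s$times)
  expect_error(extract_segment(s, 25), "only covers",
               class = "eak_segment_too_long")
  s2 <- syllectogram(seq(0, 5, 0.25), exp(-seq(0, 5, 0.25) / 3) + 1,
                     meta = list(tube = "A"))
  expect_equal(extract_segment(s2, 3)$meta$tube, "A")
})

test_that("noiseless mono-exponential curves are recovered exactly", {
  f <- fit_mono_exp(mono_syl(A0 = 1000, k = 0.3))
  expect_rel_equal(f$params$k, 0.3, 1e-6)
  expect_rel_equal(f$params$A0, 1000, 1e-6)
  expect_gte(f$r2, 1 - 1e-10)
  expect_true(f$converged)
  expect_equal(f$half_life, log(2) / f$params$k)
  # randomised oracle-equivalence sweep
  set.seed(21)
  for (i in 1:20) {
    A0 <- runif(1, 10, 5000); k <- runif(1, 0.1, 2)
    fi <- fit_mono_exp(mono_syl(A0 = A0, k = k, rate = 50))
    expect_rel_equal(fi$params$k, k, 1e-6)
    expect_gte(fi$r2, 1 - 1e-10)
  }
})

test_that("mono-exponential fit tolerates realistic noise", {
  f <- fit_mono_exp(noisy_mono_syl(A0 = 1000, k = 0.3, sd = 5, seed = 101))
  expect_rel_equal(f$params$k, 0.3, 0.02)
})

test_that("a non-decaying signal is rejected with a typed error", {
  t <- seq(0, 5, by = 0.1)
  flat <- syllectogram(t, rep(100, length(t)))
  expect_error(fit_mono_exp(flat), class = "eak_non_decaying")
  rising <- syllectogram(t, 100 * exp(0.2 * t))
  expect_error(fit_mono_exp(rising), class = "eak_non_decaying")
})

test_that("inverse-linear fit is exact on second-order data", {
  t <- seq(0, 5, by = 0.05)
  s <- syllectogram(t, eval_model1(model1_params(2, 0.5), t))
  f <- fit_inverse_linear(s)
  expect_equal(f$slope, 0.5, tolerance = 1e-10)
  expect_equal(f$intercept, 0.5, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_false(f$under_determined)
})

test_that("mono-exponential data favour the exponential over the inverse-linear fit", {
  s <- mono_syl(A0 = 1000, k = log(2) / 2.51)
  inv <- fit_inverse_linear(s)
  mono <- fit_mono_exp(s)
  expect_lt(inv$r2, 1)
  expect_lt(inv$r2, mono$r2)
})

test_that("intensity rescaling leaves rate, half-life and r2 unchanged", {
  s <- noisy_mono_syl(k = 0.28, seed = 7)
  f1 <- fit_mono_exp(s)
  for (c_scale in c(0.01, 3, 1e4)) {
    s2 <- syllectogram(s$times, c_scale * s$intensities)
    f2 <- fit_mono_exp(s2)
    expect_rel_equal(f2$params$k, f1$params$k, 1e-9)
    expect_rel_equal(f2$half_life, f1$half_life, 1e-9)
    expect_rel_equal(f2$r2, f1$r2, 1e-9)
    expect_rel_equal(f2$params$A0, c_scale * f1$params$A0, 1e-9)
  }
})

test_that("time rescaling rescales the rate inversely and the half-life directly", {
  s <- noisy_mono_syl(k = 0.35, seed = 8)
  f1 <- fit_mono_exp(s)
  for (c_scale in c(0.5, 2)) {
    s2 <- syllectogram(s$times * c_scale, s$intensities)
    f2 <- fit_mono_exp(s2)
    expect_rel_equal(f2$params$k, f1$params$k / c_scale, 1e-8)
    expect_rel_equal(f2$half_life, f1$half_life * c_scale, 1e-8)
  }
})

test_that("curve peeling recovers a well-separated bi-exponential exactly", {
  s <- simulate_syllectogram(bi_exp_params(3, 1, 1, 15, 0.5),
                             duration = 20, sampling_rate = 100)
  f <- fit_bi_exp(s)
  p <- f$params
  expect_rel_equal(p$I_f, 3, 0.01)
  expect_rel_equal(p$k_f, 1, 0.01)
  expect_rel_equal(p$I_s, 1, 0.01)
  expect_rel_equal(p$k_s, 15, 0.01)
  expect_rel_equal(p$I_0, 0.5, 0.01)
  expect_lt(p$k_f, p$k_s)
  expect_true(f$converged)
  expect_gte(f$r2, 1 - 1e-10)
})

test_that("bi-exponential fit degenerates gracefully to one component", {
  s <- simulate_syllectogram(bi_exp_params(3, 2, 0, 20, 0.5),
                             duration = 20, sampling_rate = 50)
  expect_warning(f <- fit_bi_exp(s), class = "eak_poorly_identifiable")
  expect_rel_equal(f$params$k_f, 2, 0.02)
  expect_lt(f$params$I_s, 0.05) # vanishing slow amplitude
  expect_true(f$clamped)
  expect_gte(f$r2, 1 - 1e-8)
})

test_that("equal time constants trigger the identifiability warning", {
  t <- seq(0, 20, by = 0.02)
  y <- 2 * exp(-t / 4) + 2 * exp(-t / 4) + 0.5
  s <- syllectogram(t, y)
  expect_warning(fit_bi_exp(s), class = "eak_poorly_identifiable")
})

test_that("bi-exponential fit requires a long recording", {
  expect_error(fit_bi_exp(mono_syl(duration = 5)),
               class = "eak_segment_too_short")
})

test_that("segment selection prefers the shortest of tied segments", {
  s <- mono_syl(A0 = 1000, k = 0.28, duration = 12)
  sel <- select_best_segment(s)
  r2 <- vapply(sel$fits, function(f) f$r2, numeric(1))
  expect_true(all(r2 >= 0.99))
  expect_equal(sel$best_duration, 1.5) # exact model: all tie, shortest wins
  expect_equal(sel$rule, "tie-shortest")
})

test_that("a strong slow component penalises the long segment", {
  s <- simulate_syllectogram(bi_exp_params(3, 1.2, 2, 12, 0.2),
                             duration = 12, sampling_rate = 100)
  sel <- select_best_segment(s)
  r2 <- vapply(sel$fits, function(f) f$r2, numeric(1))
  expect_lt(sel$best_duration, 10)
  expect_equal(unname(which.min(r2)), length(r2)) # 10 s fit explains least
})

test_that("segment selection demands coverage of the longest duration", {
  s6 <- mono_syl(duration = 6)
  sel <- select_best_segment(s6, durations = c(1.5, 3, 5))
  expect_true(sel$best_duration %in% c(1.5, 3, 5))
  expect_error(select_best_segment(s6), class = "eak_segment_too_long")
})

test_that("compute_eak5s is the 5 s fit and enforces its precondition", {
  f <- compute_eak5s(mono_syl(k = log(2), duration = 6))
  expect_equal(f$half_life, 1.0, tolerance = 1e-6)
  expect_equal(f$segment_duration, 5)
  expect_error(compute_eak5s(mono_syl(duration = 3)),
               class = "eak_segment_too_long")
})
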