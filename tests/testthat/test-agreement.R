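test_that("RMSE matches hand-computed values, absolute and quantile-relative", {
  # identical waveforms
  r0 <- cop_rmse(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$rmse_abs, 0)
  expect_equal(r0$rmse_rel, 0)
  # differences (3, 4) over N = 2: sqrt(25/2)
  r1 <- cop_rmse(c(3, 4), c(0, 0), reference = "sock")
  expect_equal(r1$rmse_abs, sqrt(12.5), tolerance = 1e-12)
  # uniform 1001-point ramp 0..100: the 2.5/97.5 quantiles are 2.5 and 97.5
  ramp <- seq(0, 100, length.out = 1001)
  r2 <- cop_rmse(ramp + 9.5, ramp)
  expect_equal(r2$delta_q, 95)
  expect_equal(r2$rmse_rel, 0.10, tolerance = 1e-12)
  # degenerate reference span: relative form flagged, absolute still returned
  r3 <- cop_rmse(c(1, 2, 3), c(5, 5, 5))
  expect_true(r3$degenerate)
  expect_true(is.na(r3$rmse_rel))
  expect_gt(r3$rmse_abs, 0)
  expect_error(cop_rmse(1, 1), "N >= 2")
})

test_that("RMSE decomposes into bias and population variance of the differences", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    s <- rnorm(n, sd = runif(1, 0.5, 3)) + runif(1, -5, 5)
    p <- rnorm(n, sd = runif(1, 0.5, 3))
    d <- s - p
    r <- cop_rmse(s, p)
    expect_equal(r$rmse_abs^2, mean(d)^2 + mean((d - mean(d))^2),
                 tolerance = 1e-10)
  }
})

test_that("Bland-Altman limits follow bias +/- 1.96 sample SD", {
  # constant difference: zero-width limits, nothing outside
  b0 <- bland_altman(c(3, 4, 5) + 2, c(3, 4, 5))
  expect_equal(b0$bias, 2)
  expect_equal(b0$sd_diff, 0)
  expect_equal(c(b0$loa_low, b0$loa_high), c(2, 2))
  expect_equal(b0$frac_outside, 0)
  # d = (-1, 1, -1, 1): sample SD sqrt(4/3), limits +/- 1.96*that
  b1 <- bland_altman(c(-1, 1, -1, 1), c(0, 0, 0, 0))
  expect_equal(b1$bias, 0)
  expect_equal(b1$sd_diff, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(b1$loa_high, 1.96 * sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(b1$loa_low, -b1$loa_high, tolerance = 1e-12)
  expect_error(bland_altman(c(1, 2), c(1, 2)), "N >= 3")
  expect_error(bland_altman(c(1, 2, 3), c(1, 2, 3), alpha = 1.2),
               "confidence level")
})

test_that("Lin's CCC reproduces analytic cases", {
  # perfect concordance
  c1 <- lin_ccc(c(-1, 0, 1), c(-1, 0, 1))
  expect_equal(c1$ccc, 1)
  expect_equal(c1$chi, 1)
  expect_equal(c1$rho, 1)
  # pure scale shift: rho = 1, omega = 0.5, chi = 0.8
  c2 <- lin_ccc(c(-1, 0, 1), c(-2, 0, 2))
  expect_equal(c2$rho, 1)
  expect_equal(c2$omega, 0.5)
  expect_equal(c2$v2, 0)
  expect_equal(c2$chi, 0.8)
  expect_equal(c2$ccc, 0.8, tolerance = 1e-12)
  # perfect anticorrelation with matched moments
  c3 <- lin_ccc(c(-1, 0, 1), c(1, 0, -1))
  expect_equal(c3$ccc, -1)
  # pure location shift: v^2 = 100 dominates
  c4 <- lin_ccc(c(0, 1, 2), c(10, 11, 12))
  expect_equal(c4$rho, 1)
  expect_equal(c4$v2, 100)
  expect_equal(c4$ccc, 2 / 102, tolerance = 1e-12)
  expect_error(lin_ccc(c(1, 1, 1), c(1, 2, 3)), "flat signal")
})

test_that("moments-form CCC equals the covariance form and respects |CCC| <= |rho|", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:300, 1)
    mu <- runif(2, -20, 20); sds <- runif(2, 0.2, 8)
    rho <- runif(1, -0.99, 0.99)
    z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    s <- mu[1] + sds[1] * z1
    p <- mu[2] + sds[2] * z2
    res <- lin_ccc(s, p)
    expect_equal(res$ccc, ccc_cov_form(s, p), tolerance = 1e-10)
    expect_lte(abs(res$ccc), abs(res$rho) + 1e-12)
    # swapping instruments leaves the CCC unchanged (omega -> 1/omega)
    expect_equal(lin_ccc(p, s)$ccc, res$ccc, tolerance = 1e-12)
  }
})

test_that("mean-centred pairs reduce the accuracy coefficient to its scale term", {
  set.seed(5)
  s <- rnorm(500, mean = 12, sd = 3)
  p <- 0.8 * s + rnorm(500)
  pair <- make_pair(s, p)
  res <- lin_ccc(pair)
  expect_lt(res$v2, 1e-15)
  expect_equal(res$chi, 2 / (res$omega + 1 / res$omega), tolerance = 1e-12)
  # and the Fisher variance collapses to its first term
  ci <- ccc_confidence_interval(res)
  first_term <- (1 - res$rho^2) * res$ccc^2 /
    ((1 - res$ccc^2) * res$rho^2) / (res$n - 2)
  expect_equal(ci$var_lambda, first_term, tolerance = 1e-10)
})

test_that("Fisher-transform CI has the closed form 1/(n-2) variance when CCC = rho", {
  pr <- make_exact_rho_pair(0.8, n = 102)
  res <- lin_ccc(pr$sock, pr$platform)
  expect_equal(res$ccc, 0.8, tolerance = 1e-10)
  expect_equal(res$omega, 1, tolerance = 1e-10)
  ci <- ccc_confidence_interval(res)
  expect_equal(ci$var_lambda, 1 / 100, tolerance = 1e-12)
  # tanh(atanh(0.8) -/+ 1.96 * 0.1)
  expect_equal(ci$ci_low, 0.7176, tolerance = 1e-3)
  expect_equal(ci$ci_high, 0.8603, tolerance = 1e-3)
})

test_that("CI edge cases: identical inputs degenerate, rho = 0 undefined, small n errors", {
  ident <- lin_ccc(c(1, 2, 3, 4), c(1, 2, 3, 4))
  ci <- ccc_confidence_interval(ident)
  expect_true(ci$degenerate)
  expect_equal(c(ci$ci_low, ci$ci_high), c(1, 1))

  res0 <- lin_ccc(c(-1, 0, 1, 0), c(0, 1, 0, -1))
  expect_equal(res0$rho, 0)
  ci0 <- ccc_confidence_interval(res0)
  expect_true(ci0$degenerate)
  expect_true(is.na(ci0$ci_low))

  small <- structure(list(ccc = 0.5, rho = 0.5, v2 = 0, n = 2L),
                     class = "ccc_result")
  expect_error(ccc_confidence_interval(small), "n > 2")
})

test_that("concordance classification follows both vocabularies, bounds inclusive below", {
  expect_identical(classify_concordance(0.96, "strict"), "substantial")
  expect_identical(classify_concordance(0.73, "loose"), "moderate")
  expect_identical(classify_concordance(0.92, "strict"), "moderate")
  expect_identical(classify_concordance(0.92, "loose"), "high")
  expect_identical(classify_concordance(0.995, "strict"), "almost perfect")
  expect_identical(classify_concordance(0.99, "strict"), "almost perfect")
  expect_identical(classify_concordance(0.35, "loose"), "poor")
  expect_identical(classify_concordance(c(0.95, 0.90, 0.89), "strict"),
                   c("substantial", "moderate", "poor"))
  expect_error(classify_concordance(1.2), "\\[-1, 1\\]")
})

test_that("segment-wise CCC separates a baseline shift from tracking quality", {
  set.seed(3)
  n <- 400; dt <- 0.02
  sig <- sin(2 * pi * 1 * dt * seq_len(n))
  shift <- c(rep(0, n / 2), rep(5, n / 2))
  pair <- make_pair(sig, sig + shift, dt = dt)
  whole <- lin_ccc(pair)$ccc
  seg <- ccc_by_segment(pair, breaks = dt * (n / 2 + 0.5))
  expect_equal(nrow(seg), 2L)
  expect_true(all(seg$ccc > 0.99))
  expect_lt(whole, min(seg$ccc))
})

test_that("the agreement fit bundles all metrics and flattens to one row", {
  set.seed(21)
  s <- sin(seq(0, 6 * pi, length.out = 300)) + rnorm(300, sd = 0.1)
  p <- sin(seq(0, 6 * pi, length.out = 300))
  fit <- cop_agreement(make_pair(s, p, axis = "y"))
  expect_s3_class(fit, "cop_agreement")
  expect_equal(fit$ccc$n, 300)
  expect_identical(fit$class_loose, classify_concordance(fit$ccc$ccc, "loose"))
  df <- as.data.frame(fit)
  expect_equal(nrow(df), 1L)
  expect_true(all(c("rmse_abs_mm", "bias_mm", "loa_low_mm", "ccc",
                    "ccc_ci_low", "class_strict", "class_loose") %in% names(df)))
  expect_true(df$ccc_ci_low <= df$ccc && df$ccc <= df$ccc_ci_high)
  expect_output(print(fit), "Lin's CCC")
})

test_that("agreement summaries count threshold fractions per axis and overall", {
  m <- data.frame(ccc = c(0.95, 0.50, 0.30), rmse_abs_mm = c(1, 2, 3),
                  axis = c("x", "x", "y"))
  s <- summarize_agreement(m)
  ov <- s[s$group == "overall", ]
  expect_equal(ov$frac_ccc_ge_090, 1 / 3)
  expect_equal(ov$frac_ccc_ge_060, 1 / 3)
  expect_equal(ov$frac_ccc_lt_040, 1 / 3)
  expect_equal(ov$ccc_min, 0.30)
  expect_equal(ov$ccc_max, 0.95)
  # per-axis counts partition the overall count
  expect_equal(sum(s$n[s$group != "overall"]), ov$n)
  # all perfect
  mp <- data.frame(ccc = rep(1, 4), rmse_abs_mm = rep(0, 4),
                   axis = rep(c("x", "y"), 2))
  expect_equal(summarize_agreement(mp)$frac_ccc_ge_090, rep(1, 3))
  expect_error(summarize_agreement(m[0, ]), "nonempty")
})
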