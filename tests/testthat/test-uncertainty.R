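test_that("duplicate CI propagation reproduces the hand-worked example", {
  # identical replicates: the combined interval equals each input's
  r <- propagate_duplicate_ci(10, c(8.04, 11.96), 10, c(8.04, 11.96))
  expect_equal(r$mean_thalf, 10)
  expect_equal(r$se_mean, 1)
  expect_equal(r$ci, c(8.04, 11.96))
  # hand evaluation with unequal replicates
  r2 <- propagate_duplicate_ci(10, c(8.04, 11.96), 20, c(16.08, 23.92))
  expect_equal(r2$mean_thalf, 15)
  expect_equal(r2$se_mean, sqrt(2.5), tolerance = 1e-12)
  expect_equal(r2$ci, c(11.900968, 18.099032), tolerance = 1e-6)
  # textbook variant divides the summed squared SEs by 4
  r3 <- propagate_duplicate_ci(10, c(8.04, 11.96), 20, c(16.08, 23.92),
                               textbook = TRUE)
  expect_equal(r3$se_mean, sqrt(5) / 2, tolerance = 1e-12)
})

test_that("duplicate CI propagation is symmetric and scales linearly", {
  a <- propagate_duplicate_ci(12, c(10, 14), 18, c(15, 21))
  b <- propagate_duplicate_ci(18, c(15, 21), 12, c(10, 14))
  expect_equal(a$ci, b$ci)
  expect_equal(a$mean_thalf, b$mean_thalf)
  wide <- propagate_duplicate_ci(12, c(8, 16), 18, c(12, 24))
  expect_equal(diff(wide$ci), 2 * diff(a$ci))
  expect_error(propagate_duplicate_ci(10, c(12, 8), 10, c(8, 12)),
               "high > low")
})

test_that("Monte Carlo keeps the requested fraction and is reproducible", {
  set <- reduced_m1_set(seed = 31)
  fit <- slk_fit(set)
  mc1 <- monte_carlo_ci(fit, n = 100, drop_frac = 0.05, seed = 77)
  expect_identical(mc1$n_kept, 95L)
  mc2 <- monte_carlo_ci(fit, n = 100, drop_frac = 0.05, seed = 77)
  expect_identical(mc1$samples, mc2$samples)
  expect_identical(mc1$ci, mc2$ci)
  expect_true(mc1$ci["low", "k_app"] <= median(mc1$samples[, "k_app"]))
  expect_true(mc1$ci["high", "k_app"] >= median(mc1$samples[, "k_app"]))
})

test_that("noise-free fits give degenerate Monte Carlo distributions", {
  set <- reduced_m1_set(noise_sd = 0)
  fit <- slk_fit(set)
  mc <- monte_carlo_ci(fit, n = 100, seed = 5)
  width <- diff(mc$ci[, "k_app"])
  expect_lt(width / coef(fit)["k_app"], 1e-4)
})

test_that("Monte Carlo parameter spread scales with the noise level", {
  spec1 <- fit_spec("model1", fixed = list(r_bound = 220),
                    s0_adjustable = FALSE)
  f_hi <- slk_fit(reduced_m1_set(noise_sd = 4, seed = 41), spec1)
  f_lo <- slk_fit(reduced_m1_set(noise_sd = 2, seed = 41), spec1)
  mc_hi <- monte_carlo_ci(f_hi, n = 200, seed = 8)
  mc_lo <- monte_carlo_ci(f_lo, n = 200, seed = 8)
  ratio <- mc_hi$sd[["k_app"]] / mc_lo$sd[["k_app"]]
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.8)
})

test_that("residual-resampling variant produces comparable spread", {
  set <- reduced_m1_set(seed = 51)
  fit <- slk_fit(set)
  mcp <- monte_carlo_ci(fit, n = 100, seed = 9)
  mcr <- monte_carlo_ci(fit, n = 100, seed = 9, method = "residual")
  expect_identical(mcr$n_kept, 95L)
  r <- mcr$sd[["k_app"]] / mcp$sd[["k_app"]]
  expect_gt(r, 0.5); expect_lt(r, 2)
})
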