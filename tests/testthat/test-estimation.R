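test_that("one-phase association recovers generating parameters", {
  tt <- seq(0, 600, 5)
  tr <- trace(tt, 20 + 200 * (1 - exp(-0.01 * tt)))
  f <- fit_one_phase(tr)
  expect_equal(f$Y0, 20, tolerance = 1e-3)
  expect_equal(f$Ymax, 220, tolerance = 1e-3)
  expect_equal(f$k, 0.01, tolerance = 1e-3)
  # half-life property: the fitted curve reaches the midpoint at ln(2)/k
  mid <- f$Y0 + (f$Ymax - f$Y0) * (1 - exp(-f$k * (log(2) / f$k)))
  expect_equal(mid, (f$Y0 + f$Ymax) / 2, tolerance = 1e-9)
  expect_error(fit_one_phase(trace(tt, rep(5, length(tt)))), "flat")
})

test_that("k_app conversion from pseudo-first-order rates", {
  expect_equal(kapp_from_rate(0.01, 50e-9), 2e5)
  expect_equal(kapp_from_rate(0, 1e-7), 0)
  expect_equal(kapp_from_rate(0.02, 2e-7), kapp_from_rate(0.02, 1e-7) / 2)
  expect_error(kapp_from_rate(0.01, 0), "> 0")
})

test_that("global model-1 fit recovers rate and substrate concentration", {
  set <- reduced_m1_set(noise_sd = 0)
  fit <- slk_fit(set)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["k_app"]), 1.51e5, tolerance = 1e-3)
  expect_equal(fit$adjusted_S0, 20e-9, tolerance = 1e-3)
  # deliberate 10% mis-quantification of the substrate is recovered
  set2 <- reduced_m1_set(seed = 5, true_substrate_conc = 22e-9)
  fit2 <- slk_fit(set2)
  expect_equal(fit2$adjusted_S0, 22e-9, tolerance = 0.02)
  expect_equal(unname(coef(fit2)["k_app"]), 1.51e5, tolerance = 0.05)
})

test_that("multi-start never reports a worse objective than one start", {
  set <- reduced_m1_set(seed = 9)
  f5 <- slk_fit(set, fit_spec("model1", n_starts = 5))
  f1 <- slk_fit(set, fit_spec("model1", n_starts = 1))
  expect_lte(f5$objective, f1$objective + 1e-9)
})

test_that("fixing a parameter at truth does not hurt the others", {
  set <- reduced_m1_set(seed = 13)
  free <- slk_fit(set)
  fixed <- slk_fit(set, fit_spec("model1", fixed = list(r_bound = 220)))
  err <- function(f) abs(unname(coef(f)["k_app"]) - 1.51e5) / 1.51e5
  expect_lte(err(fixed), err(free) + 0.02)
})

test_that("two-step global fit determines the composite rate best", {
  truth <- model2_params(2e7, 300, 200)       # k_app = 8e6, Kd = 15 uM
  set <- generate_traces(reduced_m2_template(), truth, sf_map(), seed = 2)
  pp <- trim_and_zero(average_replicates(set), 0)
  fit <- slk_fit(pp, fit_spec("model2", n_starts = 3))
  kap_true <- derive_kapp(truth)
  expect_equal(unname(coef(fit)["k_app"]), kap_true, tolerance = 0.1)
  # identifiability: in the second-order regime the composite k_app is
  # better determined (smaller relative sd) than k1 alone
  V <- vcov(fit)
  g <- c(1, -truth$k_minus1 / (truth$k2 + truth$k_minus1),
         truth$k_minus1 / (truth$k2 + truth$k_minus1))
  idx <- c("log10_k1", "log10_k_minus1", "log10_k2")
  sd_kapp <- sqrt(drop(t(g) %*% V[idx, idx] %*% g))
  expect_lt(sd_kapp, sqrt(V["log10_k1", "log10_k1"]))
})

test_that("competition fit recovers the competitor rate constant", {
  truth <- competition_params(kS_app = 3e6, kI_app = 1e6)
  map <- observable_map(60, 220, "PI")
  set <- generate_traces(design_template("competition", noise_sd = 0),
                         truth, map, seed = 4)
  fit <- fit_competition(set)
  expect_equal(unname(coef(fit)["kS_app"]), 3e6, tolerance = 0.01)
  expect_equal(unname(coef(fit)["kI_app"]), 1e6, tolerance = 0.01)
  # inert competitor: traces identical across competitor levels
  inert <- generate_traces(design_template("competition", noise_sd = 0),
                           competition_params(0, 1e6), map, seed = 4)
  sigs <- vapply(inert$traces[-1], function(tr) tr$signal,
                 numeric(nrow(inert$traces[[2]])))
  expect_lt(max(apply(sigs, 1, function(r) diff(range(r)))), 1e-9)
  # zero-competitor-only design degenerates to a reporter-rate fit
  keep <- vapply(set$traces, function(tr)
    attr(tr, "competitor_conc") == 0, logical(1))
  sub <- trace_set(set$traces[keep], design = "competition")
  fd <- suppressWarnings(fit_competition(sub))
  expect_equal(unname(coef(fd)["kI_app"]), 1e6, tolerance = 0.01)
  # free kI_app without a zero-competitor trace is under-identified
  nonzero <- trace_set(set$traces[!keep |
    vapply(set$traces, function(tr)
      attr(tr, "protein_conc") == 0, logical(1))], design = "competition")
  expect_error(fit_competition(nonzero), "zero-competitor")
})

test_that("sigmoidal in-cell fit recovers t_half with a sane CI", {
  tpl <- design_template("incell", noise_sd = 0)
  truth <- list(Y0 = 0.05, Ymax = 1, t_half = 20, H = 2)
  set <- generate_traces(tpl, truth, map = NULL, seed = 6)
  f <- fit_sigmoidal(set$traces[[1]])
  expect_equal(f$t_half, 20, tolerance = 5e-3)
  expect_equal(f$H, 2, tolerance = 0.01)
  expect_true(f$ci_thalf[1] <= f$t_half && f$t_half <= f$ci_thalf[2])
  # midpoint property of the Hill form, any slope
  yhat <- f$Y0 + (f$Ymax - f$Y0) / (1 + (f$t_half / f$t_half)^f$H)
  expect_equal(yhat, f$Y0 + (f$Ymax - f$Y0) / 2)
  # H = 1 is hyperbolic saturation
  x <- c(1, 5, 20, 60)
  hill1 <- 0.1 + 0.9 / (1 + 10 / x)
  hyper <- 0.1 + 0.9 * x / (10 + x)
  expect_equal(hill1, hyper)
  expect_error(fit_sigmoidal(trace(1:10, rep(1, 10))), "flat")
})

test_that("Gaussian profile fit returns the FWHM of the generator", {
  tpl <- design_template("line_profile", noise_sd = 0)
  f <- fit_gaussian_profile(generate_profile(108, tpl))
  expect_equal(f$fwhm, 108, tolerance = 1e-6)
  expect_equal(f$fwhm, f$omega * sqrt(2 * log(2)))
  # symmetric profile centers at the peak
  expect_equal(f$xc, 0, tolerance = 1e-6)
  expect_error(
    fit_gaussian_profile(generate_profile(108, tpl, amplitude = 0)),
    "degenerate")
})

test_that("extinction coefficient comes from the dilution-series slope", {
  conc <- c(7.5, 5, 3.33, 2.22) * 1e-6
  f <- fit_extinction(conc, 1e5 * 0.3 * conc, path_length = 0.3)
  expect_equal(f$epsilon, 1e5, tolerance = 1e-10)
  expect_equal(fit_extinction(c(1, 2, 3), 0.3 * c(1, 2, 3),
                              path_length = 0.3)$epsilon, 1)
  expect_warning(fz <- fit_extinction(conc, rep(0, 4)), "zero")
  expect_equal(fz$epsilon, 0)
  expect_error(fit_extinction(rep(1e-6, 4), 1:4), "variance")
})
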