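test_that("noiseless generation equals the observable-mapped model", {
  map <- default_fp_map()
  p <- model1_params(1.51e5)
  set <- generate_traces(reduced_m1_template(noise_sd = 0), p, map)
  tr <- set$traces[[3]]   # second protein level
  manual <- trajectory_to_signal(
    simulate_model1(p, initial_conditions(attr(tr, "protein_conc"), 20e-9),
                    tr$time), map)
  expect_equal(tr$signal, manual$signal)
  # zero-protein trace sits at the baseline exactly
  expect_true(all(set$traces[[1]]$signal == map$r_free))
})

test_that("generation is deterministic in the master seed", {
  a <- reduced_m1_set(seed = 10)
  b <- reduced_m1_set(seed = 10)
  d <- reduced_m1_set(seed = 11)
  expect_identical(lapply(a$traces, `[[`, "signal"),
                   lapply(b$traces, `[[`, "signal"))
  expect_false(identical(a$traces[[2]]$signal, d$traces[[2]]$signal))
})

test_that("per-trace noise substreams survive design growth", {
  tpl_small <- design_template("stoppedflow", replicates = 2L,
                               protein_concs = c(0, 1e-6),
                               grid = seq(0, 0.1, 0.01))
  tpl_big <- design_template("stoppedflow", replicates = 2L,
                             protein_concs = c(0, 1e-6, 2e-6),
                             grid = seq(0, 0.1, 0.01))
  truth <- model2_params(1e7, 100, 100)
  a <- generate_traces(tpl_small, truth, sf_map(), seed = 4)
  b <- generate_traces(tpl_big, truth, sf_map(), seed = 4)
  # traces present in both designs carry identical noise
  expect_identical(a$traces[[1]]$signal, b$traces[[1]]$signal)
  expect_identical(a$traces[[4]]$signal, b$traces[[4]]$signal)
})

test_that("empirical noise matches the requested level", {
  # full design: ~2200 residuals keep the sd estimate's own sampling
  # error well below the tolerance
  tpl <- design_template("platereader_std", noise_sd = 5)
  p <- model1_params(1.51e5)
  noisy <- generate_traces(tpl, p, default_fp_map(), seed = 20)
  clean <- generate_traces(design_template("platereader_std", noise_sd = 0),
                           p, default_fp_map(), seed = 20)
  resid <- unlist(Map(function(a, b) a$signal - b$signal,
                      noisy$traces, clean$traces))
  expect_equal(sd(resid), 5, tolerance = 0.05)
})

test_that("template/parameter mismatches are rejected", {
  expect_error(
    generate_traces(design_template("competition"),
                    model1_params(1e5), default_fp_map()),
    "requires competition")
  expect_error(
    generate_traces(design_template("platereader_std"),
                    competition_params(1e6, 1e6), default_fp_map()),
    "requires model1")
})

test_that("stopped-flow pretrigger samples are present then trimmed", {
  tpl <- design_template("stoppedflow", replicates = 1L,
                         protein_concs = c(0, 1e-6),
                         grid = seq(0, 0.05, 0.001))
  set <- generate_traces(tpl, model2_params(1e7, 100, 100), sf_map(),
                         seed = 2)
  expect_lt(set$traces[[2]]$time[1], 0)
  trimmed <- trim_and_zero(set$traces[[2]], 0)
  expect_identical(trimmed$time[1], 0)
  expect_lt(nrow(trimmed), nrow(set$traces[[2]]))
})

test_that("line profiles round-trip through the Gaussian fit", {
  tpl <- design_template("line_profile", noise_sd = 0)
  for (fwhm in c(60, 108, 200)) {
    f <- fit_gaussian_profile(generate_profile(fwhm, tpl))
    # 25 nm pixels adequately sample widths from ~60 nm FWHM up
    expect_equal(f$fwhm, fwhm, tolerance = 1e-4)
  }
})
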