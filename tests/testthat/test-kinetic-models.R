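test_that("closed-form second-order solution matches its analytic oracle", {
  p <- model1_params(1.51e5)
  ic <- initial_conditions(P0 = 100e-9, S0 = 20e-9)
  # frozen from the analytic formula evaluated independently
  expect_equal(model1_closed_form(p, ic, 100), 1.4915444454e-08,
               tolerance = 1e-9)
  expect_identical(model1_closed_form(p, ic, 0), 0)
  # P0 > S0: limiting substrate fully converted at long times
  expect_equal(model1_closed_form(p, ic, 1e9), 20e-9, tolerance = 1e-6)
})

test_that("numeric model-1 integration agrees with the closed form", {
  p <- model1_params(1.51e5)
  grid <- seq(0, 1800, by = 15)
  for (P0 in c(10e-9, 100e-9, 900e-9)) {
    ic <- initial_conditions(P0, 20e-9)
    num <- simulate_model1(p, ic, grid, method = "ode")$PS
    exact <- model1_closed_form(p, ic, grid)
    expect_lt(max_rel_dev(num, exact), 1e-8)
  }
  # equal-concentration branch against the integrator
  ic <- initial_conditions(50e-9, 50e-9)
  num <- simulate_model1(p, ic, grid, method = "ode")$PS
  expect_lt(max_rel_dev(model1_closed_form(p, ic, grid), num), 1e-8)
})

test_that("model 1 limits: no protein and pseudo-first-order excess", {
  grid <- seq(0, 60, by = 1)
  tr0 <- simulate_model1(model1_params(1e5), initial_conditions(0, 20e-9),
                         grid)
  expect_true(all(tr0$PS == 0))
  # excess protein: PS(t) = S0 (1 - exp(-k_app P0 t))
  tr <- simulate_model1(model1_params(1e5), initial_conditions(1e-6, 2e-9),
                        grid)
  expect_equal(tr$PS, 2e-9 * (1 - exp(-0.1 * grid)), tolerance = 1e-4)
})

test_that("model 2 conserves mass and is non-negative", {
  set.seed(42)
  grid <- seq(0, 2, by = 0.01)
  for (i in 1:5) {
    p <- model2_params(10^runif(1, 5, 8), 10^runif(1, -1, 3),
                       10^runif(1, -1, 3))
    ic <- initial_conditions(10^runif(1, -7, -5.5), 0.5e-6)
    tr <- simulate_model2(p, ic, grid)
    prot <- tr$P + tr$PSstar + tr$PS
    subs <- tr$S + tr$PSstar + tr$PS
    tol <- 1e-9 * max(ic$P0, ic$S0)
    expect_lt(max(abs(prot - ic$P0)), tol)
    expect_lt(max(abs(subs - ic$S0)), tol)
    expect_true(all(as.matrix(tr[-1]) > -1e-12))
    expect_true(all(diff(tr$PS) >= -1e-15))
  }
})

test_that("model 2 reduces to model 1 in its limiting regimes", {
  grid <- seq(0, 2, by = 0.002)
  # irreversible fast chemistry: k_minus1 = 0, k2 large -> direct with k1
  p2 <- model2_params(k1 = 1e6, k_minus1 = 0, k2 = 1e4)
  ic <- initial_conditions(1e-6, 0.5e-6)
  tot2 <- simulate_model2(p2, ic, grid)
  tot1 <- simulate_model1(model1_params(1e6), ic, grid)
  expect_lt(max_rel_dev(tot2$PSstar + tot2$PS, tot1$PS), 0.01)
  # second-order regime (concentrations << (k_minus1 + k2)/k1 = 25 uM):
  # total product tracks model 1 with the composite k_app within 2%
  p2 <- model2_params(k1 = 2e7, k_minus1 = 300, k2 = 200)
  kap <- derive_kapp(p2)
  ic2 <- initial_conditions(0.2e-6, 0.1e-6)   # 100x below (km1 + k2)/k1
  grid2 <- seq(0, 10, by = 0.01)
  tot2 <- simulate_model2(p2, ic2, grid2)
  tot1 <- simulate_model1(model1_params(kap), ic2, grid2)
  expect_lt(max_rel_dev(tot2$PSstar + tot2$PS, tot1$PS), 0.02)
})

test_that("competition scheme degenerates and symmetrizes correctly", {
  grid <- seq(0, 600, by = 5)
  # no competitor: reporter labeling identical to model 1
  pc <- competition_params(kS_app = 3e6, kI_app = 1e5)
  ic <- initial_conditions(100e-9, S0 = 0, I0 = 100e-9)
  tr <- simulate_competition(pc, ic, grid)
  m1 <- simulate_model1(model1_params(1e5),
                        initial_conditions(100e-9, 100e-9), grid)
  expect_lt(max_rel_dev(tr$PI, m1$PS), 1e-8)
  # equal rates and equal substrate/reporter: products split evenly
  pc <- competition_params(1e5, 1e5)
  ic <- initial_conditions(100e-9, 100e-9, 100e-9)
  tr <- simulate_competition(pc, ic, c(seq(0, 100, 10), 1e7))
  expect_equal(tail(tr$PS, 1), 50e-9, tolerance = 1e-6)
  expect_equal(tail(tr$PI, 1), 50e-9, tolerance = 1e-6)
  # no protein, no products
  tr0 <- simulate_competition(pc, initial_conditions(0, 1e-7, 1e-7), grid)
  expect_true(all(tr0$PS == 0) && all(tr0$PI == 0))
  # mass balances
  expect_lt(max(abs(tr$P + tr$PS + tr$PI - 100e-9)), 1e-16)
  expect_lt(max(abs(tr$I + tr$PI - 100e-9)), 1e-16)
})

test_that("derived rate constants follow the composite formulas", {
  expect_equal(derive_kapp(model2_params(5e6, 0, 77)), 5e6)
  expect_equal(derive_kapp(model2_params(1e7, 100, 100)), 5e6)
  expect_equal(derive_kapp(model2_params(1e7, 1e3, 1e9)), 1e7,
               tolerance = 1e-5)
  expect_error(derive_kapp(model2_params(1e7, 0, 0)), "undefined")
  expect_equal(derive_kd(model2_params(1e7, 0, 10)), 0)
  expect_equal(derive_kd(model2_params(1e7, 10, 10)), 1e-6)
  expect_error(derive_kd(model2_params(0, 10, 10)), "undefined")
  set.seed(7)
  for (i in 1:20) {
    k1 <- 10^runif(1, 2, 9); km1 <- 10^runif(1, -3, 4)
    k2 <- 10^runif(1, -3, 4)
    p <- model2_params(k1, km1, k2)
    expect_equal(derive_kd(p) * k1, km1)          # algebraic round trip
    expect_lte(derive_kapp(p), k1 * (1 + 1e-12))  # k_app never exceeds k1
  }
})

test_that("invalid inputs are rejected at the domain boundary", {
  expect_error(model1_params(-1), ">= 0")
  expect_error(model2_params(1e7, -1, 10), ">= 0")
  expect_error(initial_conditions(-1e-9, 0), ">= 0")
  expect_error(simulate_model1(model1_params(1e5),
                               initial_conditions(1e-7, 1e-8),
                               c(1, 2, 3)), "start at 0")
  expect_error(simulate_model1(model1_params(1e5),
                               initial_conditions(1e-7, 1e-8),
                               c(0, 2, 2)), "strictly increasing")
})
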