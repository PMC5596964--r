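test_that("thermal energy constant matches the kcal convention", {
  expect_equal(folding_constants()$RT, 0.591828, tolerance = 1e-10)
  expect_equal(folding_constants(310)$RT, 1.986e-3 * 310)
  expect_error(folding_constants(-1))
})

test_that("mean residue ellipticity normalisation", {
  expect_identical(mre_from_ellipticity(0, 0.2, 25e-6, 74), 0)
  # direct hand evaluation: 100 * 0.01 / (0.2 * 25e-6 * 73)
  expect_equal(mre_from_ellipticity(0.01, 0.2, 25e-6, 74),
               2739.72602739726, tolerance = 1e-12)
  # doubling concentration halves the value
  expect_equal(mre_from_ellipticity(0.01, 0.2, 50e-6, 74),
               mre_from_ellipticity(0.01, 0.2, 25e-6, 74) / 2)
  expect_error(mre_from_ellipticity(1, 0, 25e-6, 74), "path length")
  expect_error(mre_from_ellipticity(1, 0.2, -1, 74), "concentration")
  expect_error(mre_from_ellipticity(1, 0.2, 25e-6, 1), "residue")
})

test_that("fraction unfolded is 0.5 at the midpoint and logistic in x", {
  for (m in c(0.5, 1.54, 3)) for (D50 in c(1, 2.2, 5)) {
    expect_identical(fraction_unfolded(D50, m, D50), 0.5)
  }
  # hand evaluation at x = 0 for the CCL11 parameters
  E0 <- exp(1.54 * (0 - 2.20) / RT)
  expect_equal(fraction_unfolded(0, 1.54, 2.20), E0 / (1 + E0),
               tolerance = 1e-12)
  expect_gt(fraction_unfolded(4.5, 1.54, 2.20), 0.99)  # fully denatured
  x <- seq(0, 8, by = 0.1)
  expect_true(all(diff(fraction_unfolded(x, 1.54, 2.20)) > 0))
  expect_error(fraction_unfolded(1, -0.5, 2))
})

test_that("two-state titration model evaluates correctly", {
  flat <- two_state_fit(1, 0, 3, 0, m = 1, D50 = 2)
  expect_equal(eval_two_state_titration(2, flat), 2)  # midpoint average
  # native limit at x -> 0 with a stable protein
  stable <- two_state_fit(10, -0.5, 20, 0, m = 3, D50 = 5)
  expect_equal(eval_two_state_titration(0, stable), 10, tolerance = 1e-8)
  # midpoint with sloping baselines, hand value (95.6 + 202.2) / 2
  f <- two_state_fit(100, -2, 200, 1, m = 1.54, D50 = 2.20)
  expect_equal(eval_two_state_titration(2.20, f), 148.9, tolerance = 1e-12)
  # monotone when baselines are flat and a_D > a_N
  y <- eval_two_state_titration(seq(0, 8, 0.2), flat)
  expect_true(all(diff(y) > 0))
})

test_that("chevron equation: water limit, hand value, limb limits", {
  p <- phase_params(kf0 = 15.9, mf = 0.3, ku0 = 2.7, mu = 0.4)
  expect_equal(chevron_rate(0, p), 15.9 + 2.7)
  # hand evaluation at 2 M with the published fast-phase values
  expect_equal(chevron_rate(2, p),
               15.9 * exp(-0.6 / RT) + 2.7 * exp(0.8 / RT),
               tolerance = 1e-12)
  # pure folding limb decreases monotonically
  pf <- phase_params(kf0 = 10, mf = 0.5, ku0 = 1e-12, mu = 0.3)
  expect_true(all(diff(chevron_rate(seq(0, 4, 0.2), pf)) < 0))
})

test_that("log chevron rate is convex in denaturant", {
  set.seed(11)
  for (i in 1:20) {
    p <- phase_params(kf0 = 10^runif(1, -1, 2), mf = runif(1, 0, 1),
                      ku0 = 10^runif(1, -2, 1), mu = runif(1, 0, 1))
    x <- seq(0, 7, length.out = 41)
    lk <- log(chevron_rate(x, p))
    # chord test on consecutive triples
    mid <- (lk[-c(40, 41)] + lk[-c(1, 2)]) / 2
    expect_true(all(mid - lk[2:40] >= -1e-12))
  }
})

test_that("free energy from rates: sign, antisymmetry, hand values", {
  expect_equal(delta_g_from_rates(3, 3), 0)
  expect_equal(delta_g_from_rates(1, exp(1)), RT)
  expect_equal(delta_g_from_rates(15.9, 2.7), -1.0493508954580,
               tolerance = 1e-10)
  set.seed(2)
  for (i in 1:10) {
    kf <- 10^runif(1, -2, 2); ku <- 10^runif(1, -2, 2)
    expect_equal(delta_g_from_rates(kf, ku), -delta_g_from_rates(ku, kf))
  }
  expect_error(delta_g_from_rates(-1, 2))
  expect_error(delta_g_from_rates(1, 0))
})

test_that("midpoint from stability and m-value", {
  expect_equal(d50_from_dg_m(0, 1.5), 0)
  expect_error(d50_from_dg_m(3, 0))
  # round trip through dG = m * D50
  for (D50 in c(0.5, 2.2, 4.96)) {
    m <- 1.3
    expect_equal(d50_from_dg_m(m * D50, m), D50)
  }
})

test_that("equilibrium m-value adds the kinetic magnitudes", {
  expect_equal(m_eq_from_kinetic(0, 0), 0)
  expect_equal(m_eq_from_kinetic(0.25, 0.42), 0.67)
  expect_error(m_eq_from_kinetic(-0.1, 0.4))
})

test_that("chevron minimum matches numerical minimisation", {
  # symmetric case: minimum at zero
  ps <- phase_params(kf0 = 5, mf = 0.4, ku0 = 5, mu = 0.4)
  expect_equal(chevron_minimum(ps)$denaturant, 0, tolerance = 1e-12)
  # numeric oracle for the published fast-phase parameters
  p <- ccl11$phases$fast
  num <- stats::optimize(function(x) chevron_rate(x, p),
                         interval = c(0, 8), tol = 1e-10)
  cm <- chevron_minimum(p)
  expect_equal(cm$denaturant, num$minimum, tolerance = 1e-6)
  expect_equal(cm$rate, num$objective, tolerance = 1e-9)
  expect_false(cm$boundary)
  # raising ku0 moves the minimum to lower denaturant
  p2 <- phase_params(kf0 = p$kf0, mf = p$mf, ku0 = p$ku0 * 3, mu = p$mu)
  expect_lt(chevron_minimum(p2)$denaturant, cm$denaturant)
  # no interior minimum without both m-values
  pb <- phase_params(kf0 = 5, mf = 0, ku0 = 1, mu = 0.4)
  expect_true(chevron_minimum(pb)$boundary)
})

test_that("domain types validate their invariants", {
  expect_error(titration_curve(c(1, 2, 3), c(1, 2, 3)), "at least 8")
  expect_error(titration_curve(seq(8, 1), rnorm(8)), "increasing")
  expect_error(titration_curve(seq(-1, 6), rnorm(8)), ">= 0")
  f <- two_state_fit(1, 0, 2, 0, m = 1.54, D50 = 2.2)
  expect_equal(f$dG, 1.54 * 2.2, tolerance = 1e-12)
  expect_error(two_state_fit(1, 0, 2, 0, m = -1, D50 = 2))
  expect_error(two_state_fit(1, 0, 2, 0, m = 1, D50 = 0))
  expect_error(phase_params(-1, 0.3, 2, 0.4))
  expect_error(phase_params(1, -0.3, 2, 0.4), "magnitude")
  expect_error(exponential_fit(2, c(1, 1), c(2, -1), 0, 0))
  # rates are sorted descending on construction
  ef <- exponential_fit(2, c(0.2, 0.8), c(0.5, 10), 1, 0)
  expect_equal(ef$rates, c(10, 0.5))
  expect_equal(ef$amplitudes, c(0.8, 0.2))
  expect_error(chevron_dataset(1, 2, "medium"), "fast")
  tr <- kinetic_trace(c(0.001, 0.002, 0.01, 0.1), rep(1, 4), 2)
  expect_equal(tr$excluded, c(TRUE, TRUE, FALSE, FALSE))
})
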