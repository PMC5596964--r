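test_that("rate matrix conserves probability and carries the water rates", {
  sc <- toy_scheme()
  Q0 <- rate_matrix(sc, 0)
  expect_equal(Q0["I", "U"], 10)
  expect_equal(Q0["U", "I"], 1)
  expect_equal(Q0["N", "I"], 1)
  expect_equal(Q0["I", "N"], 0.05)
  off <- three_state_scheme(10, 0.5, 1, 0.3, 1, 0.4, 0.05, 0.4,
                            topology = "off_pathway")
  Qo <- rate_matrix(off, 0)
  expect_equal(Qo["N", "U"], 1)   # step 2 connects U and N directly
  expect_equal(Qo["N", "I"], 0)   # no I-N edge off-pathway
  set.seed(21)
  for (i in 1:15) {
    Q <- rate_matrix(random_scheme(), runif(1, 0, 7))
    expect_equal(colSums(Q), c(U = 0, I = 0, N = 0), tolerance = 1e-12)
    expect_true(all(Q[row(Q) != col(Q)] >= 0))
  }
})

test_that("equilibrium populations match the rate-matrix nullspace and Boltzmann weights", {
  set.seed(22)
  for (i in 1:10) {
    sc <- random_scheme()
    x <- runif(1, 0, 6)
    Q <- rate_matrix(sc, x)
    # brute-force nullspace: eigenvector of the ~0 eigenvalue
    es <- eigen(Q)
    j <- which.min(abs(Re(es$values)))
    v <- Re(es$vectors[, j]); v <- v / sum(v)
    p <- equilibrium_populations(sc, x)
    expect_equal(unname(p), v, tolerance = 1e-9)
    # Boltzmann weights from step free energies at this denaturant
    k <- c(k1 = sc$k1_0 * exp(-sc$m1 * x / RT),
           k1r = sc$k1r_0 * exp(sc$m1r * x / RT),
           k2 = sc$k2_0 * exp(-sc$m2 * x / RT),
           k2r = sc$k2r_0 * exp(sc$m2r * x / RT))
    dg1 <- -RT * log(k[["k1"]] / k[["k1r"]])
    dg2 <- -RT * log(k[["k2"]] / k[["k2r"]])
    w <- c(1, exp(-dg1 / RT), exp(-(dg1 + dg2) / RT))
    expect_equal(unname(p), w / sum(w), tolerance = 1e-9)
  }
})

test_that("relaxation rates are the nonzero eigenvalue magnitudes", {
  # two-state reduction: switching off the second step leaves k1 + k1r
  sc <- toy_scheme(k2_0 = 1e-9, k2r_0 = 1e-10)
  lam <- relaxation_rates(sc, 0)
  expect_equal(unname(lam["fast"]), 11, tolerance = 1e-6)
  expect_lt(lam["slow"], 1e-8)
  # reversible chains have a real spectrum
  set.seed(23)
  for (i in 1:10) {
    sc <- random_scheme()
    ev <- eigen(rate_matrix(sc, runif(1, 0, 6)), only.values = TRUE)$values
    expect_true(all(abs(Im(ev)) < 1e-9))
  }
})

test_that("eigen relaxation rates agree with an ODE-integration oracle", {
  set.seed(24)
  for (i in 1:5) {
    sc <- random_scheme()
    x <- runif(1, 0, 5)
    lam <- relaxation_rates(sc, x)
    if (lam["fast"] / lam["slow"] < 3) next  # near-degenerate: biexp unstable
    Q <- rate_matrix(sc, x)
    tg <- exp(seq(log(1e-4), log(20 / lam["slow"] * 0.2), length.out = 300))
    sol <- deSolve::ode(y = c(1, 0, 0), times = c(0, tg),
                        func = function(t, y, parms) list(as.numeric(Q %*% y)),
                        rtol = 1e-10, atol = 1e-12)
    sig <- drop(sol[-1, 2:4] %*% sc$fluor)
    tr <- kinetic_trace(tg, sig, x, dead_time = 0)
    fit <- fit_exponentials(tr, 2L)
    expect_equal(fit$rates[1], unname(lam["fast"]), tolerance = 0.01)
    expect_equal(fit$rates[2], unname(lam["slow"]), tolerance = 0.01)
  }
})

test_that("simulated traces conserve population and honour seeds", {
  sc <- toy_scheme(fluor = c(1, 1, 1))
  tr <- simulate_trace(sc, 1, "folding", noise = noise_spec(trace_sd = 0))
  expect_equal(tr$signal, rep(1, length(tr$time)), tolerance = 1e-9)
  # two-state limit: single exponential with rate k1(x) + k1r(x)
  sc2 <- toy_scheme(k2_0 = 1e-12, k2r_0 = 1e-12, fluor = c(1, 0, 0))
  x <- 1.5
  k1 <- sc2$k1_0 * exp(-sc2$m1 * x / RT)
  k1r <- sc2$k1r_0 * exp(sc2$m1r * x / RT)
  tr2 <- simulate_trace(sc2, x, "folding", noise = noise_spec(trace_sd = 0))
  peq <- k1r / (k1 + k1r)
  expect_equal(tr2$signal, peq + (1 - peq) * exp(-(k1 + k1r) * tr2$time),
               tolerance = 1e-6)
  # determinism under a fixed seed
  a <- simulate_trace(sc, 1, "folding", noise = noise_spec(seed = 7))
  b <- simulate_trace(sc, 1, "folding", noise = noise_spec(seed = 7))
  expect_identical(a$signal, b$signal)
  c2 <- simulate_trace(sc, 1, "folding", noise = noise_spec(seed = 8))
  expect_false(identical(a$signal, c2$signal))
  expect_error(simulate_trace(sc, 1, "folding", t_grid = numeric(0)))
  # pre-equilibration option changes the initial condition (equilibrium in
  # water is mostly native, unlike the pure-U folding default)
  sc3 <- toy_scheme()
  pre <- simulate_trace(sc3, 1, "folding", noise = noise_spec(trace_sd = 0),
                        premix = 0)
  std <- simulate_trace(sc3, 1, "folding", noise = noise_spec(trace_sd = 0))
  expect_false(isTRUE(all.equal(pre$signal[1], std$signal[1])))
})

test_that("destabilised intermediates lose the slow phase amplitude", {
  # I far above both U and N: step 1 strongly unfavourable, step 2 fast
  sc <- three_state_scheme(k1_0 = 1, m1 = 0.3, k1r_0 = 150, m1r = 0.3,
                           k2_0 = 400, m2 = 0.3, k2r_0 = 0.02, m2r = 0.3)
  # modal decomposition of the observable: the fast mode carries < 5%
  Q <- rate_matrix(sc, 0.5)
  es <- eigen(Q)
  co <- solve(es$vectors, c(1, 0, 0))
  contrib <- abs(Re(vapply(1:3, function(j)
    sum(sc$fluor * es$vectors[, j]) * co[j], complex(1))))
  ord <- order(abs(Re(es$values)))          # null, slow, fast
  expect_lt(contrib[ord[3]] / sum(contrib[ord[2:3]]), 0.05)
  # and phase-count selection sees a single phase
  tr <- simulate_trace(sc, 0.5, "folding",
                       noise = noise_spec(trace_sd = 0.005, seed = 1))
  expect_equal(select_phase_count(tr)$n_phases, 1L)
})

test_that("simulated titrations follow the two-state curve", {
  cv <- simulate_titration(3.39, 1.54, noise = noise_spec(titration_sd = 0))
  f <- two_state_fit(100, -2, 200, 1, m = 1.54, D50 = 3.39 / 1.54)
  expect_equal(cv$signal, eval_two_state_titration(cv$denaturant, f),
               tolerance = 1e-12)
  # midpoint of the noise-free CCL11 preset curve sits at 2.20 M
  flat <- simulate_titration(1.54 * 2.2, 1.54, baselines = c(1, 0, 3, 0),
                             grid = c(seq(0, 2, 0.4), 2.2, seq(2.6, 8, 0.4)),
                             noise = noise_spec(titration_sd = 0))
  expect_equal(flat$signal[flat$denaturant == 2.2], 2, tolerance = 1e-12)
  a <- simulate_titration(3.39, 1.54, noise = noise_spec(seed = 5))
  b <- simulate_titration(3.39, 1.54, noise = noise_spec(seed = 5))
  expect_identical(a$signal, b$signal)
})

test_that("simulated chevrons reproduce the rate laws", {
  p <- ccl11$phases$fast
  grid <- seq(0, 3.5, length.out = 12)
  ch <- simulate_chevron(p, grid, noise_spec(rate_rel_sd = 0))
  expect_equal(log(ch$points$rate), log(chevron_rate(grid, p)),
               tolerance = 1e-12)
  expect_true(all(ch$points$phase == "fast"))
  # scheme input gives both eigen branches
  sc <- toy_scheme()
  ch2 <- simulate_chevron(sc, c(1, 3), noise_spec(rate_rel_sd = 0))
  lam1 <- relaxation_rates(sc, 1)
  expect_equal(sort(ch2$points$rate[ch2$points$denaturant == 1]),
               sort(unname(lam1)), tolerance = 1e-9)
  a <- simulate_chevron(p, grid, noise_spec(seed = 3))
  b <- simulate_chevron(p, grid, noise_spec(seed = 3))
  expect_identical(a$points$rate, b$points$rate)
})

test_that("scheme free energies are additive", {
  set.seed(25)
  for (i in 1:10) {
    sc <- random_scheme()
    fe <- scheme_free_energies(sc)
    expect_equal(fe$total, fe$step1 + fe$step2, tolerance = 1e-12)
    # -RT log of the product of equilibrium constants equals the sum
    K <- (sc$k1_0 / sc$k1r_0) * (sc$k2_0 / sc$k2r_0)
    expect_equal(fe$total, -RT * log(K), tolerance = 1e-9)
    expect_equal(fe$m_total, sc$m1 + sc$m1r + sc$m2 + sc$m2r)
  }
})

test_that("presets carry the published parameter sets", {
  expect_equal(ccl11$equilibrium[c("dG", "m", "D50")],
               list(dG = 3.39, m = 1.54, D50 = 2.20))
  expect_equal(ccl24$equilibrium[c("dG", "m", "D50")],
               list(dG = 5.90, m = 1.19, D50 = 4.96))
  f <- ccl11$phases$fast
  expect_equal(c(f$kf0, f$mf, f$ku0, f$mu), c(15.9, 0.3, 2.7, 0.4))
  s <- ccl11$phases$slow
  expect_equal(c(s$kf0, s$mf, s$ku0, s$mu), c(2.4, 0.4, 0.1, 0.5))
  expect_equal(c(ccl24$phases$fast$kf0, ccl24$phases$fast$mf,
                 ccl24$phases$fast$ku0, ccl24$phases$fast$mu),
               c(17.4, 0.2, 0.1, 0.5))
  expect_null(ccl24$phases$slow)
  # the CCL24 stand-in slow step closes the thermodynamic cycle
  fe <- scheme_free_energies(ccl24$scheme)
  expect_equal(abs(fe$total), 5.90, tolerance = 1e-9)
})
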