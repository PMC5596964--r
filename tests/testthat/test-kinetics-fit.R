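tg <- exp(seq(log(1e-3), log(50), length.out = 200))

test_that("exponential fits recover closed-form traces", {
  y1 <- 3 + 1.5 * exp(-5 * tg)
  f1 <- fit_exponentials(kinetic_trace(tg, y1, 1), 1L)
  expect_equal(f1$rates, 5, tolerance = 1e-8)
  expect_equal(f1$amplitudes, 1.5, tolerance = 1e-6)
  expect_equal(f1$offset, 3, tolerance = 1e-8)

  y2 <- 1 + 0.5 * exp(-10 * tg) + 0.5 * exp(-0.5 * tg)
  f2 <- fit_exponentials(kinetic_trace(tg, y2, 1), 2L)
  expect_equal(f2$rates, c(10, 0.5), tolerance = 1e-6)
  expect_equal(f2$amplitudes, c(0.5, 0.5), tolerance = 1e-5)
})

test_that("amplitudes are extrapolated to the moment of mixing", {
  # all points before 3.4 ms are excluded, yet the amplitude refers to t = 0
  y <- 2 + 0.8 * exp(-20 * tg)
  f <- fit_exponentials(kinetic_trace(tg, y, 1), 1L)
  expect_equal(f$amplitudes, 0.8, tolerance = 1e-6)
})

test_that("three-state traces yield the eigen relaxation rates", {
  sc <- ccl11$scheme
  tr <- simulate_trace(sc, 1.5, "folding", noise = noise_spec(trace_sd = 0))
  f <- fit_exponentials(tr, 2L)
  lam <- relaxation_rates(sc, 1.5)
  expect_equal(f$rates[1], unname(lam["fast"]), tolerance = 0.01)
  expect_equal(f$rates[2], unname(lam["slow"]), tolerance = 0.01)
})

test_that("constant signals are flagged as no relaxation", {
  f <- fit_exponentials(kinetic_trace(tg, rep(2, 200), 1), 1L)
  expect_true("no relaxation" %in% f$flags)
})

test_that("points inside the dead time never influence the fit", {
  y <- 1 + exp(-8 * tg)
  base <- fit_exponentials(kinetic_trace(tg, y, 1), 1L)
  # fabricate wild points below 3.4 ms
  t_pre <- c(0.0005, 0.001, 0.002)
  tr2 <- kinetic_trace(c(t_pre, tg[tg > 0.0034]),
                       c(c(50, -20, 7), y[tg > 0.0034]), 1)
  f2 <- fit_exponentials(tr2, 1L)
  expect_equal(f2$rates, base$rates, tolerance = 1e-9)
})

test_that("phase-count selection applies all guards", {
  set.seed(41)
  y1 <- 1 + 0.6 * exp(-4 * tg) + rnorm(200, sd = 0.005)
  expect_equal(select_phase_count(kinetic_trace(tg, y1, 1))$n_phases, 1L)

  y2 <- 1 + 0.5 * exp(-10 * tg) + 0.5 * exp(-1 * tg) + rnorm(200, sd = 0.01)
  sel2 <- select_phase_count(kinetic_trace(tg, y2, 1))
  expect_equal(sel2$n_phases, 2L)
  expect_length(sel2$fits, 2L)
  expect_true(all(is.finite(sel2$fit$model_score)))

  # amplitude guard: a 2% minor phase is not accepted
  y3 <- 1 + 0.98 * exp(-10 * tg) + 0.02 * exp(-1 * tg) + rnorm(200, sd = 0.01)
  expect_equal(select_phase_count(kinetic_trace(tg, y3, 1))$n_phases, 1L)

  # resolvability guard: a "phase" slower than the window is a drift
  y4 <- 1 + 0.5 * exp(-10 * tg) + 0.5 * exp(-0.001 * tg) +
    rnorm(200, sd = 0.002)
  expect_equal(select_phase_count(kinetic_trace(tg, y4, 1))$n_phases, 1L)
})

test_that("selection finds two phases reliably when both are observable", {
  sc <- validation_scheme()
  hits <- 0L; n_seed <- 100L
  for (s in seq_len(n_seed)) {
    tr <- simulate_trace(sc, 2, "folding",
                         noise = noise_spec(trace_sd = 0.01, seed = s))
    if (select_phase_count(tr)$n_phases == 2L) hits <- hits + 1L
  }
  expect_gte(hits / n_seed, 0.95)
})

test_that("chevron assembly orders branches and assigns singles by continuity", {
  mk2 <- function(kf, ks) exponential_fit(2, c(0.5, 0.5), c(kf, ks), 0, 0)
  mk1 <- function(k) exponential_fit(1, 1, k, 0, 0)
  fits <- list(
    list(denaturant = 1, fit = mk2(10, 1)),
    list(denaturant = 2, fit = mk2(8, 0.8)),
    list(denaturant = 3, fit = mk1(0.9)),   # continues the slow branch
    list(denaturant = 4, fit = mk1(12)))    # continues the fast branch
  ch <- assemble_chevron(fits)
  pts <- ch$points
  expect_equal(pts$phase[pts$denaturant == 3], "slow")
  expect_equal(pts$phase[pts$denaturant == 4], "fast")
  expect_true(all(pts$rate[pts$phase == "fast"] >
                    max(pts$rate[pts$phase == "slow"])))
  # invariant to input ordering
  ch_rev <- assemble_chevron(rev(fits))
  expect_equal(ch_rev$points, pts)
  # all single-phase fits produce a single branch
  ch1 <- assemble_chevron(list(list(denaturant = 1, fit = mk1(5)),
                               list(denaturant = 2, fit = mk1(4))))
  expect_equal(length(unique(ch1$points$phase)), 1L)
  # duplicate concentrations are kept and flagged
  chd <- assemble_chevron(list(list(denaturant = 1, fit = mk1(5)),
                               list(denaturant = 1, fit = mk1(5.2))))
  expect_true("replicate" %in% chd$flags)
  expect_equal(nrow(chd$points), 2L)
  # explicit branch extrapolations override continuity for singles
  ref <- list(fast = phase_params(10, 0.3, 2, 0.4, phase_label = "fast"),
              slow = phase_params(1, 0.3, 0.1, 0.4, phase_label = "slow"))
  chr <- assemble_chevron(list(list(denaturant = 2, fit = mk1(9))),
                          refine_with = ref)
  expect_equal(chr$points$phase, "fast")
  # resolvability caps drop out-of-window rates
  chc <- assemble_chevron(fits, max_rate = 11, min_rate = 0.85)
  expect_false(any(chc$points$rate > 11 | chc$points$rate < 0.85))
  expect_true(all(c("rate_cap", "rate_floor") %in% chc$flags))
  expect_error(assemble_chevron(list()), "empty")
})
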