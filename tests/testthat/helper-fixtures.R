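# Shared fixtures built in code. RT at 298 K, kcal/mol.
RT <- folding_constants()$RT

# CCL11 ground truth (published equilibrium and per-phase kinetics).
ccl11 <- ccl_preset("CCL11")
ccl24 <- ccl_preset("CCL24")

# A generic well-separated on-pathway scheme for property tests.
toy_scheme <- function(...) {
  args <- utils::modifyList(
    list(k1_0 = 10, m1 = 0.5, k1r_0 = 1, m1r = 0.3,
         k2_0 = 1, m2 = 0.4, k2r_0 = 0.05, m2r = 0.4),
    list(...))
  do.call(three_state_scheme, args)
}

# Random valid scheme for property sweeps (rates spread over decades,
# moderate m-values).
random_scheme <- function() {
  three_state_scheme(
    k1_0 = 10^runif(1, 0, 2), m1 = runif(1, 0.1, 0.8),
    k1r_0 = 10^runif(1, -1, 1), m1r = runif(1, 0.1, 0.8),
    k2_0 = 10^runif(1, -1, 1), m2 = runif(1, 0.1, 0.8),
    k2r_0 = 10^runif(1, -2, 0), m2r = runif(1, 0.1, 0.8))
}

# Random chevron phase truth with an interior minimum in (0.5, 6).
random_phase <- function() {
  repeat {
    p <- phase_params(kf0 = 10^runif(1, 0.5, 1.8), mf = runif(1, 0.2, 0.8),
                      ku0 = 10^runif(1, -1.5, 0.5), mu = runif(1, 0.2, 0.8))
    xs <- chevron_minimum(p)$denaturant
    if (is.finite(xs) && xs > 0.5 && xs < 6) return(p)
  }
}
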