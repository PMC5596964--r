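# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps all simulator randomness reproducible
# without clobbering the global stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Default stopped-flow acquisition grid: log-spaced 1 ms to 50 s.
default_time_grid <- function(n = 200L, t_min = 1e-3, t_max = 50) {
  exp(seq(log(t_min), log(t_max), length.out = n))
}

fk_log <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}
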