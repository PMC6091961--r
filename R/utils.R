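# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# session RNG.
run_seeded <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% 2147483646L) + 1L)
  }
  force(expr)
}

# Deterministic sub-seed derivation; keeps results reproducible from a single
# master seed while giving segments/subspaces/trials independent streams.
# Always < 2^31 - 1.
derive_seed <- function(master, ...) {
  parts <- c(as.numeric(master), as.numeric(unlist(list(...))))
  primes <- c(1, 7919, 104729, 1299709, 15485863)
  s <- sum(parts * primes[seq_along(parts)])
  as.integer(s %% 2147483629)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

is_finite_matrix <- function(x) is.matrix(x) && is.numeric(x) && all(is.finite(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
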