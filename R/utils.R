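# internal helpers: seed scoping and input checks

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
# seed = NULL means "use the current RNG stream" (needed so ensemble drivers
# can hand sub-streams to the simulator without extra bookkeeping).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

# One child seed per replicate from a master seed; keeps replicates
# individually reproducible. Values stay below 2^31 - 1.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok) {
    stop(sprintf("`%s` must be in %s%s, %s%s (got %g)", name,
                 if (strict) "(" else "[", format(lower), format(upper),
                 if (strict) ")" else "]", x), call. = FALSE)
  }
  if (integer && x != trunc(x)) {
    stop(sprintf("`%s` must be a whole number (got %g)", name, x),
         call. = FALSE)
  }
  invisible(x)
}

check_fraction <- function(x, name) check_number(x, name, 0, 1, strict = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a
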