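# Internal helpers shared across the simulation and deconvolution stages.

#' Derive an independent child seed from a master seed
#'
#' All randomness in the package flows from one integer master seed; every
#' stochastic sub-step draws its own child seed so stages are independently
#' reproducible and no stage consumes global random state left over from
#' another.
#'
#' @param master integer master seed.
#' @param index non-negative integer counter identifying the sub-step.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
child_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  stopifnot(is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- (abs(master) %% m)
  # two multiplicative mixing rounds keep products inside double precision
  s <- (s * 48271 + index + 1) %% m
  s <- (s * 16807 + 12345) %% m
  as.integer(s + 1)
}

#' Round half away from zero
#'
#' Count-valued outputs of the perturbation operators use round-half-up
#' (2.5 -> 3), unlike base [round()] which rounds half to even.
#' @param x numeric.
#' @keywords internal
round_half_up <- function(x) {
  floor(x + 0.5)
}

# run code under a local RNG state so callers' random streams are untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# small non-cryptographic polynomial hash used to stamp output files with the
# configuration that produced them
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  b <- utf8ToInt(s)
  h <- 7
  m <- 2147483647
  for (v in b) h <- (h * 31 + v) %% m
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                      strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  }
  invisible(x)
}
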