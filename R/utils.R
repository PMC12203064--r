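#' Seed-scoped evaluation and derived seeds
#'
#' `withSeed()` evaluates `expr` under a temporary RNG state seeded with
#' `seed`, restoring the caller's `.Random.seed` afterwards, so seeded
#' package calls never perturb the user's random stream (`seed = NULL`
#' uses the current stream unchanged). `deriveSeed()` derives a
#' reproducible child seed (`seed + offset`, kept inside the 32-bit
#' integer range) for sub-tasks such as rarefaction repetitions.
#'
#' @param seed integer master seed (or NULL)
#' @param expr expression to evaluate
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' @rdname withSeed
#' @param offset non-negative integer offset
#' @export
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

assertCount <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      (positive && x < 1) || (!positive && x < 0))
    stop(sprintf("'%s' must be a single %s integer", name,
                 if (positive) "positive" else "non-negative"))
  as.integer(x)
}

geometricMean <- function(x) exp(mean(log(x)))
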