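#' @useDynLib rewritask, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats glm glm.fit binomial coef predict median quantile rnorm
#'   runif rlnorm plogis qlogis pnorm rbinom setNames aggregate rgamma
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expit <- function(x) stats::plogis(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_string1 <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stopf("%s must be a single non-empty string", what)
}
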