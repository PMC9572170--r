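#' @importFrom stats approx complete.cases cov fft mad median na.omit p.adjust
#' @importFrom stats quantile rbinom rgamma rlnorm rnorm rpois runif sd
#' @importFrom stats setNames shapiro.test t.test var wilcox.test rexp
#' @importFrom utils head read.csv tail write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that library code never disturbs the
#' caller's RNG stream. All stochastic internals are funnelled through this.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed (kept below 2^31 - 1; R integers are 32-bit).
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 9973 + 12345) %%
    2147483629
  as.integer(s)
}

stopifnot_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

# Linear-interpolation quantiles, IQR = Q3 - Q1 (type 7).
iqr7 <- function(x) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7, na.rm = TRUE)
  q[2] - q[1]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
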