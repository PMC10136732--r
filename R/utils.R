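#' @importFrom stats median rnorm runif rbinom rpois rnbinom rlnorm predict
#'   quantile var sd setNames
#' @importFrom utils head write.table read.table
NULL

# Internal: fail with a message naming the offending argument/field.
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_real <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop_field(field, sprintf("must be a single number in [%s, %s]", min, max))
  as.numeric(x)
}

check_pair <- function(x, field, min = -Inf) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2] ||
      any(x < min))
    stop_field(field, sprintf("must be a (low, high) pair with low <= high, both >= %s", min))
  as.numeric(x)
}

# Run `expr` under a temporary RNG seed; the caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Geometric mean of strictly positive values; 0 if any value is 0.
geomean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
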