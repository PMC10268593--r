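#' @keywords internal
"_PACKAGE"

# formatted stop without the call, used by every validator
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Weighted median
#'
#' Smallest value whose cumulative weight reaches half the total weight.
#' Used as the reference depth across scaffolds, where weights are bin counts.
#'
#' @param x numeric values.
#' @param w nonnegative weights, same length as `x`.
#' @return A single number.
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]
  w <- w[o]
  x[which(cumsum(w) >= sum(w) / 2)[1]]
}

# Evaluate `expr` under a fixed, fully specified RNG state, restoring the
# caller's state afterwards. All generators funnel through this so that a
# (config, seed) pair is a pure function of its arguments.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# spawn a stream of sub-seeds below 2^31 from one master seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stopf("%s must be a positive number", name)
  }
  invisible(x)
}
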