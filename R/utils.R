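# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so that generator calls are pure functions of their
#' seed and do not perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# stop() with sprintf formatting and no call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Population (n-denominator) variance and covariance, the moment convention
# used by Lin's concordance correlation coefficient.
pop_var <- function(x) mean((x - mean(x))^2)
pop_cov <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

# log2 with the 0 * log(0) = 0 convention used by entropy-type features
xlog2 <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}

# Stable short hash of an R object (used for run manifests): serialize to a
# temporary file and take its md5.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
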