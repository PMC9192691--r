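# Internal helpers shared across modules.

#' @importFrom stats rnorm runif rbinom sd var qnorm pt phyper cor median
#'   quantile lm.fit setNames complete.cases
NULL

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user scripts.
with_seed <- function(seed, expr) {
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Moment skewness m3 / m2^(3/2); NA-safe, 0 for (near-)constant input.
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < 1e-24) return(0)
  mean((x - m)^3) / m2^1.5
}

# Column-wise median imputation for a numeric matrix.
impute_median <- function(mat) {
  for (j in seq_len(ncol(mat))) {
    miss <- !is.finite(mat[, j])
    if (any(miss)) {
      med <- median(mat[!miss, j])
      if (!is.finite(med)) med <- 0
      mat[miss, j] <- med
    }
  }
  mat
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
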