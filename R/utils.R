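#' @useDynLib petpool, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rgamma qnorm pnorm dnorm quantile median
#'   sd var coef vcov lm anova approx setNames rlnorm pt qt aggregate
#' @importFrom utils head read.delim write.table
NULL

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Multivariate normal draws via Cholesky (n x p)
rmvnorm_chol <- function(n, mean, sigma) {
  p <- length(mean)
  L <- chol(sigma)
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% L, 2, mean, "+")
}

# Inverse-Wishart draw given df and scale matrix S
riwish <- function(df, S) {
  W <- stats::rWishart(1, df, chol2inv(chol(S)))[, , 1]
  chol2inv(chol(W))
}

# Split R-hat for a single scalar over chains: draws is a matrix
# [iterations x chains].
split_rhat <- function(x) {
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[seq.int(n - half + 1, n), , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Crude effective sample size from lag-autocorrelations (pooled chains)
ess_basic <- function(x) {
  v <- as.vector(x)
  n <- length(v)
  if (sd(v) == 0) return(n)
  ac <- stats::acf(v, lag.max = min(100, n - 2), plot = FALSE)$acf[-1]
  rho_sum <- 0
  for (r in ac) {
    if (r < 0.05) break
    rho_sum <- rho_sum + r
  }
  n / (1 + 2 * rho_sum)
}

log_dhalfnorm <- function(x, scale) {
  ifelse(x <= 0, -Inf, log(2) + dnorm(x, 0, scale, log = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
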