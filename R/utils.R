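#' @useDynLib rpemem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom qnorm pnorm plogis rgamma sd var cor
#'   cov lm coef vcov pt qt binom.test chisq.test integrate optim factanal
#'   varimax promax quantile setNames aggregate as.formula dnorm model.matrix
#'   complete.cases pchisq
#' @importFrom utils head write.csv read.csv
NULL

#' Derive a child seed from a master seed
#'
#' All stochastic stages take a single integer seed; per-subject or per-stage
#' streams are derived deterministically so that independent stages do not
#' share or perturb each other's random numbers.
#'
#' @param seed master integer seed
#' @param ... integer indices identifying the stream (stage, subject, ...)
#' @return an integer seed in `[0, 2^31 - 1)`
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (i in idx) {
    # multiplicative-congruential style mixing, kept in double precision
    h <- (h * 48271 + as.double(i) * 1046527 + 11) %% 2147483647
  }
  as.integer(h)
}

#' Split-chain Gelman-Rubin statistic
#'
#' Classic potential-scale-reduction computed after splitting each chain in
#' half, so that trends within a chain inflate the diagnostic.
#'
#' @param x a numeric matrix (iterations x chains) or a list of equal-length
#'   numeric vectors, one per chain
#' @return the split R-hat value
#' @export
rhat_split <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W < .Machine$double.eps) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Highest-density interval of a sample
#'
#' Shortest interval containing `prob` of the draws.
#'
#' @param x numeric vector of posterior draws
#' @param prob interval mass (default 0.95)
#' @return named numeric vector `c(lower, upper)`
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- max(1L, floor(prob * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Widely applicable information criterion from a pointwise log-likelihood
#' matrix
#'
#' @param ll matrix of log-likelihoods, posterior draws in rows, observations
#'   in columns
#' @return list with `waic` (deviance scale, -2 * elpd), `se`, `lppd`,
#'   `p_waic`, and the pointwise elpd contributions
#' @export
waic <- function(ll) {
  stopifnot(is.matrix(ll), nrow(ll) >= 1)
  lppd_i <- apply(ll, 2, log_mean_exp)
  p_i <- if (nrow(ll) > 1) apply(ll, 2, var) else rep(0, ncol(ll))
  elpd_i <- lppd_i - p_i
  n <- ncol(ll)
  list(
    waic = -2 * sum(elpd_i),
    se = 2 * sqrt(n * var(elpd_i)),
    lppd = sum(lppd_i),
    p_waic = sum(p_i),
    pointwise = elpd_i
  )
}

#' Standardize a numeric vector to standard deviation one half
#'
#' Centers at the mean and divides by twice the (n-1) sample standard
#' deviation, putting continuous predictors on a scale comparable to a
#' two-level categorical contrast.
#'
#' @param x numeric vector with positive variance
#' @return standardized vector (mean 0, SD 0.5) with attributes `center` and
#'   `scale`
#' @export
standardize_2sd <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s <= 0) stop("standardize_2sd: vector is constant")
  out <- (x - mean(x)) / (2 * s)
  attr(out, "center") <- mean(x)
  attr(out, "scale") <- 2 * s
  out
}
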