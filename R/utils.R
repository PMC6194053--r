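## Internal numerical helpers shared across the fitting and simulation code.

#' @importFrom stats dnorm pnorm qnorm integrate uniroot optim rnorm runif
#'   rbinom pchisq qchisq lm resid aov glm binomial coef logLik var cor sd
#'   complete.cases cov setNames anova t.test quantile na.omit rmultinom
#'   prcomp ecdf
NULL

## Standard bivariate normal CDF P(X <= h, Y <= k) with correlation rho.
## One-dimensional conditioning reduction integrated by adaptive quadrature;
## accurate to ~1e-12, which the tetrachoric/LTM oracles require (<= 1e-6).
pbvn <- function(h, k, rho) {
  if (abs(rho) > 1) stop("correlation outside [-1, 1]")
  if (!is.finite(h) || !is.finite(k)) {
    if (h == -Inf || k == -Inf) return(0)
    if (h == Inf) return(pnorm(k))
    if (k == Inf) return(pnorm(h))
  }
  if (abs(rho) >= 1 - 1e-12) {
    if (rho > 0) return(pnorm(min(h, k)))
    return(max(0, pnorm(h) + pnorm(k) - 1))
  }
  if (rho == 0) return(pnorm(h) * pnorm(k))
  s <- sqrt(1 - rho^2)
  f <- function(x) dnorm(x) * pnorm((k - rho * x) / s)
  stats::integrate(f, -8.5, h, rel.tol = 1e-12, abs.tol = 1e-14,
                   stop.on.error = FALSE)$value
}

## Orthant (quadrant) probabilities of a 2x2 dichotomised bivariate normal.
## Thresholds t1 (row variable), t2 (column variable); cells ordered
## (0,0), (0,1), (1,0), (1,1) with 1 = above threshold. Sums to 1 exactly.
bvn_cell_probs <- function(t1, t2, rho) {
  p00 <- pbvn(t1, t2, rho)
  p0dot <- pnorm(t1)
  pdot0 <- pnorm(t2)
  p01 <- p0dot - p00
  p10 <- pdot0 - p00
  p11 <- 1 - p0dot - pdot0 + p00
  pmax(c(p00 = p00, p01 = p01, p10 = p10, p11 = p11), 0)
}

## -2 log likelihood of n iid multivariate-normal observations summarised by
## their sample mean xbar and (biased, /n) covariance S, under N(mu, sigma).
## Sufficient-statistic form: constant-time in n, which keeps twin fits at
## thousands of pairs fast.
neg2ll_mvn_suff <- function(n, xbar, S, mu, sigma) {
  p <- length(xbar)
  if (any(!is.finite(sigma))) return(1e10)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  d <- xbar - mu
  sigma_inv <- chol2inv(ch)
  quad <- sum(diag(sigma_inv %*% S)) + drop(t(d) %*% sigma_inv %*% d)
  n * (p * log(2 * pi) + logdet + quad)
}

## Mean and /n covariance of the rows of a matrix.
suff_stats <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  xbar <- colMeans(x)
  xc <- sweep(x, 2, xbar)
  list(n = n, xbar = xbar, S = crossprod(xc) / n)
}

## Spherical (hyperspherical Cholesky) parameterisation of a correlation
## matrix: angles in (0, pi) map to a valid correlation matrix of any
## dimension, so the optimiser can roam freely without leaving the PSD cone.
angles_to_corr <- function(theta, p) {
  L <- diag(p)
  idx <- 1L
  for (i in 2:p) {
    prod_sin <- 1
    for (j in 1:(i - 1)) {
      L[i, j] <- cos(theta[idx]) * prod_sin
      prod_sin <- prod_sin * sin(theta[idx])
      idx <- idx + 1L
    }
    L[i, i] <- prod_sin
  }
  tcrossprod(L)
}

n_angles <- function(p) p * (p - 1) / 2

corr_to_angles <- function(R) {
  p <- nrow(R)
  L <- t(chol(R))
  theta <- numeric(n_angles(p))
  idx <- 1L
  for (i in 2:p) {
    prod_sin <- 1
    for (j in 1:(i - 1)) {
      cj <- L[i, j] / prod_sin
      cj <- min(1, max(-1, cj))
      theta[idx] <- acos(cj)
      prod_sin <- prod_sin * sin(theta[idx])
      if (prod_sin < 1e-12) prod_sin <- 1e-12
      idx <- idx + 1L
    }
  }
  theta
}

## Draw n samples from N(mu, sigma) via Cholesky (upper-triangular) factor.
rmvn <- function(n, mu, sigma) {
  p <- length(mu)
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop(sprintf("covariance matrix not positive semi-definite (eigenvalue %.3g)",
                 min(ev$values)))
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p) %*% t(ev$vectors)
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% rt, 2, mu, `+`)
}

## Run expr with a private RNG stream: the caller's .Random.seed is
## untouched. All exported simulators route their draws through this.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
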