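## Multivariate twin models. All three designs model the 2T x 2T pair
## covariance per zygosity (T traits per twin) by maximum likelihood on
## complete-case pairs, using the sufficient-statistic Gaussian likelihood.
##
## Correlated factors: per-trait A/C/E factors linked by correlation
## matrices r_a, r_c, r_e (spherical-angle parameterisation keeps them
## positive definite). Common pathway: a single latent phenotype with its
## own ACE decomposition loads on every trait, plus trait-specific ACE
## residuals. Independent pathway: one common A, C and E factor each loads
## directly on every trait, plus trait-specific residuals.

cf_suff <- function(pairs, traits) {
  out <- list()
  for (z in c("MZ", "DZ")) {
    ws <- lapply(traits, function(tr) pairs_to_wide(pairs, tr, z)$pairs)
    sub <- pairs[pairs$zygosity == z, ]
    t1 <- sub[sub$twin == 1, c("family_id", traits)]
    t2 <- sub[sub$twin == 2, c("family_id", traits)]
    m <- merge(t1, t2, by = "family_id", suffixes = c("_1", "_2"))
    x <- as.matrix(m[, c(paste0(traits, "_1"), paste0(traits, "_2"))])
    x <- x[complete.cases(x), , drop = FALSE]
    if (nrow(x) < length(traits) * 2 + 3)
      stop("too few complete ", z, " pairs for a multivariate fit")
    out[[z]] <- suff_stats(x)
  }
  out
}

mv_neg2ll <- function(suff, mu_trait, within, cross_mz, cross_dz) {
  mu <- c(mu_trait, mu_trait)
  tot <- 0
  for (z in c("MZ", "DZ")) {
    cross <- if (z == "MZ") cross_mz else cross_dz
    sigma <- rbind(cbind(within, cross), cbind(t(cross), within))
    s <- suff[[z]]
    tot <- tot + neg2ll_mvn_suff(s$n, s$xbar, s$S, mu, sigma)
  }
  tot
}

#' Fit the correlated-factors multivariate twin model
#'
#' Each trait gets additive genetic, shared and non-shared environmental
#' factors; same-kind factors correlate across traits through the matrices
#' `r_a`, `r_c`, `r_e`, which are estimated under a spherical-angle
#' parameterisation that keeps them positive definite throughout
#' optimisation. Per-trait total variances and means are free (means
#' equated across twins and zygosity). Cross-twin genetic covariance is
#' weighted 1 (MZ) or 0.5 (DZ); shared environment crosses fully;
#' non-shared environment does not cross twins.
#'
#' @param pairs A twin-pair table.
#' @param traits Character vector (>= 2) of continuous trait columns;
#'   complete-case pairs are used.
#' @param n_starts Optimisation restarts.
#' @param start_seed Seed for restart draws.
#' @return A `"cf_fit"`: `shares` (traits x a2/c2/e2, standardized within
#'   trait), `r_a`, `r_c`, `r_e`, `means`, `variances`, `minus2ll`, `df`,
#'   `aic`, `n_pairs`. Methods: `print`, `coef`, `logLik`, `confint`
#'   (profile CIs on the factor correlations, bivariate fits).
#' @export
fit_correlated_factors <- function(pairs, traits, n_starts = 10,
                                   start_seed = 23L) {
  t_n <- length(traits)
  if (t_n < 2) stop("need >= 2 traits")
  suff <- cf_suff(pairs, traits)
  na <- n_angles(t_n)
  ## theta layout: [mu (T)] [logv (T)] [p (T)] [q (T)] [ang_a ang_c ang_e]
  unpack <- function(th) {
    mu <- th[1:t_n]
    v <- exp(th[t_n + 1:t_n])
    p <- pmin(pmax(th[2 * t_n + 1:t_n], 0), 1)
    q <- pmin(pmax(th[3 * t_n + 1:t_n], 0), 1)
    a2 <- p; c2 <- (1 - p) * q; e2 <- (1 - p) * (1 - q)
    ang <- th[4 * t_n + seq_len(3 * na)]
    list(mu = mu, v = v, a2 = a2, c2 = c2, e2 = e2,
         r_a = angles_to_corr(ang[seq_len(na)], t_n),
         r_c = angles_to_corr(ang[na + seq_len(na)], t_n),
         r_e = angles_to_corr(ang[2 * na + seq_len(na)], t_n))
  }
  implied <- function(u) {
    da <- sqrt(u$v * u$a2); dc <- sqrt(u$v * u$c2); de <- sqrt(u$v * u$e2)
    A <- tcrossprod(da) * u$r_a
    C <- tcrossprod(dc) * u$r_c
    E <- tcrossprod(de) * u$r_e
    list(within = A + C + E, mz = A + C, dz = 0.5 * A + C)
  }
  obj <- function(th) {
    u <- unpack(th)
    s <- implied(u)
    mv_neg2ll(suff, u$mu, s$within, s$mz, s$dz)
  }
  ## moment-based start: double-entry Falconer per trait, mid angles
  start0 <- local({
    mu0 <- v0 <- p0 <- q0 <- numeric(t_n)
    for (j in seq_len(t_n)) {
      idx <- c(j, t_n + j)
      r_mz <- suff$MZ$S[idx[1], idx[2]] /
        sqrt(suff$MZ$S[idx[1], idx[1]] * suff$MZ$S[idx[2], idx[2]])
      r_dz <- suff$DZ$S[idx[1], idx[2]] /
        sqrt(suff$DZ$S[idx[1], idx[1]] * suff$DZ$S[idx[2], idx[2]])
      a0 <- min(max(2 * (r_mz - r_dz), 0.05), 0.9)
      c0 <- min(max(r_mz - a0, 0.02), 0.9)
      if (a0 + c0 > 0.95) { sc <- 0.95 / (a0 + c0); a0 <- a0 * sc; c0 <- c0 * sc }
      p0[j] <- a0; q0[j] <- c0 / max(1 - a0, 1e-6)
      mu0[j] <- mean(c(suff$MZ$xbar[idx], suff$DZ$xbar[idx]))
      v0[j] <- mean(c(suff$MZ$S[idx[1], idx[1]], suff$MZ$S[idx[2], idx[2]],
                      suff$DZ$S[idx[1], idx[1]], suff$DZ$S[idx[2], idx[2]]))
    }
    c(mu0, log(v0), p0, q0, rep(pi / 3, 3 * na))
  })
  lower <- c(rep(-Inf, t_n), rep(-20, t_n), rep(0, 2 * t_n),
             rep(1e-3, 3 * na))
  upper <- c(rep(Inf, t_n), rep(20, t_n), rep(1, 2 * t_n),
             rep(pi - 1e-3, 3 * na))
  starts <- with_seed(start_seed, {
    extra <- replicate(max(0, n_starts - 1), {
      s <- start0
      s[2 * t_n + seq_len(2 * t_n)] <-
        pmin(pmax(s[2 * t_n + seq_len(2 * t_n)] + rnorm(2 * t_n, 0, 0.15),
                  0.02), 0.98)
      s[4 * t_n + seq_len(3 * na)] <- runif(3 * na, 0.3, pi - 0.3)
      s
    }, simplify = FALSE)
    c(list(start0), extra)
  })
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e5, maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value - 1e-8))
      best <- res
  }
  if (is.null(best)) stop("correlated-factors optimisation failed")
  u <- unpack(best$par)
  shares <- cbind(a2 = u$a2, c2 = u$c2, e2 = u$e2)
  rownames(shares) <- traits
  dimnames(u$r_a) <- dimnames(u$r_c) <- dimnames(u$r_e) <-
    list(traits, traits)
  k <- 4L * t_n + 3L * na
  structure(list(shares = shares, r_a = u$r_a, r_c = u$r_c, r_e = u$r_e,
                 means = setNames(u$mu, traits),
                 variances = setNames(u$v, traits),
                 minus2ll = best$value, df = k, aic = best$value + 2 * k,
                 n_pairs = c(MZ = suff$MZ$n, DZ = suff$DZ$n),
                 traits = traits, suff = suff, model = "correlated_factors",
                 theta = best$par),
            class = "cf_fit")
}

#' @export
print.cf_fit <- function(x, ...) {
  cat(sprintf("%s twin model: %s (%d MZ + %d DZ pairs)\n",
              gsub("_", " ", x$model), paste(x$traits, collapse = ", "),
              x$n_pairs["MZ"], x$n_pairs["DZ"]))
  cat("Standardized shares:\n"); print(round(x$shares, 3))
  if (x$model == "correlated_factors") {
    cat("r_a:\n"); print(round(x$r_a, 3))
    cat("r_c:\n"); print(round(x$r_c, 3))
    cat("r_e:\n"); print(round(x$r_e, 3))
  }
  cat(sprintf("-2lnL = %.2f, df = %d, AIC = %.2f\n", x$minus2ll, x$df, x$aic))
  invisible(x)
}

#' @export
coef.cf_fit <- function(object, ...) object$shares

#' @export
logLik.cf_fit <- function(object, ...)
  structure(-object$minus2ll / 2, df = object$df, class = "logLik")

#' Profile confidence intervals for factor correlations (bivariate)
#'
#' Profiles the `-2lnL` over a fixed value of one factor correlation
#' (`r_a`, `r_c` or `r_e`), maximising over all other parameters; the
#' interval collects values within `qchisq(level, 1)` of the minimum,
#' truncated to `[-1, 1]`.
#'
#' @param object A bivariate `"cf_fit"` (model `correlated_factors`).
#' @param parm Subset of `c("r_a", "r_c", "r_e")`.
#' @param level Confidence level.
#' @param ... Unused.
#' @return Matrix with `lower`/`upper` columns.
#' @export
confint.cf_fit <- function(object, parm = c("r_a", "r_c", "r_e"),
                           level = 0.95, ...) {
  if (object$model != "correlated_factors" || length(object$traits) != 2)
    stop("profile CIs implemented for bivariate correlated-factors fits")
  parm <- match.arg(parm, several.ok = TRUE)
  suff <- object$suff
  cut <- object$minus2ll + qchisq(level, 1)
  comp_idx <- c(r_a = 1L, r_c = 2L, r_e = 3L)
  prof <- function(comp, r_fix) {
    ## theta: mu(2) logv(2) p(2) q(2) + 2 free angles
    obj <- function(th) {
      mu <- th[1:2]; v <- exp(th[3:4])
      p <- pmin(pmax(th[5:6], 0), 1); q <- pmin(pmax(th[7:8], 0), 1)
      a2 <- p; c2 <- (1 - p) * q; e2 <- (1 - p) * (1 - q)
      rr <- c(NA, NA, NA)
      rr[comp_idx[comp]] <- r_fix
      rr[-comp_idx[comp]] <- cos(th[9:10])
      da <- sqrt(v * a2); dc <- sqrt(v * c2); de <- sqrt(v * e2)
      m2 <- function(d, r) matrix(c(d[1]^2, prod(d) * r, prod(d) * r,
                                    d[2]^2), 2, 2)
      A <- m2(da, rr[1]); C <- m2(dc, rr[2]); E <- m2(de, rr[3])
      mv_neg2ll(suff, mu, A + C + E, A + C, 0.5 * A + C)
    }
    th0 <- c(object$means, log(object$variances),
             pmin(pmax(object$shares[, "a2"], 0), 1),
             pmin(pmax(object$shares[, "c2"] /
                         pmax(1 - object$shares[, "a2"], 1e-6), 0), 1),
             acos(min(max(object[[setdiff(names(comp_idx), comp)[1]]][1, 2], -0.999), 0.999)),
             acos(min(max(object[[setdiff(names(comp_idx), comp)[2]]][1, 2], -0.999), 0.999)))
    optim(th0, obj, method = "L-BFGS-B",
          lower = c(rep(-Inf, 2), rep(-20, 2), rep(0, 4), rep(1e-3, 2)),
          upper = c(rep(Inf, 2), rep(20, 2), rep(1, 4), rep(pi - 1e-3, 2)),
          control = list(factr = 1e6, maxit = 500))$value
  }
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  for (p in parm) {
    hat <- object[[p]][1, 2]
    g <- function(r) prof(p, r) - cut
    lo <- if (g(-0.999) <= 0) -1 else
      uniroot(g, c(-0.999, hat), tol = 1e-4)$root
    hi <- if (g(0.999) <= 0) 1 else
      uniroot(g, c(hat, 0.999), tol = 1e-4)$root
    out[p, ] <- c(lo, hi)
  }
  out
}

#' Fit the common-pathway multivariate twin model
#'
#' One latent phenotype, itself decomposed into A, C and E (latent variance
#' fixed at 1 for identification), loads on every observed trait; each
#' trait additionally has specific A, C and E residual variances. Requires
#' at least three traits for identification. Loadings are bounded below at
#' zero (Heywood cases are flagged).
#'
#' @inheritParams fit_correlated_factors
#' @return A `"cf_fit"` with `model = "common_pathway"`, `loadings`,
#'   `latent_shares`, `specifics`.
#' @export
fit_common_pathway <- function(pairs, traits, n_starts = 8,
                               start_seed = 31L) {
  t_n <- length(traits)
  if (t_n < 3)
    stop("common-pathway model needs >= 3 traits for identification")
  suff <- cf_suff(pairs, traits)
  ## theta: mu(T) lam(T) pL qL spec_a(T) spec_c(T) spec_e(T) (sd scale)
  unpack <- function(th) {
    mu <- th[1:t_n]; lam <- th[t_n + 1:t_n]
    pL <- th[2 * t_n + 1]; qL <- th[2 * t_n + 2]
    aL2 <- pL; cL2 <- (1 - pL) * qL; eL2 <- (1 - pL) * (1 - qL)
    sa <- th[2 * t_n + 2 + 1:t_n]^2
    sc <- th[3 * t_n + 2 + 1:t_n]^2
    se <- th[4 * t_n + 2 + 1:t_n]^2
    list(mu = mu, lam = lam, aL2 = aL2, cL2 = cL2, eL2 = eL2,
         sa = sa, sc = sc, se = se)
  }
  sig_of <- function(u) {
    LL <- tcrossprod(u$lam)
    within <- LL + diag(u$sa + u$sc + u$se, t_n)
    mz <- LL * (u$aL2 + u$cL2) + diag(u$sa + u$sc, t_n)
    dz <- LL * (0.5 * u$aL2 + u$cL2) + diag(0.5 * u$sa + u$sc, t_n)
    list(within = within, mz = mz, dz = dz)
  }
  obj <- function(th) {
    u <- unpack(th)
    s <- sig_of(u)
    mv_neg2ll(suff, u$mu, s$within, s$mz, s$dz)
  }
  mu0 <- colMeans(rbind(suff$MZ$xbar[1:t_n], suff$MZ$xbar[t_n + 1:t_n],
                        suff$DZ$xbar[1:t_n], suff$DZ$xbar[t_n + 1:t_n]))
  start0 <- c(mu0, rep(0.7, t_n), 0.5, 0.5, rep(0.5, 3 * t_n))
  lower <- c(rep(-Inf, t_n), rep(0, t_n), 0, 0, rep(0, 3 * t_n))
  upper <- c(rep(Inf, t_n), rep(10, t_n), 1, 1, rep(10, 3 * t_n))
  starts <- with_seed(start_seed, c(list(start0),
    replicate(max(0, n_starts - 1), {
      s <- start0
      s[t_n + 1:t_n] <- runif(t_n, 0.3, 1.2)
      s[2 * t_n + 1:2] <- runif(2, 0.1, 0.9)
      s[2 * t_n + 2 + seq_len(3 * t_n)] <- runif(3 * t_n, 0.1, 0.9)
      s
    }, simplify = FALSE)))
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e5, maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value - 1e-8))
      best <- res
  }
  if (is.null(best)) stop("common-pathway optimisation failed")
  u <- unpack(best$par)
  tot <- u$lam^2 + u$sa + u$sc + u$se
  shares <- cbind(a2 = (u$lam^2 * u$aL2 + u$sa) / tot,
                  c2 = (u$lam^2 * u$cL2 + u$sc) / tot,
                  e2 = (u$lam^2 * u$eL2 + u$se) / tot)
  rownames(shares) <- traits
  k <- 5L * t_n + 2L
  heywood <- any(abs(best$par[t_n + 1:t_n] - upper[t_n + 1:t_n]) < 1e-6)
  structure(list(shares = shares,
                 loadings = setNames(u$lam, traits),
                 latent_shares = c(a2 = u$aL2, c2 = u$cL2, e2 = u$eL2),
                 specifics = cbind(a = u$sa, c = u$sc, e = u$se),
                 means = setNames(u$mu, traits),
                 minus2ll = best$value, df = k, aic = best$value + 2 * k,
                 n_pairs = c(MZ = suff$MZ$n, DZ = suff$DZ$n),
                 traits = traits, suff = suff, model = "common_pathway",
                 heywood = heywood),
            class = "cf_fit")
}

#' Fit the independent-pathway multivariate twin model
#'
#' One common additive-genetic factor, one common shared-environment
#' factor and one common non-shared-environment factor each load directly
#' on every trait (free-sign loadings), plus trait-specific A, C and E
#' residual variances.
#'
#' @inheritParams fit_correlated_factors
#' @return A `"cf_fit"` with `model = "independent_pathway"`,
#'   `common_loadings` (traits x a/c/e), `specifics`.
#' @export
fit_independent_pathway <- function(pairs, traits, n_starts = 8,
                                    start_seed = 37L) {
  t_n <- length(traits)
  if (t_n < 2) stop("need >= 2 traits")
  suff <- cf_suff(pairs, traits)
  ## theta: mu(T) la(T) lc(T) le(T) spec_a(T) spec_c(T) spec_e(T)
  unpack <- function(th) {
    list(mu = th[1:t_n], la = th[t_n + 1:t_n], lc = th[2 * t_n + 1:t_n],
         le = th[3 * t_n + 1:t_n], sa = th[4 * t_n + 1:t_n]^2,
         sc = th[5 * t_n + 1:t_n]^2, se = th[6 * t_n + 1:t_n]^2)
  }
  sig_of <- function(u) {
    A <- tcrossprod(u$la) + diag(u$sa, t_n)
    C <- tcrossprod(u$lc) + diag(u$sc, t_n)
    E <- tcrossprod(u$le) + diag(u$se, t_n)
    list(within = A + C + E, mz = A + C, dz = 0.5 * A + C)
  }
  obj <- function(th) {
    u <- unpack(th)
    s <- sig_of(u)
    mv_neg2ll(suff, u$mu, s$within, s$mz, s$dz)
  }
  mu0 <- colMeans(rbind(suff$MZ$xbar[1:t_n], suff$MZ$xbar[t_n + 1:t_n],
                        suff$DZ$xbar[1:t_n], suff$DZ$xbar[t_n + 1:t_n]))
  start0 <- c(mu0, rep(0.5, 3 * t_n), rep(0.4, 3 * t_n))
  starts <- with_seed(start_seed, c(list(start0),
    replicate(max(0, n_starts - 1),
              c(mu0, runif(3 * t_n, -0.8, 0.8), runif(3 * t_n, 0.1, 0.9)),
              simplify = FALSE)))
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, obj, method = "BFGS",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value - 1e-8))
      best <- res
  }
  if (is.null(best)) stop("independent-pathway optimisation failed")
  u <- unpack(best$par)
  tot <- u$la^2 + u$sa + u$lc^2 + u$sc + u$le^2 + u$se
  shares <- cbind(a2 = (u$la^2 + u$sa) / tot, c2 = (u$lc^2 + u$sc) / tot,
                  e2 = (u$le^2 + u$se) / tot)
  rownames(shares) <- traits
  k <- 7L * t_n
  structure(list(shares = shares,
                 common_loadings = cbind(a = u$la, c = u$lc, e = u$le),
                 specifics = cbind(a = u$sa, c = u$sc, e = u$se),
                 means = setNames(u$mu, traits),
                 minus2ll = best$value, df = k, aic = best$value + 2 * k,
                 n_pairs = c(MZ = suff$MZ$n, DZ = suff$DZ$n),
                 traits = traits, suff = suff,
                 model = "independent_pathway"),
            class = "cf_fit")
}
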