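## Univariate ACE twin model: maximum likelihood on the bivariate-normal
## pair distribution with implied covariance
##   Sigma_z = v * [[1, r_z], [r_z, 1]],  r_MZ = a2 + c2,  r_DZ = a2/2 + c2
## where a2, c2, e2 are standardized variance shares. Internally the shares
## are stick-broken as a2 = p, c2 = (1-p) q, e2 = (1-p)(1-q) so box
## constraints keep the simplex; means are equated across twins and
## zygosity; singletons (missing co-twin) enter through their marginal
## density (full-information ML).

ace_suff <- function(pairs, trait) {
  out <- list()
  for (z in c("MZ", "DZ")) {
    w <- pairs_to_wide(pairs, trait, z)
    if (nrow(w$pairs) < 3) stop("need >= 3 complete ", z, " pairs")
    out[[z]] <- list(pair = suff_stats(w$pairs),
                     single = if (length(w$singles))
                       list(n = length(w$singles), m = mean(w$singles),
                            s2 = mean((w$singles - mean(w$singles))^2))
                     else NULL)
  }
  out
}

ace_neg2ll <- function(mu, v, sa, sc, suff) {
  if (v <= 0) return(1e10)
  tot <- 0
  for (z in c("MZ", "DZ")) {
    r <- if (z == "MZ") sa + sc else 0.5 * sa + sc
    sigma <- v * matrix(c(1, r, r, 1), 2, 2)
    p <- suff[[z]]$pair
    tot <- tot + neg2ll_mvn_suff(p$n, p$xbar, p$S, c(mu, mu), sigma)
    s <- suff[[z]]$single
    if (!is.null(s))
      tot <- tot + s$n * (log(2 * pi) + log(v) +
                            (s$s2 + (s$m - mu)^2) / v)
  }
  tot
}

## map stick-breaking parameters to shares under each submodel; inputs are
## clamped because bounded optimisers may evaluate a hair outside the box
ace_shares <- function(p, q, submodel) {
  p <- min(max(p, 0), 1)
  q <- min(max(q, 0), 1)
  switch(submodel,
         ACE = c(a2 = p, c2 = (1 - p) * q, e2 = (1 - p) * (1 - q)),
         AE  = c(a2 = p, c2 = 0, e2 = 1 - p),
         CE  = c(a2 = 0, c2 = q, e2 = 1 - q),
         E   = c(a2 = 0, c2 = 0, e2 = 1))
}

ace_n_par <- function(submodel)
  switch(submodel, ACE = 4L, AE = 3L, CE = 3L, E = 2L)

#' Fit a univariate ACE twin model by maximum likelihood
#'
#' Decomposes the phenotypic variance of a (preferably standardized)
#' continuous trait into additive genetic (A), shared environmental (C)
#' and non-shared environmental (E) shares by maximising the
#' bivariate-normal pair likelihood with the classical implied covariance
#' structure (MZ off-diagonal `a2 + c2`, DZ `0.5 a2 + c2`). Means and total
#' variance are free but equated across twins and zygosity. Nested
#' submodels fix dropped components at zero. Optimisation is bounded
#' quasi-Newton with multiple deterministic random restarts; individuals
#' whose co-twin is missing contribute their marginal density.
#'
#' @param pairs A twin-pair table (long format).
#' @param trait Phenotype column name.
#' @param submodel One of `"ACE"`, `"AE"`, `"CE"`, `"E"`.
#' @param n_starts Number of optimisation restarts.
#' @param start_seed Seed for the restart draws (fixed for determinism).
#' @return An object of class `"ace_fit"` with components `shares`
#'   (standardized a2/c2/e2), `paths` (their square roots), `mean`,
#'   `variance`, `minus2ll`, `df` (free parameters), `aic`, `submodel`,
#'   `n_pairs`, and the sufficient statistics needed for profiling.
#'   Methods: `print`, `summary`, `coef`, `logLik`, `confint`
#'   (profile-likelihood CIs), `simulate`.
#' @examples
#' pairs <- simulate_ace_pairs(ace_params(0.5, 0.2, 0.3), 400, 400, seed = 2)
#' fit <- fit_ace(pairs, "trait")
#' coef(fit)
#' @export
fit_ace <- function(pairs, trait, submodel = c("ACE", "AE", "CE", "E"),
                    n_starts = 10, start_seed = 17L) {
  submodel <- match.arg(submodel)
  suff <- ace_suff(pairs, trait)
  ## moment start: Falconer from sample correlations
  r_mz <- suff$MZ$pair$S[1, 2] / sqrt(prod(diag(suff$MZ$pair$S)))
  r_dz <- suff$DZ$pair$S[1, 2] / sqrt(prod(diag(suff$DZ$pair$S)))
  a0 <- min(max(2 * (r_mz - r_dz), 0.05), 0.9)
  c0 <- min(max(r_mz - a0, 0.05), 0.9)
  if (a0 + c0 > 0.95) { s <- 0.95 / (a0 + c0); a0 <- a0 * s; c0 <- c0 * s }
  mu0 <- mean(c(suff$MZ$pair$xbar, suff$DZ$pair$xbar))
  v0 <- mean(c(diag(suff$MZ$pair$S), diag(suff$DZ$pair$S)))
  obj <- function(th) {
    sh <- ace_shares(th[3], th[4], submodel)
    ace_neg2ll(th[1], exp(th[2]), sh["a2"], sh["c2"], suff)
  }
  starts <- with_seed(start_seed, {
    s0 <- c(mu0, log(v0), a0, c0 / max(1 - a0, 1e-6))
    extra <- replicate(max(0, n_starts - 1),
                       c(mu0 + rnorm(1, 0, 0.1), log(v0) + rnorm(1, 0, 0.2),
                         runif(1, 0.02, 0.95), runif(1, 0.02, 0.95)),
                       simplify = FALSE)
    c(list(s0), extra)
  })
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, obj, method = "L-BFGS-B",
            lower = c(-Inf, -20, 0, 0), upper = c(Inf, 20, 1, 1),
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value - 1e-10))
      best <- res
  }
  if (is.null(best))
    stop("ACE optimisation failed to converge from any start")
  th <- best$par
  sh <- ace_shares(th[3], th[4], submodel)
  n_pairs <- c(MZ = suff$MZ$pair$n, DZ = suff$DZ$pair$n)
  k <- ace_n_par(submodel)
  structure(list(shares = sh, paths = sqrt(sh), mean = th[1],
                 variance = exp(th[2]), minus2ll = best$value, df = k,
                 aic = best$value + 2 * k, submodel = submodel,
                 n_pairs = n_pairs, trait = trait, suff = suff,
                 convergence = best$convergence),
            class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("%s twin model for '%s' (%d MZ + %d DZ pairs)\n",
              x$submodel, x$trait, x$n_pairs["MZ"], x$n_pairs["DZ"]))
  cat(sprintf("  a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              x$shares["a2"], x$shares["c2"], x$shares["e2"]))
  cat(sprintf("  -2lnL = %.2f, df = %d, AIC = %.2f\n",
              x$minus2ll, x$df, x$aic))
  invisible(x)
}

#' @export
coef.ace_fit <- function(object, ...) object$shares

#' @export
logLik.ace_fit <- function(object, ...) {
  structure(-object$minus2ll / 2, df = object$df,
            nobs = sum(object$n_pairs), class = "logLik")
}

#' @export
summary.ace_fit <- function(object, conf_level = 0.95, ...) {
  ci <- confint(object, level = conf_level)
  out <- list(fit = object, ci = ci, conf_level = conf_level)
  class(out) <- "summary.ace_fit"
  out
}

#' @export
print.summary.ace_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Profile %.0f%% CIs:\n", 100 * x$conf_level))
  print(round(x$ci, 3))
  invisible(x)
}

#' @export
simulate.ace_fit <- function(object, nsim = 1, seed = 1, ...) {
  params <- ace_params(object$shares["a2"], object$shares["c2"],
                       object$shares["e2"])
  reps <- lapply(seq_len(nsim), function(i)
    simulate_ace_pairs(params, object$n_pairs["MZ"], object$n_pairs["DZ"],
                       seed = seed + i - 1L, trait = object$trait))
  if (nsim == 1) reps[[1]] else reps
}

## Profile -2lnL with one standardized share fixed at s, maximising over
## the remaining free parameters (respecting the submodel's zero
## constraints).
ace_profile_value <- function(fit, component, s) {
  suff <- fit$suff
  submodel <- fit$submodel
  free_split <- switch(fit$submodel,
                       ACE = TRUE,
                       AE = component == "e2",  # a2 = 1 - e2, no split
                       CE = component == "e2",
                       E = FALSE)
  shares_at <- function(u) {
    rest <- 1 - s
    switch(component,
      a2 = switch(submodel,
                  ACE = c(s, rest * u, rest * (1 - u)),
                  AE = c(s, 0, rest),
                  stop("a2 not free in ", submodel)),
      c2 = switch(submodel,
                  ACE = c(rest * u, s, rest * (1 - u)),
                  CE = c(0, s, rest),
                  stop("c2 not free in ", submodel)),
      e2 = switch(submodel,
                  ACE = c(rest * u, rest * (1 - u), s),
                  AE = c(rest, 0, s),
                  CE = c(0, rest, s),
                  E = c(0, 0, 1)))
  }
  obj <- function(th) {
    sh <- shares_at(if (length(th) > 2) th[3] else 0.5)
    ace_neg2ll(th[1], exp(th[2]), sh[1], sh[2], suff)
  }
  n_free <- if (fit$submodel == "ACE") 3 else 2
  start <- c(fit$mean, log(fit$variance),
             if (n_free == 3) 0.5 else NULL)
  res <- optim(start, obj, method = "L-BFGS-B",
               lower = c(-Inf, -20, 0)[seq_len(n_free)],
               upper = c(Inf, 20, 1)[seq_len(n_free)],
               control = list(factr = 1e4, maxit = 500))
  res$value
}

#' Profile-likelihood confidence intervals for ACE shares
#'
#' Likelihood-based intervals: the set of values of a standardized share
#' whose profile `-2lnL` lies within `qchisq(level, 1)` (3.84 at 95%) of
#' the minimum, found by root bisection and truncated to `[0, 1]`. When
#' the profile never crosses the cutoff before a bound, the interval is
#' one-sided at that bound (recorded in the `"one_sided"` attribute).
#'
#' @param object An `"ace_fit"`.
#' @param parm Which shares; default all shares free in the submodel.
#' @param level Confidence level.
#' @param ... Unused.
#' @return A matrix with columns `lower`, `upper` and one row per share.
#' @export
confint.ace_fit <- function(object, parm = NULL,
                            level = 0.95, ...) {
  avail <- switch(object$submodel, ACE = c("a2", "c2", "e2"),
                  AE = c("a2", "e2"), CE = c("c2", "e2"), E = "e2")
  parm <- parm %||% avail
  parm <- match.arg(parm, avail, several.ok = TRUE)
  cut <- object$minus2ll + qchisq(level, 1)
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  flags <- character(0)
  for (p in parm) {
    hat <- unname(object$shares[p])
    g <- function(s) ace_profile_value(object, p, s) - cut
    ## lower endpoint
    lo <- if (hat <= 1e-8 || g(max(hat - 1e-6, 0)) > 0) hat else {
      if (g(0) <= 0) { flags <- c(flags, paste0(p, ":lower")); 0 }
      else uniroot(g, c(0, hat), tol = 1e-6)$root
    }
    hi <- if (hat >= 1 - 1e-8) hat else {
      if (g(1) <= 0) { flags <- c(flags, paste0(p, ":upper")); 1 }
      else uniroot(g, c(hat, 1), tol = 1e-6)$root
    }
    out[p, ] <- c(lo, hi)
  }
  attr(out, "one_sided") <- flags
  out
}

#' Fit the saturated twin model
#'
#' Free means, variances and within-pair covariance per zygosity group, the
#' reference model against which structured twin models are judged. By
#' default means and variances are equated across twin order within
#' zygosity (`equate = "order"`, the exchangeable-twin model whose MLEs are
#' the double-entry moments); `equate = "none"` leaves all five parameters
#' per zygosity free (MLEs are the raw sample moments).
#'
#' @param pairs A twin-pair table.
#' @param trait Phenotype column name.
#' @param equate `"order"` (default) or `"none"`.
#' @return A `"saturated_fit"`: `minus2ll`, `df`, `aic`, per-zygosity
#'   parameter estimates.
#' @export
fit_saturated <- function(pairs, trait, equate = c("order", "none")) {
  equate <- match.arg(equate)
  suff <- ace_suff(pairs, trait)
  m2ll <- 0
  est <- list()
  k <- 0L
  for (z in c("MZ", "DZ")) {
    p <- suff[[z]]$pair
    if (equate == "none") {
      mu <- p$xbar; S <- p$S
      est[[z]] <- list(mean = mu, cov = S)
      k <- k + 5L
    } else {
      m <- mean(p$xbar)
      d <- p$xbar - m
      v <- mean(diag(p$S)) + mean(d^2)
      cv <- p$S[1, 2] + d[1] * d[2]
      mu <- c(m, m)
      S <- matrix(c(v, cv, cv, v), 2, 2)
      est[[z]] <- list(mean = m, var = v, cov = cv)
      k <- k + 3L
    }
    m2ll <- m2ll + neg2ll_mvn_suff(p$n, p$xbar, p$S, mu, S)
    s <- suff[[z]]$single
    if (!is.null(s)) {
      vv <- if (equate == "none") mean(diag(S)) else S[1, 1]
      mm <- mean(mu)
      m2ll <- m2ll + s$n * (log(2 * pi) + log(vv) +
                              (s$s2 + (s$m - mm)^2) / vv)
    }
  }
  structure(list(minus2ll = m2ll, df = k, aic = m2ll + 2 * k,
                 estimates = est, equate = equate, trait = trait),
            class = "saturated_fit")
}

#' @export
print.saturated_fit <- function(x, ...) {
  cat(sprintf("Saturated twin model for '%s' (equate = %s): -2lnL = %.2f, df = %d\n",
              x$trait, x$equate, x$minus2ll, x$df))
  invisible(x)
}

#' Likelihood-ratio comparison of nested twin models
#'
#' `chi^2 = -2lnL(nested) - (-2lnL(full))` on `df(full) - df(nested)`
#' degrees of freedom, with the standard chi-square p-value, plus both
#' models' AIC. The accompanying [select_model()] applies the parsimony
#' rule: prefer the simplest model not significantly worse than the full
#' one.
#'
#' @param full,nested Fitted model objects with `minus2ll` and `df`
#'   components (e.g. from [fit_ace()], [fit_saturated()], [fit_ltm()]).
#' @param tol Numerical tolerance for a slightly negative chi-square
#'   (refit signal beyond it).
#' @return A `"model_comparison"` list: `chi_square`, `df_diff`, `p_value`,
#'   `aic_full`, `aic_nested`.
#' @export
compare_models <- function(full, nested, tol = 1e-4) {
  chi <- nested$minus2ll - full$minus2ll
  if (chi < -tol)
    stop("nested model fits better than full (chi-square = ",
         signif(chi, 4), "); refit with more starts")
  chi <- max(chi, 0)
  dfd <- full$df - nested$df
  if (dfd < 1) stop("nested model must have fewer free parameters")
  structure(list(chi_square = chi, df_diff = dfd,
                 p_value = pchisq(chi, dfd, lower.tail = FALSE),
                 aic_full = full$minus2ll + 2 * full$df,
                 aic_nested = nested$minus2ll + 2 * nested$df),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("LRT: chi^2 = %.3f on %d df, p = %.4f (AIC full %.2f, nested %.2f)\n",
              x$chi_square, x$df_diff, x$p_value, x$aic_full, x$aic_nested))
  invisible(x)
}

#' Select the most parsimonious adequate submodel
#'
#' Given a full fit and candidate nested fits, returns the label of the
#' nested model with the fewest parameters whose likelihood-ratio test
#' against the full model is non-significant at `alpha`; falls back to the
#' full model when every reduction fits significantly worse.
#'
#' @param full A fitted full model.
#' @param nested Named list of nested fits.
#' @param alpha Significance level.
#' @return The selected model's name (or `"full"`).
#' @export
select_model <- function(full, nested, alpha = 0.05) {
  ord <- order(vapply(nested, function(f) f$df, numeric(1)))
  for (i in ord) {
    cmp <- compare_models(full, nested[[i]])
    if (cmp$p_value >= alpha) return(names(nested)[i])
  }
  "full"
}
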