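## Liability threshold twin model (LTM): a binary trait is a dichotomised
## latent standard-normal liability; the per-zygosity 2x2 concordance
## tables are multinomial with cell probabilities given by bivariate-normal
## orthant probabilities at the threshold(s), with latent correlation
## a2 + c2 (MZ) or a2/2 + c2 (DZ).

ltm_tables <- function(pairs, trait) {
  out <- list()
  for (z in c("MZ", "DZ")) {
    w <- pairs_to_wide(pairs, trait, z)
    x <- w$pairs
    if (!all(x %in% 0:1)) stop("trait must be coded 0/1")
    tab <- matrix(0, 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
    for (i in 0:1) for (j in 0:1)
      tab[i + 1, j + 1] <- sum(x[, 1] == i & x[, 2] == j)
    out[[z]] <- list(table = tab,
                     single = c(n0 = sum(w$singles == 0),
                                n1 = sum(w$singles == 1)))
  }
  out
}

## -2 log multinomial likelihood of both zygosity tables; thresholds is a
## list with $MZ and $DZ each length-2 (twin 1, twin 2); rs named c(MZ, DZ)
ltm_neg2ll <- function(tabs, thresholds, rs) {
  tot <- 0
  for (z in c("MZ", "DZ")) {
    t12 <- thresholds[[z]]
    pr <- bvn_cell_probs(t12[1], t12[2], rs[[z]])
    if (any(pr <= 0)) return(1e10)
    tab <- tabs[[z]]$table
    counts <- c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    tot <- tot - 2 * sum(counts * log(pr))
    s <- tabs[[z]]$single
    if (sum(s) > 0) {
      p1 <- 1 - pnorm(mean(t12))
      tot <- tot - 2 * (s["n0"] * log(1 - p1) + s["n1"] * log(p1))
    }
  }
  tot
}

#' Fit a liability threshold model to binary twin data
#'
#' Maximum likelihood over the per-zygosity 2x2 concordance tables.
#' Threshold structure follows the classical submodel ladder: the
#' `"saturated"` model frees a threshold per twin per zygosity and a
#' tetrachoric correlation per zygosity; `"Sub1"` equates thresholds across
#' twin 1 and twin 2 within zygosity; `"Sub2"` equates them across twin
#' pairs and zygosity. ACE-structured fits (`components` of `"ACE"`,
#' `"AE"`, `"CE"` or `"E"`) use the Sub2 single threshold and constrain the
#' latent correlations to `a2 + c2` (MZ) and `a2/2 + c2` (DZ), yielding
#' liability-scale variance shares.
#'
#' @param pairs A twin-pair table with a 0/1 phenotype (1 = affected).
#' @param trait Phenotype column name.
#' @param submodel `"ACE"` (structured, default), `"saturated"`, `"Sub1"`
#'   or `"Sub2"`.
#' @param components Variance components for the structured fit.
#' @return An `"ltm_fit"`: `shares` (liability-scale a2/c2/e2, structured
#'   fits only), `thresholds`, `tetrachoric` (implied per-zygosity latent
#'   r), `prevalence` (implied), `minus2ll`, `df`, `aic`, `submodel`.
#'   Methods: `print`, `coef`, `logLik`, `confint` (profile CIs).
#' @examples
#' lp <- liability_params(ace_params(0.51, 0.36, 0.13), 0.57)
#' pairs <- simulate_liability_pairs(lp, 800, 800, seed = 3)
#' fit_ltm(pairs, "affected")
#' @export
fit_ltm <- function(pairs, trait,
                    submodel = c("ACE", "saturated", "Sub1", "Sub2"),
                    components = c("ACE", "AE", "CE", "E")) {
  submodel <- match.arg(submodel)
  components <- match.arg(components)
  tabs <- ltm_tables(pairs, trait)
  for (z in c("MZ", "DZ")) {
    tab <- tabs[[z]]$table
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      warning(z, " concordance table has a zero margin; threshold at boundary")
  }
  n_tot <- sum(vapply(tabs, function(t) sum(t$table) * 2 + sum(t$single),
                      numeric(1)))
  p_aff <- sum(vapply(tabs, function(t)
    sum(t$table * matrix(c(0, 1, 1, 2), 2, 2)) + t$single["n1"],
    numeric(1))) / n_tot
  t0 <- qnorm(1 - min(max(p_aff, 1e-3), 1 - 1e-3))

  if (submodel != "ACE") {
    fit <- ltm_fit_threshold_model(tabs, submodel, t0)
    fit$trait <- trait
    return(fit)
  }

  obj <- function(th) {
    sh <- ace_shares(th[2], th[3], components)
    rs <- c(MZ = unname(sh["a2"] + sh["c2"]),
            DZ = unname(0.5 * sh["a2"] + sh["c2"]))
    ltm_neg2ll(tabs, list(MZ = rep(th[1], 2), DZ = rep(th[1], 2)), rs)
  }
  starts <- with_seed(29L, {
    c(list(c(t0, 0.4, 0.4)),
      replicate(9, c(t0 + rnorm(1, 0, 0.1), runif(1, 0.05, 0.9),
                     runif(1, 0.05, 0.9)), simplify = FALSE))
  })
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = c(-5, 0, 0),
            upper = c(5, 1, 1), control = list(factr = 1e5, maxit = 300)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value - 1e-10))
      best <- res
  }
  if (is.null(best)) stop("LTM optimisation failed to converge")
  sh <- ace_shares(best$par[2], best$par[3], components)
  k <- switch(components, ACE = 3L, AE = 2L, CE = 2L, E = 1L)
  structure(list(shares = sh,
                 thresholds = c(all = best$par[1]),
                 tetrachoric = c(MZ = unname(sh["a2"] + sh["c2"]),
                                 DZ = unname(0.5 * sh["a2"] + sh["c2"])),
                 prevalence = 1 - pnorm(best$par[1]),
                 minus2ll = best$value, df = k, aic = best$value + 2 * k,
                 submodel = components, trait = trait, tabs = tabs),
            class = "ltm_fit")
}

## saturated / Sub1 / Sub2 threshold models: free tetrachoric r per
## zygosity, threshold structure per submodel
ltm_fit_threshold_model <- function(tabs, submodel, t0) {
  n_thr <- switch(submodel, saturated = 4L, Sub1 = 2L, Sub2 = 1L)
  thr_of <- function(th) switch(submodel,
    saturated = list(MZ = th[1:2], DZ = th[3:4]),
    Sub1 = list(MZ = rep(th[1], 2), DZ = rep(th[2], 2)),
    Sub2 = list(MZ = rep(th[1], 2), DZ = rep(th[1], 2)))
  obj <- function(th) {
    rs <- c(MZ = tanh(th[n_thr + 1]), DZ = tanh(th[n_thr + 2]))
    ltm_neg2ll(tabs, thr_of(th), rs)
  }
  start <- c(rep(t0, n_thr), atanh(0.5), atanh(0.3))
  res <- optim(start, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  th <- res$par
  k <- n_thr + 2L
  structure(list(shares = NULL, thresholds = th[seq_len(n_thr)],
                 tetrachoric = c(MZ = tanh(th[n_thr + 1]),
                                 DZ = tanh(th[n_thr + 2])),
                 prevalence = 1 - pnorm(mean(th[seq_len(n_thr)])),
                 minus2ll = res$value, df = k, aic = res$value + 2 * k,
                 submodel = submodel, tabs = tabs),
            class = "ltm_fit")
}

#' @export
print.ltm_fit <- function(x, ...) {
  cat(sprintf("Liability threshold model (%s) for '%s'\n",
              x$submodel, x$trait %||% "trait"))
  if (!is.null(x$shares))
    cat(sprintf("  liability a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
                x$shares["a2"], x$shares["c2"], x$shares["e2"]))
  cat(sprintf("  tetrachoric r: MZ = %.3f, DZ = %.3f; prevalence = %.3f\n",
              x$tetrachoric["MZ"], x$tetrachoric["DZ"], x$prevalence))
  cat(sprintf("  -2lnL = %.2f, df = %d, AIC = %.2f\n",
              x$minus2ll, x$df, x$aic))
  invisible(x)
}

#' @export
coef.ltm_fit <- function(object, ...)
  object$shares %||% object$tetrachoric

#' @export
logLik.ltm_fit <- function(object, ...) {
  structure(-object$minus2ll / 2, df = object$df, class = "logLik")
}

#' @export
confint.ltm_fit <- function(object, parm = NULL, level = 0.95, ...) {
  if (is.null(object$shares))
    stop("profile CIs are defined for structured (ACE-family) LTM fits")
  avail <- switch(object$submodel, ACE = c("a2", "c2", "e2"),
                  AE = c("a2", "e2"), CE = c("c2", "e2"), E = "e2")
  parm <- parm %||% avail
  parm <- match.arg(parm, avail, several.ok = TRUE)
  cut <- object$minus2ll + qchisq(level, 1)
  tabs <- object$tabs
  submodel <- object$submodel
  prof <- function(component, s) {
    shares_at <- function(u) {
      rest <- 1 - s
      switch(component,
        a2 = switch(submodel, ACE = c(s, rest * u, rest * (1 - u)),
                    AE = c(s, 0, rest)),
        c2 = switch(submodel, ACE = c(rest * u, s, rest * (1 - u)),
                    CE = c(0, s, rest)),
        e2 = switch(submodel, ACE = c(rest * u, rest * (1 - u), s),
                    AE = c(rest, 0, s), CE = c(0, rest, s), E = c(0, 0, 1)))
    }
    n_free <- if (submodel == "ACE") 2 else 1
    obj <- function(th) {
      sh <- shares_at(if (n_free == 2) th[2] else 0.5)
      rs <- c(MZ = sh[1] + sh[2], DZ = 0.5 * sh[1] + sh[2])
      ltm_neg2ll(tabs, list(MZ = rep(th[1], 2), DZ = rep(th[1], 2)), rs)
    }
    optim(c(unname(object$thresholds[1]), if (n_free == 2) 0.5),
          obj, method = "L-BFGS-B",
          lower = c(-5, 0)[seq_len(n_free)],
          upper = c(5, 1)[seq_len(n_free)],
          control = list(factr = 1e5, maxit = 300))$value
  }
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  for (p in parm) {
    hat <- unname(object$shares[p])
    g <- function(s) prof(p, s) - cut
    lo <- if (hat <= 1e-8 || g(0) <= 0) 0 else
      uniroot(g, c(0, hat), tol = 1e-5)$root
    hi <- if (hat >= 1 - 1e-8 || g(1) <= 0) 1 else
      uniroot(g, c(hat, 1), tol = 1e-5)$root
    out[p, ] <- c(lo, hi)
  }
  out
}
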