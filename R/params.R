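#' ACE variance-component parameters
#'
#' Bundle of standardized variance shares for the classical twin design:
#' additive genetic (`a2`), shared environmental (`c2`) and non-shared
#' environmental (`e2`) proportions of phenotypic variance. The three shares
#' must be non-negative and sum to one. Under this model the expected
#' within-pair phenotypic correlation is `a2 + c2` for monozygotic (MZ) pairs
#' and `0.5 * a2 + c2` for dizygotic (DZ) pairs.
#'
#' @param a2,c2,e2 Variance shares in `[0, 1]`; must sum to 1 (within 1e-8).
#' @return An object of class `"ace_params"`: a named numeric vector.
#' @examples
#' ace_params(0.57, 0.13, 0.30)  # entrance-exam-like trait
#' @export
ace_params <- function(a2, c2, e2) {
  p <- c(a2 = unname(a2), c2 = unname(c2), e2 = unname(e2))
  if (any(!is.finite(p)) || any(p < -1e-12))
    stop("ACE shares must be finite and non-negative")
  if (abs(sum(p) - 1) > 1e-8)
    stop("ACE shares must sum to 1 (got ", signif(sum(p), 6), ")")
  structure(pmax(p, 0), class = "ace_params")
}

#' @export
print.ace_params <- function(x, ...) {
  cat(sprintf("ACE shares: a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              x["a2"], x["c2"], x["e2"]))
  invisible(x)
}

#' Liability-threshold parameters for a binary trait
#'
#' A binary trait is modelled as an unobserved standard-normal liability
#' dichotomised at a threshold; the threshold is `qnorm(1 - prevalence)` so
#' that the expected affected fraction equals `prevalence`. ACE shares apply
#' on the liability scale.
#'
#' @param ace An [ace_params()] object (liability-scale shares).
#' @param prevalence Population proportion affected, in (0, 1).
#' @return An object of class `"liability_params"`.
#' @examples
#' liability_params(ace_params(0.51, 0.36, 0.13), prevalence = 0.57)
#' @export
liability_params <- function(ace, prevalence) {
  if (!inherits(ace, "ace_params")) ace <- do.call(ace_params, as.list(ace))
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)")
  structure(list(ace = ace, prevalence = prevalence,
                 threshold = qnorm(1 - prevalence)),
            class = "liability_params")
}

#' Correlated-factors model parameters
#'
#' Multivariate twin-model parameters: per-trait standardized path
#' coefficients (`a`, `c`, `e`, with `a^2 + c^2 + e^2 = 1` for each trait)
#' and the factor correlation matrices `r_a`, `r_c`, `r_e` linking the
#' trait-specific additive-genetic, shared-environmental and non-shared
#' environmental factors.
#'
#' @param shares A matrix or data frame with one row per trait and columns
#'   `a2`, `c2`, `e2` (each row summing to 1), or a list of [ace_params()].
#' @param r_a,r_c,r_e Correlation matrices (symmetric, unit diagonal,
#'   positive semi-definite), one per component. Scalars are accepted for
#'   two traits.
#' @param traits Optional character vector of trait names.
#' @return An object of class `"cf_params"` with elements `path` (traits x
#'   (a, c, e) path coefficients), `r_a`, `r_c`, `r_e`.
#' @examples
#' cf_params(rbind(c(0.57, 0.13, 0.30), c(0.57, 0.05, 0.38)),
#'           r_a = 0.76, r_c = 0.81, r_e = 0.35)
#' @export
cf_params <- function(shares, r_a, r_c, r_e, traits = NULL) {
  if (is.list(shares) && !is.data.frame(shares))
    shares <- do.call(rbind, lapply(shares, unclass))
  shares <- as.matrix(shares)
  colnames(shares) <- c("a2", "c2", "e2")
  t_n <- nrow(shares)
  if (t_n < 2) stop("correlated-factors parameters need >= 2 traits")
  if (any(abs(rowSums(shares) - 1) > 1e-8))
    stop("each trait's a2 + c2 + e2 must equal 1")
  if (any(shares < -1e-12)) stop("variance shares must be non-negative")
  as_corr <- function(r, label) {
    if (length(r) == 1 && t_n == 2) r <- matrix(c(1, r, r, 1), 2, 2)
    r <- as.matrix(r)
    if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8)) ||
        any(abs(diag(r) - 1) > 1e-8) || any(abs(r) > 1 + 1e-8))
      stop(label, " must be a correlation matrix")
    ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      stop(label, " is not positive semi-definite (eigenvalue ",
           signif(ev, 3), ")")
    r
  }
  traits <- traits %||% rownames(shares) %||% paste0("trait", seq_len(t_n))
  path <- sqrt(pmax(shares, 0))
  colnames(path) <- c("a", "c", "e")
  rownames(path) <- traits
  structure(list(path = path,
                 r_a = as_corr(r_a, "r_a"),
                 r_c = as_corr(r_c, "r_c"),
                 r_e = as_corr(r_e, "r_e"),
                 traits = traits),
            class = "cf_params")
}

## Component covariance blocks of the correlated-factors model. For traits
## i, j the within-person covariance is
##   a_i a_j r_a(ij) + c_i c_j r_c(ij) + e_i e_j r_e(ij)
## and the cross-twin covariance replaces r_a's weight with k = 1 (MZ) or
## 0.5 (DZ) and drops the e term.
cf_component_cov <- function(params) {
  p <- params$path
  list(A = tcrossprod(p[, "a"]) * params$r_a,
       C = tcrossprod(p[, "c"]) * params$r_c,
       E = tcrossprod(p[, "e"]) * params$r_e)
}

#' Implied pair covariance of a correlated-factors model
#'
#' Assembles the full `2T x 2T` covariance matrix of a twin pair (T traits
#' for twin 1 stacked on T traits for twin 2) implied by correlated-factors
#' parameters, for a given zygosity. The cross-twin genetic weight is 1 for
#' MZ and 0.5 for DZ pairs; shared environment is fully shared either way;
#' non-shared environment does not cross twins.
#'
#' @param params A [cf_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A symmetric positive semi-definite matrix.
#' @export
cf_pair_covariance <- function(params, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  k <- if (zygosity == "MZ") 1 else 0.5
  comp <- cf_component_cov(params)
  within <- comp$A + comp$C + comp$E
  cross <- k * comp$A + comp$C
  sigma <- rbind(cbind(within, cross), cbind(cross, within))
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    stop(sprintf("assembled %s pair covariance is not positive semi-definite (eigenvalue %.3g)",
                 zygosity, ev))
  sigma
}

#' ACE decomposition of a residualized trait
#'
#' Under a bivariate correlated-factors model, regressing trait 2 on trait 1
#' (population regression, standardized traits) leaves a residual whose
#' variance still decomposes into A, C and E. This returns that implied
#' decomposition, used to choose generating parameters for
#' achievement-adjusted university quality.
#'
#' @param params A bivariate [cf_params()] object; trait 1 is the regressor.
#' @return An [ace_params()] for the standardized residual of trait 2.
#' @export
implied_residual_ace <- function(params) {
  comp <- cf_component_cov(params)
  within <- comp$A + comp$C + comp$E
  b <- within[1, 2] / within[1, 1]
  res <- vapply(comp, function(m) {
    m[2, 2] - 2 * b * m[1, 2] + b^2 * m[1, 1]
  }, numeric(1))
  ace_params(res[["A"]] / sum(res), res[["C"]] / sum(res),
             res[["E"]] / sum(res))
}

#' Solve bivariate parameters for a target residual heritability
#'
#' Given trait 1's shares and the factor correlations, finds trait 2's
#' additive share (holding its shared-environment share fixed) so that the
#' implied residual-trait heritability from [implied_residual_ace()] equals
#' `target_h2`. Used to set up generating conditions for the
#' achievement-adjusted quality analysis.
#'
#' @param trait1 [ace_params()] for the regressor trait.
#' @param r_a,r_c,r_e Factor correlations (scalars, two traits).
#' @param target_h2 Desired residual heritability in (0, 1).
#' @param c2 Trait 2 shared-environment share, held fixed; the default
#'   (`NULL`) instead chooses the share that minimises the residual
#'   trait's shared-environment variance, matching a residual trait whose
#'   best-fitting univariate model drops C.
#' @return A bivariate [cf_params()] object meeting the target.
#' @export
solve_residual_h2 <- function(trait1, r_a, r_c, r_e, target_h2, c2 = NULL) {
  build <- function(a2, c2v)
    cf_params(rbind(unclass(trait1), c(a2, c2v, 1 - a2 - c2v)),
              r_a = r_a, r_c = r_c, r_e = r_e,
              traits = c("exam", "quality"))
  solve_a2 <- function(c2v) {
    f <- function(a2) implied_residual_ace(build(a2, c2v))["a2"] - target_h2
    uniroot(f, c(0.01, 1 - c2v - 0.01), tol = 1e-10)$root
  }
  if (!is.null(c2)) return(build(solve_a2(c2), c2))
  ## fixed point: residual C variance is minimised at c_2 = b * c_1 * r_c,
  ## where b is the implied phenotypic regression slope
  c1 <- unclass(trait1)[["c2"]]
  c2v <- 0.05
  for (i in 1:50) {
    a2 <- solve_a2(c2v)
    p <- build(a2, c2v)
    comp <- cf_component_cov(p)
    within <- comp$A + comp$C + comp$E
    b <- within[1, 2] / within[1, 1]
    c2_new <- min(max((b * sqrt(c1) * r_c)^2, 1e-6), 0.5)
    if (abs(c2_new - c2v) < 1e-10) break
    c2v <- c2_new
  }
  build(solve_a2(c2v), c2v)
}

#' Default generating parameters for university-success traits
#'
#' The study conditions used throughout the package's recovery analyses:
#' univariate ACE shares for entrance-exam achievement, university quality
#' and university achievement, liability-scale shares and prevalence for
#' enrolment, and the exam-quality correlated-factors parameters. Shares
#' not individually reported for a trait are fixed once (documented in the
#' methods vignette) and never tuned.
#'
#' @return A named list: `exam`, `quality`, `achievement` ([ace_params()]),
#'   `enrolment` ([liability_params()]), `exam_quality` ([cf_params()]),
#'   `gps_r2` (scalar).
#' @export
uni_success_params <- function() {
  list(
    exam        = ace_params(0.57, 0.13, 0.30),
    quality     = ace_params(0.57, 0.05, 0.38),
    achievement = ace_params(0.46, 0.00, 0.54),
    adjusted_quality_h2 = 0.47,
    enrolment   = liability_params(ace_params(0.51, 0.36, 0.13),
                                   prevalence = 0.57),
    exam_quality = cf_params(rbind(c(0.57, 0.13, 0.30),
                                   c(0.57, 0.05, 0.38)),
                             r_a = 0.76, r_c = 0.81, r_e = 0.35,
                             traits = c("exam", "quality")),
    gps_r2 = 0.04
  )
}
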