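#' Residualize a trait on age and sex
#'
#' Ordinary least-squares regression of a continuous trait on covariates
#' (typically age and sex), returning the residuals. Constant covariate
#' columns are dropped with a warning. Residuals are exactly uncorrelated
#' with each retained covariate (OLS orthogonality).
#'
#' @param y Numeric trait values.
#' @param covariates A `data.frame` or matrix of per-individual covariates;
#'   rows align with `y`. `NA`s in `y` are carried through; individuals
#'   with missing covariates among those with observed `y` are an error.
#' @return A `"residualized_trait"`: numeric residuals (NA where `y` was
#'   NA) with a `provenance` attribute recording the applied step.
#' @export
regress_covariates <- function(y, covariates) {
  covariates <- as.data.frame(covariates)
  obs <- !is.na(y)
  if (anyNA(covariates[obs, , drop = FALSE]))
    stop("missing covariate values for individuals with observed trait")
  keep <- vapply(covariates, function(v) length(unique(v[obs])) > 1,
                 logical(1))
  if (!all(keep)) {
    warning("dropping constant covariate column(s): ",
            paste(names(covariates)[!keep], collapse = ", "))
    covariates <- covariates[, keep, drop = FALSE]
  }
  out <- rep(NA_real_, length(y))
  if (ncol(covariates) == 0) {
    out[obs] <- y[obs] - mean(y[obs])
  } else {
    fit <- lm(y ~ ., data = cbind(data.frame(y = y), covariates),
              na.action = stats::na.exclude)
    out <- as.numeric(resid(fit))
  }
  new_residualized(out, sprintf("ols_residual(%s)",
                                paste(names(covariates), collapse = "+")))
}

#' Van der Waerden (rank-based inverse-normal) transform
#'
#' Maps values to normal scores `qnorm(rank / (n + 1))` where ranks use
#' mid-ranks for ties and `n` counts non-missing observations. The output
#' is a monotone function of the ranks, so rank order (and any Spearman
#' correlation) is preserved exactly.
#'
#' @param x Numeric values; `NA`s are passed through.
#' @return A `"residualized_trait"` of normal scores.
#' @examples
#' van_der_waerden(c(1, 2, 3))  # -0.674, 0, 0.674
#' @export
van_der_waerden <- function(x) {
  obs <- !is.na(x)
  if (length(unique(x[obs])) < 2)
    stop("van der Waerden transform needs >= 2 distinct values")
  n <- sum(obs)
  out <- rep(NA_real_, length(x))
  out[obs] <- qnorm(rank(x[obs], ties.method = "average") / (n + 1))
  new_residualized(out, "van_der_waerden")
}

#' Residualize one trait on another and re-standardize
#'
#' OLS residuals of `y` (e.g., university quality) on `x` (e.g., entrance
#' exam achievement), computed on complete pairs and re-standardized to
#' unit variance. Used to isolate the component of university quality not
#' explained by prior achievement.
#'
#' @param y,x Numeric vectors of equal length.
#' @param standardize Re-scale residuals to mean 0, SD 1 (default TRUE).
#' @return A `"residualized_trait"` (NA where either input was missing).
#' @export
residualize_on_trait <- function(y, x, standardize = TRUE) {
  ok <- !is.na(y) & !is.na(x)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  out <- rep(NA_real_, length(y))
  fit <- lm(y[ok] ~ x[ok])
  r <- resid(fit)
  ## guard: an (almost) perfect fit leaves numerical dust, not signal
  if (standardize && sd(r) > 1e-10 * max(sd(y[ok]), 1e-300))
    r <- (r - mean(r)) / sd(r)
  out[ok] <- r
  new_residualized(out, if (standardize) "ols_residual(x);standardized"
                   else "ols_residual(x)")
}

new_residualized <- function(values, step) {
  prev <- attr(values, "provenance")
  structure(as.numeric(values), provenance = c(prev, step),
            class = "residualized_trait")
}

#' The canonical phenotype-preparation pipeline
#'
#' Age-and-sex regression followed by the van der Waerden transform, in
#' that order; the order is recorded in the result's provenance and can be
#' reversed with `transform_first = TRUE`.
#'
#' @inheritParams regress_covariates
#' @param transform_first Apply the rank-normal transform before (instead
#'   of after) covariate regression.
#' @return A `"residualized_trait"` with full provenance.
#' @export
prepare_trait <- function(y, covariates, transform_first = FALSE) {
  if (transform_first) {
    z <- van_der_waerden(y)
    out <- regress_covariates(as.numeric(z), covariates)
    attr(out, "provenance") <- c(attr(z, "provenance"),
                                 attr(out, "provenance"))
    out
  } else {
    r <- regress_covariates(y, covariates)
    out <- van_der_waerden(as.numeric(r))
    attr(out, "provenance") <- c(attr(r, "provenance"),
                                 attr(out, "provenance"))
    out
  }
}

#' @export
print.residualized_trait <- function(x, ...) {
  cat("Residualized trait, n =", sum(!is.na(x)), "observed\n")
  cat("Provenance:", paste(attr(x, "provenance"), collapse = " -> "), "\n")
  invisible(x)
}

#' Two-way ANOVA for sex and zygosity mean effects
#'
#' Fits `trait ~ sex * zygosity` and reports the variance explained
#' (eta-squared) by each term and in total, the screening used to decide
#' whether sex-limitation modelling is warranted. With empty design cells
#' the interaction is dropped (main-effects model) with a warning.
#'
#' @param trait Numeric values.
#' @param sex,zygosity Factors (or coercible) of the same length.
#' @return A `data.frame` with rows per term plus `"total"`: `df`, `ss`,
#'   `eta_sq`.
#' @export
sex_zygosity_anova <- function(trait, sex, zygosity) {
  sex <- factor(sex); zygosity <- factor(zygosity)
  if (nlevels(droplevels(sex)) < 2 || nlevels(droplevels(zygosity)) < 2)
    stop("both factors need >= 2 levels present")
  d <- data.frame(trait = trait, sex = sex, zygosity = zygosity)
  d <- d[complete.cases(d), ]
  full_cells <- all(table(d$sex, d$zygosity) > 0)
  if (!full_cells) {
    warning("empty sex x zygosity cells; fitting main effects only")
    fit <- aov(trait ~ sex + zygosity, data = d)
  } else {
    fit <- aov(trait ~ sex * zygosity, data = d)
  }
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]
  terms <- trimws(rownames(tab))
  ss_total <- sum(ss)
  model_terms <- terms != "Residuals"
  out <- data.frame(term = c(terms[model_terms], "total"),
                    df = c(tab[["Df"]][model_terms], sum(tab[["Df"]][model_terms])),
                    ss = c(ss[model_terms], sum(ss[model_terms])),
                    stringsAsFactors = FALSE)
  out$eta_sq <- out$ss / ss_total
  out
}

#' Sensitivity t-test between reporters and non-reporters
#'
#' Compares an outcome between individuals who did and did not report some
#' follow-up measure (e.g., final degree grade): Welch two-sample t-test
#' plus the point-biserial r-squared as the variance in the outcome
#' explained by group membership.
#'
#' @param outcome Numeric values.
#' @param reported Logical or 0/1 flag of the same length.
#' @return A list: `t`, `df`, `p`, `variance_explained`.
#' @export
sensitivity_t_test <- function(outcome, reported) {
  reported <- as.logical(reported)
  ok <- !is.na(outcome) & !is.na(reported)
  outcome <- outcome[ok]; reported <- reported[ok]
  if (sum(reported) < 2 || sum(!reported) < 2)
    stop("each group needs >= 2 members")
  tt <- t.test(outcome[reported], outcome[!reported])
  r <- cor(outcome, as.numeric(reported))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, variance_explained = r^2)
}
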