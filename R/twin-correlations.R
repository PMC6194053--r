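#' Double-entry intraclass twin correlation
#'
#' Pearson correlation on double-entered pairs: each complete pair
#' contributes both orderings (1,2) and (2,1), which makes the estimate
#' invariant to twin-order permutation. The 95% CI uses the Fisher
#' z-transform with effective sample size equal to the number of pairs
#' (not the doubled count).
#'
#' @param pairs A twin-pair table (long format; see [simulate_ace_pairs()]).
#' @param trait Phenotype column name.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param conf_level Confidence level for the interval.
#' @return A list: `r`, `n_pairs`, `ci` (length-2).
#' @export
intraclass_correlation <- function(pairs, trait, zygosity,
                                   conf_level = 0.95) {
  w <- pairs_to_wide(pairs, trait, zygosity)$pairs
  if (nrow(w) < 3) stop("need >= 3 complete pairs in the group")
  if (sd(w[, 1]) == 0 && sd(w[, 2]) == 0)
    stop("zero variance within zygosity group")
  x <- c(w[, 1], w[, 2])
  y <- c(w[, 2], w[, 1])
  r <- cor(x, y)
  n <- nrow(w)
  se <- 1 / sqrt(n - 3)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(atanh(min(max(r, -0.999999), 0.999999)) + c(-1, 1) * zq * se)
  list(r = r, n_pairs = n, ci = ci)
}

#' Falconer moment estimates of A, C and E
#'
#' The textbook rough decomposition from intraclass correlations:
#' `A = 2 * (r_mz - r_dz)`, `C = r_mz - A`, `E = 1 - r_mz`. Values are
#' reported raw (no clipping); estimates outside `[0, 1]` are flagged.
#'
#' @param r_mz,r_dz MZ and DZ intraclass correlations, each in `[-1, 1]`.
#' @return A list: `A`, `C`, `E`, and `flags` (character vector naming any
#'   out-of-range component; empty when all are proper proportions).
#' @examples
#' falconer_estimates(0.70, 0.40)  # A = 0.6, C = 0.1, E = 0.3
#' @export
falconer_estimates <- function(r_mz, r_dz) {
  if (abs(r_mz) > 1 || abs(r_dz) > 1) stop("correlations must lie in [-1, 1]")
  A <- 2 * (r_mz - r_dz)
  C <- r_mz - A
  E <- 1 - r_mz
  est <- c(A = A, C = C, E = E)
  flags <- names(est)[est < 0 | est > 1]
  list(A = A, C = C, E = E, flags = flags)
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Maximum-likelihood estimate of the latent bivariate-normal correlation
#' underlying a 2x2 contingency table, with the two dichotomisation
#' thresholds. For a 2x2 table the model is saturated: the thresholds are
#' determined by the margins and the correlation solves the observed
#' (1,1)-cell probability equation; this coincides with the joint ML
#' solution whenever the table is reproducible.
#'
#' @param table A 2x2 matrix of counts, rows = variable 1 (0 then 1),
#'   columns = variable 2 (0 then 1).
#' @return A list: `rho`, `thresholds` (length-2), `n`.
#' @export
tetrachoric_correlation <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  n <- sum(tab)
  t1 <- qnorm(sum(tab[1, ]) / n)   # P(var1 = 0)
  t2 <- qnorm(sum(tab[, 1]) / n)
  p11 <- tab[2, 2] / n
  f <- function(rho) (1 - pnorm(t1) - pnorm(t2) + pbvn(t1, t2, rho)) - p11
  lo <- f(-0.9999); hi <- f(0.9999)
  rho <- if (lo >= 0) -0.999 else if (hi <= 0) 0.999 else
    uniroot(f, c(-0.9999, 0.9999), tol = 1e-10)$root
  list(rho = rho, thresholds = c(t1, t2), n = n)
}

#' Fisher r-to-z comparison of two correlations
#'
#' Tests equality of two independent correlations via
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes (> 3).
#' @return A list: `z`, `p`.
#' @export
fisher_r_to_z <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}
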