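#' LD clumping / pruning configuration
#'
#' @param r2_cutoff Dosage r-squared above which a SNP is removed in favour
#'   of a better-associated neighbour; default 0.1.
#' @param window_bp Base-pair window within which LD is checked; default
#'   250,000 (distance between retained and candidate SNP <= window).
#' @return A `"prune_config"` list.
#' @export
prune_config <- function(r2_cutoff = 0.1, window_bp = 250000L) {
  if (r2_cutoff <= 0 || r2_cutoff > 1) stop("r2_cutoff must lie in (0, 1]")
  if (window_bp <= 0) stop("window_bp must be positive")
  structure(list(r2_cutoff = r2_cutoff, window_bp = as.integer(window_bp)),
            class = "prune_config")
}

#' Greedy p-value-priority LD clumping
#'
#' Visits SNPs in ascending order of their summary p-value and retains each
#' one unless its dosage r-squared with an already-retained SNP on the same
#' chromosome within `window_bp` exceeds `r2_cutoff`. Ties in p are broken
#' by position, so the retained set is independent of input row order. A
#' pure r-squared pruning mode (`mode = "prune"`) visits SNPs by position
#' instead, ignoring p-values.
#'
#' @param panel A `"genotype_panel"` with `summary_stats`.
#' @param config A [prune_config()].
#' @param mode `"clump"` (default, p-value priority) or `"prune"`
#'   (position order).
#' @return Character vector of retained SNP ids.
#' @export
clump_snps <- function(panel, config = prune_config(),
                       mode = c("clump", "prune")) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(panel$summary_stats) && mode == "clump")
    stop("clumping needs summary p-values; run simulate_summary_stats() or supply them")
  map <- panel$snp_map
  if (any(unlist(tapply(map$pos, map$chr, function(p) diff(p) <= 0))))
    message("SNP map not position-sorted; visiting by sorted position")
  p <- if (mode == "clump") panel$summary_stats$p[match(map$id, panel$summary_stats$id)]
       else rep(0, nrow(map))
  visit <- if (mode == "clump") order(p, map$chr, map$pos) else
    order(map$chr, map$pos)
  dos <- panel$dosages
  retained <- integer(0)
  for (j in visit) {
    keep <- TRUE
    cand <- retained[map$chr[retained] == map$chr[j] &
                       abs(map$pos[retained] - map$pos[j]) <= config$window_bp]
    for (k in cand) {
      r <- suppressWarnings(cor(dos[, j], dos[, k]))
      if (!is.na(r) && r^2 > config$r2_cutoff) { keep <- FALSE; break }
    }
    if (keep) retained <- c(retained, j)
  }
  map$id[sort(retained)]
}

#' Weighted-allele-sum polygenic score
#'
#' For each individual, sums dosages of the retained SNPs whose summary
#' p-value is at or below the threshold, weighted by the reported effect
#' size: `score_i = sum_j dosage_ij * beta_j`. Missing dosages are imputed
#' as twice the allele frequency (mean imputation), with a flag.
#'
#' @param panel A `"genotype_panel"` with `summary_stats`.
#' @param retained_ids SNP ids surviving clumping (subset of the map).
#' @param p_threshold Include SNPs with `p <= p_threshold`, in (0, 1].
#' @return Numeric scores, one per individual; attribute `n_snps` records
#'   how many SNPs entered, `imputed` how many dosages were mean-imputed.
#'   Zero SNPs passing gives all-zero scores with a warning.
#' @export
compute_gps <- function(panel, retained_ids, p_threshold = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  ss <- panel$summary_stats
  if (is.null(ss)) stop("panel has no summary statistics")
  if (p_threshold <= 0 || p_threshold > 1)
    stop("p_threshold must lie in (0, 1]")
  if (!all(retained_ids %in% panel$snp_map$id))
    stop("retained ids must be a subset of the SNP map")
  idx <- match(retained_ids, panel$snp_map$id)
  pv <- ss$p[match(retained_ids, ss$id)]
  use <- idx[pv <= p_threshold]
  if (length(use) == 0) {
    warning("no SNP passes the p-value threshold; scores are all zero")
    return(structure(numeric(nrow(panel$dosages)), n_snps = 0L, imputed = 0L))
  }
  d <- panel$dosages[, use, drop = FALSE]
  n_imp <- sum(is.na(d))
  if (n_imp > 0) {
    fr <- panel$snp_map$freq[use]
    for (j in seq_along(use)) {
      nas <- is.na(d[, j])
      if (any(nas)) d[nas, j] <- 2 * fr[j]
    }
  }
  b <- ss$beta[match(panel$snp_map$id[use], ss$id)]
  structure(drop(d %*% b), n_snps = length(use), imputed = n_imp)
}

#' Principal-component correction of polygenic scores
#'
#' Computes principal components from the standardized dosage matrix and
#' replaces the scores by their OLS residuals on the first `n_pcs`
#' components, the standard guard against population stratification.
#' Rank-deficient panels fall back to the available rank with a warning.
#'
#' @param scores Numeric scores per individual.
#' @param panel A `"genotype_panel"`.
#' @param n_pcs Number of leading components to remove (default 10).
#' @return Residual scores (same length).
#' @export
pc_correct <- function(scores, panel, n_pcs = 10) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$dosages)
  if (n <= n_pcs) stop("need more individuals than components")
  g <- scale(panel$dosages)
  g[is.na(g)] <- 0  # monomorphic columns carry no structure
  pc <- prcomp(g, center = FALSE, scale. = FALSE, rank. = n_pcs)
  k <- min(n_pcs, ncol(pc$x))
  if (k < n_pcs)
    warning("genotype matrix supports only ", k, " components")
  resid(lm(scores ~ pc$x[, seq_len(k)]))
}

#' Nagelkerke pseudo R-squared
#'
#' Logistic regression of a binary outcome on a score;
#' `R2 = (1 - (L0/L1)^(2/n)) / (1 - L0^(2/n))` where `L0`, `L1` are the
#' null and fitted likelihoods. Invariant to affine rescaling of the
#' score; perfect separation reports 1 with a warning.
#'
#' @param y Binary 0/1 outcome with both classes present.
#' @param score Numeric predictor.
#' @return Value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(y, score) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("outcome must have both classes")
  n <- length(y)
  fit1 <- suppressWarnings(glm(y ~ score, family = binomial()))
  fit0 <- glm(y ~ 1, family = binomial())
  ll1 <- as.numeric(logLik(fit1)); ll0 <- as.numeric(logLik(fit0))
  if (!fit1$converged || ll1 > -1e-8) {
    warning("perfect separation; Nagelkerke R2 reported as 1")
    return(1)
  }
  cox_snell <- 1 - exp(2 * (ll0 - ll1) / n)
  max_r2 <- 1 - exp(2 * ll0 / n)
  min(max(cox_snell / max_r2, 0), 1)
}

#' High-resolution polygenic scoring over a p-value threshold grid
#'
#' Computes the polygenic score at every threshold from `grid_from` to 1
#' in steps of `grid_by` (default 0.001 to 1 by 0.001), regresses the
#' phenotype on each score and records the variance explained — ordinary
#' R-squared for continuous outcomes, Nagelkerke R-squared for binary —
#' and picks the most predictive threshold. Scores are accumulated
#' incrementally across the sorted p-values, so the full grid costs one
#' pass over the panel. Note the best-threshold R-squared is maximised
#' over the grid and is therefore slightly optimistic in finite samples.
#'
#' @param panel A `"genotype_panel"` with `summary_stats`.
#' @param phenotype Numeric (or 0/1) outcome, one per individual.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param retained_ids SNP ids to score (default: all; pass the result of
#'   [clump_snps()] for clumped scoring).
#' @param grid_from,grid_by Threshold grid definition.
#' @return A `"gps_result"`: `curve` (`data.frame` of `threshold`,
#'   `n_snps`, `variance_explained`), `best_threshold`, `best_r2`,
#'   `best_scores`, `n`. Methods: `print`, `plot`-ready curve.
#' @export
high_resolution_scoring <- function(panel, phenotype,
                                    outcome_type = c("continuous", "binary"),
                                    retained_ids = NULL,
                                    grid_from = 0.001, grid_by = 0.001) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(panel$summary_stats)) stop("panel has no summary statistics")
  if (sd(phenotype) == 0) stop("degenerate phenotype")
  retained_ids <- retained_ids %||% panel$snp_map$id
  idx <- match(retained_ids, panel$snp_map$id)
  ss <- panel$summary_stats
  pv <- ss$p[match(retained_ids, ss$id)]
  beta <- ss$beta[match(retained_ids, ss$id)]
  ord <- order(pv)
  idx <- idx[ord]; pv <- pv[ord]; beta <- beta[ord]
  thresholds <- seq(grid_from, 1, by = grid_by)
  n <- nrow(panel$dosages)
  score <- numeric(n)
  curve <- data.frame(threshold = thresholds, n_snps = NA_integer_,
                      variance_explained = NA_real_)
  scores_best <- score
  best <- -Inf; best_thr <- thresholds[1]
  taken <- 0L
  y <- phenotype
  for (i in seq_along(thresholds)) {
    thr <- thresholds[i]
    while (taken < length(pv) && pv[taken + 1L] <= thr) {
      taken <- taken + 1L
      score <- score + panel$dosages[, idx[taken]] * beta[taken]
    }
    curve$n_snps[i] <- taken
    r2 <- if (taken == 0L || sd(score) == 0) 0 else if
      (outcome_type == "continuous") cor(y, score)^2 else
      nagelkerke_r2(y, score)
    curve$variance_explained[i] <- r2
    if (r2 > best) { best <- r2; best_thr <- thr; scores_best <- score }
  }
  structure(list(curve = curve, best_threshold = best_thr, best_r2 = best,
                 best_scores = scores_best, n = n,
                 outcome_type = outcome_type),
            class = "gps_result")
}

#' @export
print.gps_result <- function(x, ...) {
  cat(sprintf("Polygenic score threshold scan (%s outcome, n = %d)\n",
              x$outcome_type, x$n))
  cat(sprintf("  best threshold p <= %.3f (%d SNPs): variance explained = %.4f\n",
              x$best_threshold,
              x$curve$n_snps[match(x$best_threshold, x$curve$threshold)],
              x$best_r2))
  invisible(x)
}

#' @export
plot.gps_result <- function(x, ...) {
  plot(x$curve$threshold, x$curve$variance_explained, type = "l",
       xlab = "p-value threshold", ylab = "variance explained", ...)
  graphics::abline(v = x$best_threshold, lty = 2)
  invisible(x)
}
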