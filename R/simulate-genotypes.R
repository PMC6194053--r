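#' Simulate a genotype dosage panel with block LD
#'
#' Generates biallelic SNP dosages (0-2 scale) for unrelated individuals.
#' SNPs are organised in linkage-disequilibrium (LD) blocks: within a block,
#' pairwise dosage r-squared is approximately `within_block_r2`; across
#' blocks SNPs are independent. Each SNP's two alleles are drawn as
#' thresholded latent Gaussians (one per haplotype), which keeps per-SNP
#' margins Hardy-Weinberg while giving controllable block correlation; the
#' latent equicorrelation is solved numerically so the *dosage* correlation
#' hits the target despite threshold attenuation. Allele frequencies are
#' Uniform(0.05, 0.5). Positions are assigned so each block spans well under
#' 250 kb and consecutive blocks are separated by 1 Mb.
#'
#' @param n_ind Number of individuals.
#' @param n_snps Number of SNPs (>= 1).
#' @param block_size SNPs per LD block.
#' @param within_block_r2 Target within-block dosage r-squared, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `"genotype_panel"` list: `dosages` (n_ind x n_snps matrix),
#'   `snp_map` (`data.frame`: `chr`, `pos`, `id`, `effect_allele`,
#'   `other_allele`, `freq`), and `summary_stats` (`NULL` until
#'   [simulate_summary_stats()] is applied).
#' @export
simulate_genotype_panel <- function(n_ind, n_snps, block_size = 5,
                                    within_block_r2 = 0.8, seed = 1) {
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (within_block_r2 >= 1 || within_block_r2 < 0)
    stop("within_block_r2 must lie in [0, 1)")
  with_seed(seed, {
    n_blocks <- ceiling(n_snps / block_size)
    block <- rep(seq_len(n_blocks), each = block_size)[seq_len(n_snps)]
    ## SNPs in tight LD share an allele frequency (one draw per block);
    ## the marginal frequency distribution stays Uniform(0.05, 0.5)
    block_freq <- runif(n_blocks, 0.05, 0.5)
    freq <- block_freq[block]
    target_r <- sqrt(within_block_r2)
    dos <- matrix(0, n_ind, n_snps)
    for (b in seq_len(n_blocks)) {
      idx <- which(block == b)
      m <- length(idx)
      rho <- if (m == 1 || target_r == 0) 0 else
        latent_rho_for_dosage_r(target_r, block_freq[b])
      R <- matrix(rho, m, m); diag(R) <- 1
      thr <- qnorm(freq[idx])  # allele present when latent < threshold
      h1 <- rmvn(n_ind, rep(0, m), R)
      h2 <- rmvn(n_ind, rep(0, m), R)
      dos[, idx] <- (sweep(h1, 2, thr, `<`) + sweep(h2, 2, thr, `<`)) * 1
    }
    ## positions: blocks of ~block_size SNPs spaced 5 kb apart inside a
    ## block (span < 250 kb for block_size <= 50), blocks 1 Mb apart
    pos <- integer(n_snps)
    for (b in seq_len(n_blocks)) {
      idx <- which(block == b)
      pos[idx] <- (b - 1L) * 1000000L + 10000L + (seq_along(idx) - 1L) * 5000L
    }
    snp_map <- data.frame(
      chr = 1L, pos = pos, id = sprintf("rs%06d", seq_len(n_snps)),
      effect_allele = "A", other_allele = "G", freq = freq,
      stringsAsFactors = FALSE)
    structure(list(dosages = dos, snp_map = snp_map, summary_stats = NULL),
              class = "genotype_panel")
  })
}

## Solve the latent equicorrelation rho so two equally-thresholded binary
## indicators (allele frequency p) have phi correlation target_r; the
## dosage (sum of two independent haplotypes) inherits the same correlation.
latent_rho_for_dosage_r <- function(target_r, p) {
  if (target_r <= 0) return(0)
  t <- qnorm(p)
  phi_of <- function(rho) {
    p11 <- pbvn(t, t, rho)
    (p11 - p^2) / (p * (1 - p))
  }
  if (phi_of(0.9999) <= target_r) return(0.9999)
  uniroot(function(r) phi_of(r) - target_r, c(0, 0.9999), tol = 1e-8)$root
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d individuals x %d SNPs%s\n",
              nrow(x$dosages), ncol(x$dosages),
              if (is.null(x$summary_stats)) ""
              else sprintf(" (+ summary stats, %d causal)",
                           sum(x$summary_stats$beta_true != 0))))
  invisible(x)
}

#' Attach simulated GWAS summary statistics to a panel
#'
#' Chooses `n_causal` causal SNPs (spread across LD blocks) with
#' standardized true effects of magnitude `effect_size` and random sign,
#' then emulates a discovery genome-wide association study of size
#' `discovery_n`: the reported per-SNP beta equals the true beta plus
#' normal estimation noise with standard error `1/sqrt(discovery_n)` on
#' the standardized-genotype scale, and the p-value comes from the
#' corresponding two-sided Wald statistic. Betas are stored on the dosage
#' scale for direct use in scoring.
#'
#' @param panel A `"genotype_panel"`.
#' @param n_causal Number of causal SNPs (`<= n_snps`).
#' @param discovery_n Discovery-study sample size (>= 2).
#' @param effect_size Standardized per-SNP true effect magnitude.
#' @param seed Integer seed.
#' @return The panel with `summary_stats` filled: `id`, `effect_allele`,
#'   `beta`, `p`, plus `beta_true` and `se` kept for diagnostics.
#' @export
simulate_summary_stats <- function(panel, n_causal, discovery_n,
                                   effect_size = 0.02, seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  m <- ncol(panel$dosages)
  if (n_causal > m) stop("n_causal must be <= number of SNPs")
  if (discovery_n < 2) stop("discovery_n must be >= 2")
  with_seed(seed, {
    sds <- apply(panel$dosages, 2, sd)
    sds[sds == 0] <- 1
    beta_true_std <- numeric(m)
    if (n_causal > 0) {
      causal <- if (n_causal == m) seq_len(m) else
        sort(sample.int(m, n_causal))
      beta_true_std[causal] <- effect_size * sample(c(-1, 1), n_causal,
                                                   replace = TRUE)
    }
    se <- 1 / sqrt(discovery_n)
    beta_hat_std <- beta_true_std + rnorm(m, 0, se)
    z <- beta_hat_std / se
    p <- 2 * pnorm(-abs(z))
    p <- pmax(p, 1e-300)
    panel$summary_stats <- data.frame(
      id = panel$snp_map$id,
      effect_allele = panel$snp_map$effect_allele,
      beta = beta_hat_std / sds,        # dosage scale
      p = p,
      beta_true = beta_true_std / sds,
      se = se / sds,
      stringsAsFactors = FALSE)
    panel
  })
}

#' Attach a phenotype with a specified true-score R-squared
#'
#' Builds the standardized true polygenic score from the panel's true
#' effects and sets `phenotype = sqrt(target_r2) * score + residual` so the
#' population variance explained by the true score equals `target_r2` and
#' the phenotype has unit variance. With `prevalence` given, the continuous
#' construction is treated as a liability and dichotomised.
#'
#' @param panel A panel with `summary_stats` (from
#'   [simulate_summary_stats()]).
#' @param target_r2 Population R-squared of the true score, in `[0, 1)`.
#' @param seed Integer seed.
#' @param prevalence Optional; if given, return a 0/1 trait with this
#'   expected prevalence on the liability scale.
#' @return A `data.frame`: `id`, `phenotype`, `true_score` (standardized).
#' @export
attach_gps_phenotype <- function(panel, target_r2, seed = 1,
                                 prevalence = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(panel$summary_stats))
    stop("panel has no summary statistics; run simulate_summary_stats() first")
  if (target_r2 >= 1 || target_r2 < 0) stop("target_r2 must lie in [0, 1)")
  n <- nrow(panel$dosages)
  with_seed(seed, {
    raw <- drop(panel$dosages %*% panel$summary_stats$beta_true)
    s <- sd(raw)
    score <- if (s > 0) (raw - mean(raw)) / s else raw * 0
    lam <- sqrt(target_r2)
    phen <- lam * score + sqrt(1 - target_r2) * rnorm(n)
    if (!is.null(prevalence)) {
      if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
      phen <- as.integer(phen > qnorm(1 - prevalence))
    }
    data.frame(id = sprintf("ind%05d", seq_len(n)),
               phenotype = phen, true_score = score,
               stringsAsFactors = FALSE)
  })
}
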