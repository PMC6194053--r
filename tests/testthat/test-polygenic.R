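test_that("genotype panel has calibrated frequencies, LD blocks and positions", {
  panel <- simulate_genotype_panel(2000, 200, block_size = 5,
                                  within_block_r2 = 0.8, seed = 201)
  expect_true(all(panel$dosages %in% 0:2))
  ## allele-frequency consistency
  est <- colMeans(panel$dosages) / 2
  expect_lt(max(abs(est - panel$snp_map$freq)), 0.03)
  ## within-block dosage r-squared near target
  r2s <- unlist(lapply(split(seq_len(200), rep(1:40, each = 5)), function(idx) {
    cm <- cor(panel$dosages[, idx])^2
    cm[upper.tri(cm)]
  }))
  expect_gt(mean(r2s), 0.7)
  expect_lt(mean(r2s), 0.9)
  ## across-block independence when requested
  flat <- simulate_genotype_panel(2000, 100, block_size = 5,
                                  within_block_r2 = 0, seed = 202)
  cm <- cor(flat$dosages)
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.02)
  ## positions strictly increasing within chromosome
  expect_true(all(tapply(panel$snp_map$pos, panel$snp_map$chr,
                         function(p) all(diff(p) > 0))))
  expect_error(simulate_genotype_panel(10, 10, within_block_r2 = 1),
               "within_block_r2")
})

test_that("summary statistics behave under the null and with power", {
  panel <- simulate_genotype_panel(200, 400, block_size = 4,
                                  within_block_r2 = 0.3, seed = 203)
  null <- simulate_summary_stats(panel, n_causal = 0, discovery_n = 5e4,
                                 seed = 204)
  expect_true(all(null$summary_stats$beta_true == 0))
  ks <- suppressWarnings(ks.test(null$summary_stats$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  ## power: Wald noncentrality 0.02 * sqrt(1e5) ~ 6.3, essentially all
  ## causal SNPs significant; well above the 5% null rate
  pow <- simulate_summary_stats(panel, n_causal = 200, discovery_n = 1e5,
                                effect_size = 0.02, seed = 205)
  causal <- pow$summary_stats$beta_true != 0
  expect_gt(mean(pow$summary_stats$p[causal] <= 0.05), 0.05)
  ## vanishing estimation noise at huge discovery n
  exact <- simulate_summary_stats(panel, n_causal = 50, discovery_n = 1e12,
                                  seed = 206)
  expect_lt(max(abs(exact$summary_stats$beta - exact$summary_stats$beta_true)),
            1e-3)
  expect_error(simulate_summary_stats(panel, 1000, 1e4), "<= number")
})

test_that("phenotype attachment hits the target variance explained", {
  ## population contract: at large n the true-score R2 pins the target
  panel <- tiny_panel(n_ind = 20000, n_snps = 300, seed = 207, n_causal = 100)
  ph <- attach_gps_phenotype(panel, target_r2 = 0.04, seed = 208)
  expect_equal(var(ph$phenotype), 1, tolerance = 0.05)
  r2 <- summary(lm(ph$phenotype ~ ph$true_score))$r.squared
  expect_equal(r2, 0.04, tolerance = 0.006 / 0.04)
  ## zero target: no association
  ph0 <- attach_gps_phenotype(panel, target_r2 = 0, seed = 209)
  expect_lt(summary(lm(ph0$phenotype ~ ph0$true_score))$r.squared, 0.01)
  ## binary variant honours prevalence
  phb <- attach_gps_phenotype(panel, 0.05, seed = 210, prevalence = 0.57)
  expect_true(all(phb$phenotype %in% 0:1))
  expect_equal(mean(phb$phenotype), 0.57, tolerance = 0.05 / 0.57)
})

test_that("greedy clumping follows p-value priority within the window", {
  ## three co-located SNPs in strong LD with p = 1e-8, 1e-4, 1e-2: only
  ## the most significant survives
  set.seed(211)
  base <- rbinom(500, 2, 0.3)
  flip <- function(x) { i <- sample(500, 25); x[i] <- 2 - x[i]; x }
  dos <- cbind(base, flip(base), flip(base), rbinom(500, 2, 0.4))
  panel <- structure(list(
    dosages = dos,
    snp_map = data.frame(chr = 1L, pos = c(1000L, 2000L, 3000L, 500000L),
                         id = paste0("s", 1:4), effect_allele = "A",
                         other_allele = "G", freq = c(0.3, 0.3, 0.3, 0.4)),
    summary_stats = data.frame(id = paste0("s", 1:4), effect_allele = "A",
                               beta = c(0.1, 0.2, 0.3, 0.1),
                               p = c(1e-8, 1e-4, 1e-2, 0.5))),
    class = "genotype_panel")
  kept <- clump_snps(panel, prune_config(0.1, 250000))
  expect_identical(kept, c("s1", "s4"))
  ## row order must not matter
  perm <- c(3, 1, 4, 2)
  panel2 <- panel
  panel2$dosages <- panel2$dosages[, perm]
  panel2$snp_map <- panel2$snp_map[perm, ]
  panel2$summary_stats <- panel2$summary_stats[perm, ]
  expect_setequal(clump_snps(panel2, prune_config(0.1, 250000)), kept)
  ## generous cutoff keeps everything
  expect_length(clump_snps(panel, prune_config(1, 250000)), 4)
  ## distant SNPs are never compared: shrink the window and all survive
  expect_length(clump_snps(panel, prune_config(0.1, 500)), 4)
})

test_that("score computation matches hand arithmetic and a double-loop oracle", {
  panel <- structure(list(
    dosages = matrix(c(0, 1, 2), 1, 3),
    snp_map = data.frame(chr = 1L, pos = c(100L, 200L, 300L),
                         id = c("a", "b", "c"), effect_allele = "A",
                         other_allele = "G", freq = 0.3),
    summary_stats = data.frame(id = c("a", "b", "c"), effect_allele = "A",
                               beta = c(0.1, -0.2, 0.3), p = c(0.01, 0.02, 0.03))),
    class = "genotype_panel")
  s <- compute_gps(panel, c("a", "b", "c"), 1)
  expect_equal(as.numeric(s), 0.4, tolerance = 1e-12)
  ## linearity in the weights
  panel2 <- panel
  panel2$summary_stats$beta <- panel2$summary_stats$beta * 2
  expect_equal(as.numeric(compute_gps(panel2, c("a", "b", "c"), 1)), 0.8)
  ## double-loop oracle on a random 10 x 20 fixture, exact equality
  big <- tiny_panel(n_ind = 10, n_snps = 20, seed = 212)
  ids <- big$snp_map$id[c(2, 5, 7, 11, 19)]
  thr <- 0.6
  got <- compute_gps(big, ids, thr)
  oracle <- numeric(10)
  for (i in 1:10) {
    acc <- 0
    for (id in ids) {
      j <- match(id, big$snp_map$id)
      pj <- big$summary_stats$p[match(id, big$summary_stats$id)]
      if (pj <= thr)
        acc <- acc + big$dosages[i, j] *
          big$summary_stats$beta[match(id, big$summary_stats$id)]
    }
    oracle[i] <- acc
  }
  expect_equal(as.numeric(got), oracle, tolerance = 1e-14)
  ## empty threshold: zero scores with a warning
  expect_warning(z <- compute_gps(big, ids, 1e-30), "no SNP")
  expect_true(all(z == 0))
})

test_that("missing dosages are mean-imputed during scoring", {
  big <- tiny_panel(n_ind = 20, n_snps = 10, seed = 213)
  big$dosages[1, 3] <- NA
  s <- compute_gps(big, big$snp_map$id, 1)
  expect_equal(attr(s, "imputed"), 1L)
  manual <- big$dosages
  manual[1, 3] <- 2 * big$snp_map$freq[3]
  expect_equal(as.numeric(s),
               as.numeric(manual %*% big$summary_stats$beta))
})

test_that("PC correction removes structure and only structure", {
  panel <- tiny_panel(n_ind = 200, n_snps = 80, seed = 214)
  set.seed(215)
  score <- rnorm(200)
  corrected <- pc_correct(score, panel, n_pcs = 10)
  expect_gt(cor(corrected, score), 0.9)
  ## a score that is exactly PC1 vanishes
  g <- scale(panel$dosages); g[is.na(g)] <- 0
  pc1 <- prcomp(g, center = FALSE)$x[, 1]
  expect_lt(var(pc_correct(pc1, panel, 10)), var(pc1) * 1e-6)
  ## two diverged subpopulations: correction shrinks the label signal
  withr::with_seed(216, {
    n <- 300; m <- 150
    lab <- rep(0:1, each = n / 2)
    f1 <- runif(m, 0.1, 0.5); f2 <- pmin(f1 + runif(m, 0.05, 0.25), 0.95)
    dos <- t(vapply(lab, function(l)
      rbinom(m, 2, if (l == 0) f1 else f2), numeric(m)))
  })
  strat <- structure(list(
    dosages = dos,
    snp_map = data.frame(chr = 1L, pos = seq_len(m) * 1000L,
                         id = paste0("s", seq_len(m)), effect_allele = "A",
                         other_allele = "G", freq = (f1 + f2) / 2),
    summary_stats = NULL), class = "genotype_panel")
  raw_score <- dos %*% runif(m, -0.1, 0.1)
  corr_score <- pc_correct(raw_score, strat, 10)
  expect_lt(abs(cor(corr_score, lab)) / abs(cor(raw_score, lab)), 0.5)
})

test_that("Nagelkerke R2 matches likelihood arithmetic and its invariances", {
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  x <- c(-1.2, -0.8, -0.1, 0.3, 0.2, 0.9, 1.4, 2.0)
  got <- nagelkerke_r2(y, x)
  ## oracle: plug the two fitted likelihoods into the formula directly
  fit1 <- glm(y ~ x, family = binomial())
  p1 <- fitted(fit1)
  l1 <- prod(p1^y * (1 - p1)^(1 - y))
  p0 <- mean(y)
  l0 <- prod(p0^y * (1 - p0)^(1 - y))
  n <- length(y)
  oracle <- (1 - (l0 / l1)^(2 / n)) / (1 - l0^(2 / n))
  expect_equal(got, oracle, tolerance = 1e-8)
  ## affine invariance of the score
  expect_equal(nagelkerke_r2(y, 3 * x - 7), got, tolerance = 1e-6)
  ## independence gives ~0
  withr::with_seed(217, {
    yy <- rbinom(2000, 1, 0.5); xx <- rnorm(2000)
  })
  expect_lt(nagelkerke_r2(yy, xx), 0.01)
  expect_error(nagelkerke_r2(rep(1, 5), rnorm(5)), "both classes")
})

test_that("threshold scan is monotone in SNP count and consistent at threshold 1", {
  panel <- tiny_panel(n_ind = 500, n_snps = 200, seed = 218, n_causal = 50)
  ph <- attach_gps_phenotype(panel, 0.1, seed = 219)
  res <- high_resolution_scoring(panel, ph$phenotype, "continuous",
                                 grid_by = 0.01, grid_from = 0.01)
  expect_true(all(diff(res$curve$n_snps) >= 0))
  expect_equal(max(res$curve$variance_explained), res$best_r2)
  all_score <- compute_gps(panel, panel$snp_map$id, 1)
  r2_all <- cor(ph$phenotype, as.numeric(all_score))^2
  expect_equal(res$curve$variance_explained[nrow(res$curve)], r2_all,
               tolerance = 1e-10)
  ## binary outcome routes through Nagelkerke
  phb <- attach_gps_phenotype(panel, 0.1, seed = 220, prevalence = 0.5)
  resb <- high_resolution_scoring(panel, phb$phenotype, "binary",
                                  grid_by = 0.05, grid_from = 0.05)
  expect_true(all(resb$curve$variance_explained >= 0 &
                    resb$curve$variance_explained <= 1))
})

test_that("a null summary-stat grid yields only selection-bias-sized R2", {
  panel <- simulate_genotype_panel(3000, 5000, block_size = 5,
                                  within_block_r2 = 0.5, seed = 221)
  panel <- simulate_summary_stats(panel, n_causal = 0, discovery_n = 1e5,
                                  seed = 222)
  withr::with_seed(223, phen <- rnorm(3000))
  res <- high_resolution_scoring(panel, phen, "continuous")
  expect_gt(res$best_r2, 0)
  expect_lt(res$best_r2, 0.01)
})
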