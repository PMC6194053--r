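## Shared fixtures, built in code at test time.

## small genotype panel with summary stats for scoring tests
tiny_panel <- function(n_ind = 50, n_snps = 20, seed = 101,
                       n_causal = 5, discovery_n = 1e5) {
  panel <- simulate_genotype_panel(n_ind, n_snps, block_size = 4,
                                   within_block_r2 = 0.5, seed = seed)
  simulate_summary_stats(panel, n_causal = n_causal,
                         discovery_n = discovery_n, seed = seed + 1)
}

## independent bivariate-normal density, used by likelihood oracles
dbvn_log <- function(x1, x2, mu, v, r) {
  det <- v^2 * (1 - r^2)
  q <- ((x1 - mu)^2 - 2 * r * (x1 - mu) * (x2 - mu) + (x2 - mu)^2) /
    (v * (1 - r^2))
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

## brute-force -2lnL of the ACE model on raw pair data (independent of the
## package's sufficient-statistic implementation)
oracle_ace_neg2ll <- function(mz, dz, mu, v, a2, c2) {
  r_mz <- a2 + c2
  r_dz <- 0.5 * a2 + c2
  -2 * (sum(dbvn_log(mz[, 1], mz[, 2], mu, v, r_mz)) +
          sum(dbvn_log(dz[, 1], dz[, 2], mu, v, r_dz)))
}
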