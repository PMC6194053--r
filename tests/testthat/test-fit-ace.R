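test_that("optimiser matches an independent grid-search likelihood on a small fixture", {
  p <- ace_params(0.5, 0.2, 0.3)
  pairs <- simulate_ace_pairs(p, 100, 100, seed = 61)
  fit <- fit_ace(pairs, "trait")
  mz <- cbind(pairs$trait[pairs$zygosity == "MZ" & pairs$twin == 1],
              pairs$trait[pairs$zygosity == "MZ" & pairs$twin == 2])
  dz <- cbind(pairs$trait[pairs$zygosity == "DZ" & pairs$twin == 1],
              pairs$trait[pairs$zygosity == "DZ" & pairs$twin == 2])
  ## independent oracle: dense grid over the shares (a2, c2); for each
  ## grid point the common mean and total variance are profiled out in
  ## closed form (the deviance is quadratic in mu and monotone-convex in
  ## v), then the raw-data bivariate density is summed directly
  oracle_at <- function(a2, c2) {
    rs <- c(MZ = a2 + c2, DZ = 0.5 * a2 + c2)
    groups <- list(MZ = mz, DZ = dz)
    num <- den <- 0
    for (z in names(groups)) {
      x <- groups[[z]]
      num <- num + sum(x) / (1 + rs[z])
      den <- den + 2 * nrow(x) / (1 + rs[z])
    }
    mu <- num / den
    Q <- 0; N <- 0
    for (z in names(groups)) {
      x <- groups[[z]]; r <- rs[z]
      d1 <- x[, 1] - mu; d2 <- x[, 2] - mu
      Q <- Q + sum(d1^2 - 2 * r * d1 * d2 + d2^2) / (1 - r^2)
      N <- N + nrow(x)
    }
    v <- Q / (2 * N)
    oracle_ace_neg2ll(mz, dz, mu, v, a2, c2)
  }
  best <- Inf
  for (a2 in seq(0, 0.99, by = 0.01))
    for (c2 in seq(0, 0.99 - a2, by = 0.01))
      best <- min(best, oracle_at(a2, c2))
  expect_lt(abs(fit$minus2ll - best), 0.05)
})

test_that("null and non-null generating shares are recovered", {
  null <- simulate_ace_pairs(ace_params(0, 0, 1), 2000, 2000, seed = 62)
  f0 <- fit_ace(null, "trait")
  expect_lt(f0$shares["a2"], 0.05)
  expect_lt(f0$shares["c2"], 0.05)
  p <- ace_params(0.57, 0.07, 0.36)
  f1 <- fit_ace(simulate_ace_pairs(p, 2000, 2000, seed = 63), "trait")
  expect_equal(unname(f1$shares["a2"]), 0.57, tolerance = 0.07 / 0.57)
  expect_equal(unname(sum(f1$shares)), 1, tolerance = 1e-8)
  ## AE fit drops C exactly
  fae <- fit_ace(simulate_ace_pairs(ace_params(0.46, 0, 0.54),
                                    1000, 1000, seed = 64), "trait", "AE")
  expect_identical(unname(fae$shares["c2"]), 0)
})

test_that("likelihood nesting chain holds on arbitrary data", {
  for (s in c(65, 66)) {
    pairs <- simulate_ace_pairs(ace_params(0.4, 0.3, 0.3), 300, 300, seed = s)
    sat <- fit_saturated(pairs, "trait", equate = "none")
    sat_eq <- fit_saturated(pairs, "trait")
    ace <- fit_ace(pairs, "trait", "ACE")
    ae <- fit_ace(pairs, "trait", "AE")
    ce <- fit_ace(pairs, "trait", "CE")
    e <- fit_ace(pairs, "trait", "E")
    tol <- 1e-4
    expect_lte(sat$minus2ll, sat_eq$minus2ll + tol)
    expect_lte(sat_eq$minus2ll, ace$minus2ll + tol)
    expect_lte(ace$minus2ll, ae$minus2ll + tol)
    expect_lte(ace$minus2ll, ce$minus2ll + tol)
    expect_lte(ae$minus2ll, e$minus2ll + tol)
    expect_lte(ce$minus2ll, e$minus2ll + tol)
  }
})

test_that("saturated estimates equal sample moments and tolerate exchangeable equating", {
  pairs <- simulate_ace_pairs(ace_params(0.5, 0.2, 0.3), 400, 400, seed = 67)
  sat <- fit_saturated(pairs, "trait", equate = "none")
  w <- pairs[pairs$zygosity == "MZ", ]
  x <- cbind(w$trait[w$twin == 1], w$trait[w$twin == 2])
  expect_equal(sat$estimates$MZ$mean, colMeans(x), tolerance = 1e-6)
  n <- nrow(x)
  expect_equal(sat$estimates$MZ$cov, cov(x) * (n - 1) / n, tolerance = 1e-6)
  ## data are exchangeable by construction: equating costs little fit
  sat_eq <- fit_saturated(pairs, "trait")
  expect_lt(sat_eq$minus2ll - sat$minus2ll, qchisq(0.999, 4))
})

test_that("likelihood-ratio comparison arithmetic and guards", {
  pairs <- simulate_ace_pairs(ace_params(0.5, 0.2, 0.3), 300, 300, seed = 68)
  ace <- fit_ace(pairs, "trait")
  ae <- fit_ace(pairs, "trait", "AE")
  cmp <- compare_models(ace, ae)
  expect_equal(cmp$chi_square, ae$minus2ll - ace$minus2ll, tolerance = 1e-10)
  expect_equal(cmp$df_diff, 1)
  expect_equal(cmp$p_value, pchisq(cmp$chi_square, 1, lower.tail = FALSE))
  expect_equal(cmp$aic_full, ace$aic)
  ## same model twice: no parameter reduction to test
  expect_error(compare_models(ace, ace), "fewer free parameters")
  ## a better-fitting "nested" model signals a refit
  expect_error(compare_models(ae, ace), "refit")
})

test_that("AE-vs-ACE rejection rate is conservative when C is absent", {
  reject <- vapply(1:120, function(i) {
    pairs <- simulate_ace_pairs(ace_params(0.5, 0, 0.5), 500, 500,
                                seed = 7000 + i)
    full <- fit_ace(pairs, "trait", "ACE", n_starts = 3)
    nested <- fit_ace(pairs, "trait", "AE", n_starts = 3)
    compare_models(full, nested)$p_value < 0.05
  }, logical(1))
  ## boundary chi-square mixture: at most nominal, allow Monte-Carlo slack
  expect_lte(mean(reject), 0.07 + 2 * sqrt(0.05 * 0.95 / 120))
})

test_that("CE-vs-ACE comparison has power against real additive variance", {
  reject <- vapply(1:40, function(i) {
    pairs <- simulate_ace_pairs(ace_params(0.5, 0.2, 0.3), 2000, 2000,
                                seed = 7500 + i)
    full <- fit_ace(pairs, "trait", "ACE", n_starts = 3)
    nested <- fit_ace(pairs, "trait", "CE", n_starts = 3)
    compare_models(full, nested)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.8)
})

test_that("parsimony selection never keeps AE when C is strong", {
  picks <- vapply(1:20, function(i) {
    pairs <- simulate_ace_pairs(ace_params(0.3, 0.4, 0.3), 2000, 2000,
                                seed = 7700 + i)
    full <- fit_ace(pairs, "trait", "ACE", n_starts = 3)
    nested <- list(AE = fit_ace(pairs, "trait", "AE", n_starts = 3),
                   CE = fit_ace(pairs, "trait", "CE", n_starts = 3),
                   E = fit_ace(pairs, "trait", "E"))
    select_model(full, nested)
  }, character(1))
  expect_false(any(picks == "AE"))
})

test_that("profile intervals respect bounds, cover and tighten with n", {
  p <- ace_params(0.5, 0.2, 0.3)
  small <- fit_ace(simulate_ace_pairs(p, 500, 500, seed = 71), "trait")
  big <- fit_ace(simulate_ace_pairs(p, 2000, 2000, seed = 71), "trait")
  ci_s <- confint(small); ci_b <- confint(big)
  expect_true(all(ci_s[, "lower"] <= small$shares[rownames(ci_s)] + 1e-6))
  expect_true(all(ci_s[, "upper"] >= small$shares[rownames(ci_s)] - 1e-6))
  ## e2 interval is bounded away from zero (residual variance always present)
  expect_gt(ci_s["e2", "lower"], 0)
  ## quadrupling pairs tightens every interval
  expect_true(all((ci_b[, 2] - ci_b[, 1]) < (ci_s[, 2] - ci_s[, 1])))
})

test_that("missing co-twin phenotypes enter through the marginal likelihood", {
  pairs <- simulate_ace_pairs(ace_params(0.5, 0.2, 0.3), 800, 800, seed = 72)
  holed <- pairs
  drop_idx <- which(holed$twin == 2 & holed$family_id %in% 1:100)
  holed$trait[drop_idx] <- NA
  f_full <- fit_ace(pairs, "trait")
  f_holed <- fit_ace(holed, "trait")
  expect_equal(unname(f_holed$shares["a2"]), unname(f_full$shares["a2"]),
               tolerance = 0.1)
  ## singleton contribution strictly increases the deviance versus
  ## dropping the broken families entirely
  dropped <- holed[!(holed$family_id %in% 1:100), ]
  f_dropped <- fit_ace(dropped, "trait")
  expect_gt(f_holed$minus2ll, f_dropped$minus2ll)
})

test_that("simulate method round-trips the fitted generating process", {
  p <- ace_params(0.6, 0.1, 0.3)
  fit <- fit_ace(simulate_ace_pairs(p, 1500, 1500, seed = 73), "trait")
  re <- simulate(fit, seed = 74)
  refit <- fit_ace(re, "trait")
  expect_equal(unname(refit$shares["a2"]), unname(fit$shares["a2"]),
               tolerance = 0.08)
})
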