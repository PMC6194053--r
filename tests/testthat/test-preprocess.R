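test_that("van der Waerden transform matches the closed form and preserves ranks", {
  z <- van_der_waerden(c(1, 2, 3))
  expect_equal(as.numeric(z), qnorm(c(0.25, 0.5, 0.75)), tolerance = 1e-4)
  ## odd length, tie-free: middle observation maps to zero
  x <- c(10, -3, 5, 7, 0.2)
  z2 <- as.numeric(van_der_waerden(x))
  expect_equal(z2[x == 5], 0)
  expect_equal(cor(rank(x), rank(z2)), 1)
  ## ties get mid-ranks
  z3 <- as.numeric(van_der_waerden(c(1, 2, 2, 3)))
  expect_equal(z3[2], z3[3])
  expect_equal(z3[2], qnorm(2.5 / 5))
  ## idempotent in rank: reapplication preserves the ordering exactly
  z4 <- as.numeric(van_der_waerden(z2))
  expect_equal(rank(z4), rank(z2))
  expect_error(van_der_waerden(rep(1, 5)), "distinct")
})

test_that("covariate regression is orthogonal and handles degenerate input", {
  set.seed(5)
  n <- 300
  age <- rnorm(n, 18, 0.5); sex <- rbinom(n, 1, 0.5)
  y <- 0.3 * age - 0.2 * sex + rnorm(n)
  r <- regress_covariates(y, data.frame(age = age, sex = sex))
  expect_lt(abs(cor(as.numeric(r), age)), 1e-8)
  expect_lt(abs(cor(as.numeric(r), sex)), 1e-8)
  expect_equal(mean(as.numeric(r)), 0, tolerance = 1e-10)
  ## perfect fit leaves nothing
  r2 <- regress_covariates(2 * age, data.frame(age = age))
  expect_lt(max(abs(as.numeric(r2))), 1e-10)
  ## constant covariate dropped with warning, falls back to centering
  expect_warning(r3 <- regress_covariates(y, data.frame(k = rep(1, n))),
                 "constant")
  expect_equal(as.numeric(r3), y - mean(y))
  ## NA trait values pass through, covariates still used for the rest
  y_na <- y; y_na[1:5] <- NA
  r4 <- regress_covariates(y_na, data.frame(age = age))
  expect_true(all(is.na(as.numeric(r4)[1:5])))
})

test_that("trait-on-trait residualization recovers the OLS decomposition", {
  set.seed(6)
  x <- rnorm(500)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(500)
  raw <- residualize_on_trait(y, x, standardize = FALSE)
  expect_lt(abs(cor(as.numeric(raw), x)), 1e-8)
  expect_equal(var(as.numeric(raw)), (1 - cor(y, x)^2) * var(y),
               tolerance = 1e-6)
  std <- residualize_on_trait(y, x)
  expect_equal(sd(as.numeric(std)), 1, tolerance = 1e-10)
  expect_lt(max(abs(as.numeric(residualize_on_trait(x, x)))), 1e-10)
  expect_error(residualize_on_trait(y[1:2], x[1:2]), "3 complete")
})

test_that("pipeline order is regress-then-transform and is recorded", {
  set.seed(7)
  y <- rnorm(100); cov <- data.frame(age = rnorm(100))
  p <- prepare_trait(y, cov)
  expect_equal(attr(p, "provenance"),
               c("ols_residual(age)", "van_der_waerden"))
  p2 <- prepare_trait(y, cov, transform_first = TRUE)
  expect_equal(attr(p2, "provenance"),
               c("van_der_waerden", "ols_residual(age)"))
})

test_that("sex-by-zygosity ANOVA eta-squared matches hand-computed sums of squares", {
  ## 20-row fixture, balanced 2x2 design with 5 per cell
  trait <- c(1, 2, 3, 4, 5,   2, 3, 4, 5, 6,
             3, 4, 5, 6, 7,   3, 3, 4, 6, 9)
  sex <- rep(c(0, 1), each = 10)
  zyg <- rep(rep(c("MZ", "DZ"), each = 5), 2)
  out <- sex_zygosity_anova(trait, sex, zyg)
  ## brute-force sequential sums of squares for the balanced design
  gm <- mean(trait)
  ss_tot <- sum((trait - gm)^2)
  m_sex <- tapply(trait, sex, mean)
  ss_sex <- sum(10 * (m_sex - gm)^2)
  m_zyg <- tapply(trait, zyg, mean)
  ss_zyg <- sum(10 * (m_zyg - gm)^2)
  m_cell <- tapply(trait, interaction(sex, zyg), mean)
  ss_cells <- sum(5 * (m_cell - gm)^2)
  ss_int <- ss_cells - ss_sex - ss_zyg
  expect_equal(out$eta_sq[out$term == "sex"], ss_sex / ss_tot,
               tolerance = 1e-10)
  expect_equal(out$eta_sq[out$term == "zygosity"], ss_zyg / ss_tot,
               tolerance = 1e-10)
  expect_equal(out$eta_sq[out$term == "sex:zygosity"], ss_int / ss_tot,
               tolerance = 1e-10)
  ## sex indicator trait: all variance to sex
  out2 <- sex_zygosity_anova(as.numeric(sex) + rnorm(20, 0, 1e-8), sex, zyg)
  expect_gt(out2$eta_sq[out2$term == "sex"], 0.999)
  ## independence at large n: cumulative variance explained under 1%
  set.seed(8)
  n <- 10000
  out3 <- sex_zygosity_anova(rnorm(n), rbinom(n, 1, 0.5),
                             sample(c("MZ", "DZ"), n, replace = TRUE))
  expect_lt(out3$eta_sq[out3$term == "total"], 0.01)
})

test_that("sensitivity t-test matches hand arithmetic and detects no inflation under the null", {
  g1 <- c(1, 2, 3); g2 <- c(2, 4, 6)
  res <- sensitivity_t_test(c(g1, g2), c(1, 1, 1, 0, 0, 0))
  ## Welch t by hand
  se <- sqrt(var(g1) / 3 + var(g2) / 3)
  expect_equal(res$t, (mean(g1) - mean(g2)) / se, tolerance = 1e-12)
  expect_equal(res$variance_explained,
               cor(c(g1, g2), c(1, 1, 1, 0, 0, 0))^2, tolerance = 1e-12)
  ## identical distributions, large n: under 1% variance explained
  set.seed(9)
  out <- sensitivity_t_test(rnorm(4000), rbinom(4000, 1, 0.55))
  expect_lt(out$variance_explained, 0.01)
  ## equal means give t near zero
  expect_lt(abs(sensitivity_t_test(c(1, 2, 3, 1, 2, 3),
                                   c(1, 1, 1, 0, 0, 0))$t), 1e-10)
  expect_error(sensitivity_t_test(1:5, c(1, 0, 0, 0, 0)), ">= 2 members")
})
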