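---
title: "Twin variance decomposition and polygenic scoring: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin variance decomposition and polygenic scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpgs)
```

## The problem

University outcomes — entrance-exam achievement, whether a student
enrols, the league-table rank of the institution, and the final degree
grade — cluster in families. The classical twin design separates that
clustering into additive genetic (A), shared environmental (C) and
non-shared environmental (E) sources by comparing monozygotic (MZ) twins,
who share all segregating alleles, with dizygotic (DZ) twins, who share
half on average. Twin-registry data of this kind are access-controlled,
so `twinpgs` couples every estimator with a synthetic-data generator that
produces cohorts with exactly the covariance structure the models assume.
Every claim the package makes about its estimators is then testable as
parameter recovery: simulate under known values, refit, compare.

## The univariate ACE model

For a standardized trait the pair vector of twin $j$ in zygosity group
$z$ is modelled as bivariate normal with common mean $\mu$, variance $v$,
and within-pair correlation

$$r_{MZ} = a^2 + c^2, \qquad r_{DZ} = \tfrac12 a^2 + c^2,$$

where $a^2 + c^2 + e^2 = 1$ are the standardized variance shares. The
coefficient $\tfrac12$ is the expected additive-genetic sharing of DZ
pairs; C is shared fully by both kinds of pair; E (which also absorbs
measurement error) is not shared. Assumptions inherited from the design:
equal environments across zygosity, no assortative mating, no dominance
or epistasis, no gene–environment interaction; opposite- and same-sex DZ
pairs are pooled and no sex-limitation structure is fitted.

`fit_ace()` maximises this likelihood directly. Numerical choices:

* **Parameterisation.** Shares are stick-broken as $a^2 = p$,
  $c^2 = (1-p)q$, $e^2 = (1-p)(1-q)$ with $p, q \in [0,1]$, so box
  constraints alone keep the simplex and submodels (AE, CE, E) are exact
  restrictions ($q = 0$, $p = 0$, both). Path coefficients are reported
  as $\sqrt{\text{share}}$, i.e. constrained non-negative — the sign is
  not identified.
* **Optimiser.** Bounded L-BFGS-B from a moment-based start (Falconer
  estimates from the observed double-entry correlations) plus nine
  deterministic random restarts (fixed internal seed); convergence at
  `factr = 1e4`. The likelihood is evaluated through per-group
  sufficient statistics, so cost is independent of the number of pairs.
* **Missing co-twins.** Individuals whose co-twin is unobserved
  contribute their marginal normal density (full-information ML), the
  same policy SEM packages use; complete-pairs analysis can be had by
  filtering the input.
* **Saturated reference.** `fit_saturated()` defaults to equating means
  and variances across twin order within zygosity (the exchangeable-twin
  model, MLEs equal to symmetrised moments); `equate = "none"` frees all
  five parameters per group. Twin order in a registry is arbitrary, which
  is why the equated form is the default reference.
* **Model comparison.** $\chi^2 = -2\ln L_{nested} + 2\ln L_{full}$ with
  the standard $\chi^2$ p-value. When a variance component sits on the
  boundary ($a^2 = 0$ or $c^2 = 0$) the asymptotic distribution is a
  mixture and the standard p-value is conservative; we report the
  standard value, as twin analyses conventionally do, and verified by
  simulation that the AE-vs-ACE rejection rate under a true zero C stays
  at or below nominal.
* **Confidence intervals.** `confint()` profiles the deviance over one
  share at a time: the interval is the set of values within
  $\chi^2_{0.95,1} = 3.84$ of the minimum, found by root bisection and
  truncated to $[0,1]$ (one-sided intervals are flagged). Simulated
  coverage for $a^2$ at 500 + 500 pairs lies in the nominal 90–99% band
  over 200 replicates.

## The liability threshold model

Binary enrolment is modelled as a latent standard-normal liability
dichotomised at $t = \Phi^{-1}(1 - K)$ with prevalence $K = 0.57$. The
per-zygosity 2×2 concordance tables are multinomial with cell
probabilities given by bivariate-normal orthant probabilities at latent
correlation $a^2 + c^2$ (MZ) or $\tfrac12 a^2 + c^2$ (DZ). The orthant
probabilities reduce to one-dimensional integrals
$\int \phi(x)\,\Phi\!\big((t_2 - \rho x)/\sqrt{1-\rho^2}\big)\,dx$
evaluated by adaptive quadrature to ~1e-12, cross-checked in the tests
against independent two-dimensional quadrature at 1e-6. Threshold
submodels: the saturated model frees a threshold per twin per zygosity;
Sub1 equates thresholds across twin order within zygosity; Sub2 equates
them everywhere. ACE-structured fits use the single Sub2 threshold;
covariates are not modelled inside the threshold (age and sex effects on
a binary 18-year-old outcome are absorbed by the common threshold, and
the generator creates none).

## Multivariate models

`fit_correlated_factors()` gives each trait its own A/C/E factors and
lets same-kind factors correlate across traits ($r_a$, $r_c$, $r_e$).
Cross-twin cross-trait covariance is $k\,a_i a_j r_{a,ij} + c_i c_j
r_{c,ij}$ with $k = 1$ (MZ) or $\tfrac12$ (DZ). The correlation matrices
are optimised under a spherical (hyperspherical-Cholesky) angle
parameterisation, so every iterate is a valid correlation matrix of any
dimension and no ad-hoc positive-definiteness repairs are needed.
`fit_common_pathway()` (one latent phenotype with its own ACE
decomposition, variance fixed at 1 for identification, loadings bounded
at zero with Heywood flagging, at least three traits) and
`fit_independent_pathway()` (common A, C and E factors loading directly,
free sign) are fitted for AIC comparison; the correlated-factors
structure nests the independent-pathway covariance for two or three
traits, which the tests assert as a deviance inequality.

**Identifiability caveat.** When a trait's shared-environment share is
small, the factor correlation $r_c$ multiplies a product of small paths,
so its single-cohort ML estimate is heavy-tailed and censors at the
$\pm 1$ boundary even at 3,000 + 3,000 pairs (Monte-Carlo SD ≈ 0.14 under
this package's default generating conditions, against ≈ 0.02 for $r_a$).
Recovery of the factor correlations is therefore always assessed on the
mean over replicate cohorts — 20 replicates in `scripts/acceptance.R` —
rather than on a single draw; the same replicate-mean design is applied
to every recovery quantity for uniformity, with replicate counts fixed as
design constants.

## The synthetic cohort generator

Defaults encode the study conditions the package targets:

| Quantity | Default | Basis |
|---|---|---|
| Exam shares (a², c², e²) | 0.57, 0.13, 0.30 | published heritability with MZ/DZ correlations ≈ 0.70/0.40 |
| Quality shares | 0.57, 0.05, 0.38 | published heritability; remaining variance predominantly non-shared |
| Achievement shares (AE) | 0.46, 0, 0.54 | published AE fit |
| Enrolment liability | 0.51, 0.36, 0.13; K = 0.57 | published liability estimates and prevalence |
| Exam–quality correlations | r_a 0.76, r_c 0.81, r_e 0.35 | published multivariate results |
| Adjusted-quality h² | 0.47 | solved by `solve_residual_h2()` so the implied residual heritability matches the published estimate, with the residual C share minimised because the residual trait was best fit by an AE model |
| Institutions / grades | ranks 1–124; grades 1–5 | published coding |
| UCAS tariff | A-level 56…16 by 8s; AS 20…6 in equal steps rounded (20, 17, 14, 12, 9, 6) | published endpoints; intermediate AS steps are an interpolation assumption |

Quality ranks store 1 = best; analyses use the standardized latent so
higher = better. Degree grades exist only for enrolled individuals, with
follow-up non-response controllable via `grade_missing`. Genotypes are
drawn per LD block from a thresholded latent Gaussian: SNPs within a
block share one allele frequency (drawn Uniform(0.05, 0.5) per block) and
the latent equicorrelation is solved numerically so the *dosage*
r² matches the requested block LD despite threshold attenuation; blocks
span well under 250 kb and sit 1 Mb apart, so the clumping window covers
a block but never two. Summary statistics add normal estimation noise
with SE $1/\sqrt{n_{discovery}}$ on the standardized scale and Wald
p-values. `attach_gps_phenotype()` scales the true score so its
population R² equals the target exactly.

What the generator does *not* emulate: real LD decay (block-equicorrelated
instead), assortative mating, sex differences in variance, X-linked
effects, selective attrition correlated with phenotype, measurement
artefacts of rank/grade coarsening beyond simple binning. Recovery tests
therefore validate the estimators under the models' own assumptions; they
do not certify behaviour under real-data violations of those assumptions.

## Polygenic scoring choices

Clumping is greedy p-value-priority: visit SNPs by ascending p (ties by
position, so results are order-invariant), retain unless dosage r² with a
retained SNP within 250 kb exceeds 0.1; a pure position-order pruning
mode exists behind `mode = "prune"`. Missing dosages are mean-imputed
(2 × allele frequency). The threshold scan accumulates scores
incrementally over the sorted p-values, so the full 1,000-point grid
costs one pass over the panel. The best threshold maximises in-sample
variance explained and is therefore slightly optimistic — the report
records this — and with clumped tags at block r² 0.8 a score recovers
roughly 80% of a tagged causal SNP's signal, so recovered R² sits a
little below the generating true-score R². Nagelkerke's
$R^2 = \big(1 - (L_0/L_1)^{2/n}\big)\big/\big(1 - L_0^{2/n}\big)$ handles
binary outcomes; perfect separation reports 1 with a warning. PC
correction regresses scores on the top 10 components of the standardized
dosage matrix.

## Preprocessing

The canonical pipeline regresses each continuous trait on age and sex and
then applies van der Waerden scores $\Phi^{-1}(r_i/(n+1))$ with mid-ranks
for ties; the order is recorded in the result's provenance and reversible
by flag. The achievement-adjusted quality measure is the OLS residual of
quality on exam achievement, re-standardized before twin modelling (a
flag disables re-standardization; the standardized form is the default
because twin shares are scale-free while profile CIs benefit from a unit
scale). Binary enrolment is never transformed.

## Problem sizes used in validation

The test suite fits at 100–5,000 pairs per zygosity depending on what the
check needs (grid-search oracles at 75–100 pairs; recovery at the study's
own 1,600–5,000 pairs; coverage at 500 + 500 over 200 replicates), and
panels up to 3,000 individuals × 5,000 SNPs. `scripts/acceptance.R` runs
every recovery at the study's sample sizes with the replicate counts
listed above and completes in about a minute on one CPU.

## Known limitations

* Path-coefficient signs are not identified in univariate models;
  estimates are reported as non-negative shares.
* Boundary p-values are conservative (χ² mixture, documented above).
* The common-pathway fit requires three traits; two-trait common-pathway
  structures are not identified and are rejected.
* Profile CIs for multivariate fits are implemented for bivariate
  correlated-factors models; larger models report point estimates and
  deviances only.
* SNP-based heritability (GREML/LDSC-style) is out of scope, as are
  imputation, array QC and reference-panel LD.
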