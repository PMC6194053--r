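#' Simulate twin pairs under an ACE model
#'
#' Draws continuous phenotypes for MZ and DZ twin pairs from a zero-mean,
#' unit-variance bivariate normal whose within-pair covariance is
#' `a2 + c2` (MZ) or `0.5 * a2 + c2` (DZ), the classical twin-design
#' expectation under additive genetic, shared and non-shared environmental
#' influences.
#'
#' @param params An [ace_params()] object.
#' @param n_mz,n_dz Numbers of MZ and DZ pairs (each >= 1).
#' @param seed Integer seed; a fixed seed gives bit-identical output and the
#'   caller's RNG state is untouched.
#' @param trait Name of the phenotype column.
#' @return A twin-pair table: a long-format `data.frame` with one row per
#'   individual and columns `family_id`, `twin` (1 or 2), `zygosity`
#'   (`"MZ"`/`"DZ"`), and the phenotype.
#' @examples
#' pairs <- simulate_ace_pairs(ace_params(0.57, 0.13, 0.30), 500, 500, seed = 1)
#' head(pairs)
#' @export
simulate_ace_pairs <- function(params, n_mz, n_dz, seed, trait = "trait") {
  if (!inherits(params, "ace_params")) params <- do.call(ace_params, as.list(params))
  check_pair_counts(n_mz, n_dz)
  with_seed(seed, {
    vals <- rbind(
      draw_pairs(n_mz, r = params[["a2"]] + params[["c2"]]),
      draw_pairs(n_dz, r = 0.5 * params[["a2"]] + params[["c2"]])
    )
    assemble_pairs(vals, n_mz, n_dz, trait)
  })
}

#' Simulate binary twin pairs under a liability threshold model
#'
#' Latent liabilities are drawn exactly as in [simulate_ace_pairs()] and
#' dichotomised at the prevalence-defined threshold `qnorm(1 - prevalence)`;
#' the returned trait is coded 1 = affected (e.g., enrolled at university).
#'
#' @param params A [liability_params()] object.
#' @inheritParams simulate_ace_pairs
#' @return A twin-pair table with a binary 0/1 phenotype.
#' @export
simulate_liability_pairs <- function(params, n_mz, n_dz, seed,
                                     trait = "affected") {
  if (!inherits(params, "liability_params"))
    stop("params must be a liability_params object")
  check_pair_counts(n_mz, n_dz)
  tab <- simulate_ace_pairs(params$ace, n_mz, n_dz, seed, trait = trait)
  tab[[trait]] <- as.integer(tab[[trait]] > params$threshold)
  tab
}

#' Simulate multivariate twin pairs under a correlated-factors model
#'
#' Each trait has its own additive genetic, shared and non-shared
#' environmental factors; factors of the same kind correlate across traits
#' through `r_a`, `r_c`, `r_e`. The full pair covariance is assembled with
#' [cf_pair_covariance()] (and rejected with a diagnostic if not positive
#' semi-definite) before sampling.
#'
#' @param params A [cf_params()] object.
#' @inheritParams simulate_ace_pairs
#' @return A twin-pair table with one column per trait.
#' @export
simulate_correlated_factors_pairs <- function(params, n_mz, n_dz, seed) {
  if (!inherits(params, "cf_params")) stop("params must be a cf_params object")
  check_pair_counts(n_mz, n_dz)
  t_n <- nrow(params$path)
  sig_mz <- cf_pair_covariance(params, "MZ")
  sig_dz <- cf_pair_covariance(params, "DZ")
  with_seed(seed, {
    mz <- rmvn(n_mz, rep(0, 2 * t_n), sig_mz)
    dz <- rmvn(n_dz, rep(0, 2 * t_n), sig_dz)
    vals <- rbind(mz, dz)
    tab <- assemble_pairs(vals[, c(1, t_n + 1)], n_mz, n_dz, params$traits[1])
    if (t_n > 1) {
      for (j in 2:t_n) {
        v <- vals[, c(j, t_n + j)]
        tab[[params$traits[j]]] <- as.vector(t(v))
      }
    }
    tab
  })
}

## bivariate standard-normal pair draws with correlation r
draw_pairs <- function(n, r) {
  rmvn(n, c(0, 0), matrix(c(1, r, r, 1), 2, 2))
}

check_pair_counts <- function(n_mz, n_dz) {
  if (n_mz < 1 || n_dz < 1 || n_mz != round(n_mz) || n_dz != round(n_dz))
    stop("pair counts must be positive integers")
}

## vals: (n_mz + n_dz) x 2 matrix of pair values -> long table
assemble_pairs <- function(vals, n_mz, n_dz, trait) {
  n <- n_mz + n_dz
  out <- data.frame(
    family_id = rep(seq_len(n), each = 2),
    twin = rep(1:2, n),
    zygosity = rep(c("MZ", "DZ"), times = c(2 * n_mz, 2 * n_dz)),
    stringsAsFactors = FALSE
  )
  out[[trait]] <- as.vector(t(vals))
  out
}

## long table -> per-zygosity list of n x 2 pair matrices (plus singleton
## values when a co-twin is missing)
pairs_to_wide <- function(pairs, trait, zygosity) {
  sub <- pairs[pairs$zygosity == zygosity, c("family_id", "twin", trait)]
  t1 <- sub[sub$twin == 1, ]
  t2 <- sub[sub$twin == 2, ]
  m <- merge(t1, t2, by = "family_id", all = TRUE, suffixes = c("_1", "_2"))
  x <- cbind(m[[paste0(trait, "_1")]], m[[paste0(trait, "_2")]])
  ok <- complete.cases(x)
  single <- c(x[!ok, 1], x[!ok, 2])
  list(pairs = x[ok, , drop = FALSE], singles = single[!is.na(single)])
}

#' UCAS tariff points from A-level / AS-level grades
#'
#' Converts school-leaving qualification grades to Universities and Colleges
#' Admissions Service (UCAS) tariff points and sums them. A-level grades
#' A* through E are worth 56, 48, 40, 32, 24 and 16 points (equal 8-point
#' steps between the published endpoints); AS-level grades run from 20 (A*)
#' down to 6 (E) in equal steps rounded to the nearest point
#' (20, 17, 14, 12, 9, 6).
#'
#' @param grades A data frame (or list of 2-element vectors) with columns
#'   `level` (`"A"` or `"AS"`) and `grade` (`"A*"`, `"A"`, `"B"`, `"C"`,
#'   `"D"`, `"E"`).
#' @return Integer total tariff points.
#' @examples
#' ucas_points_from_grades(data.frame(level = c("A", "A", "A"),
#'                                    grade = c("A*", "A*", "E")))
#' @export
ucas_points_from_grades <- function(grades) {
  if (is.list(grades) && !is.data.frame(grades))
    grades <- do.call(rbind.data.frame,
                      lapply(grades, function(g)
                        data.frame(level = g[[1]], grade = g[[2]])))
  letters6 <- c("A*", "A", "B", "C", "D", "E")
  a_tariff <- setNames(seq(56, 16, by = -8), letters6)
  as_tariff <- setNames(round(seq(20, 6, length.out = 6)), letters6)
  lv <- as.character(grades$level)
  gr <- as.character(grades$grade)
  if (!all(lv %in% c("A", "AS"))) stop("level must be 'A' or 'AS'")
  if (!all(gr %in% letters6))
    stop("unknown grade letter: ", paste(setdiff(gr, letters6), collapse = ", "))
  pts <- ifelse(lv == "A", a_tariff[gr], as_tariff[gr])
  as.integer(sum(pts))
}

#' Cohort specification for the full synthetic twin study
#'
#' @param n_mz_pairs,n_dz_pairs Pair counts.
#' @param prevalence Enrolment prevalence on the liability scale.
#' @param enrolment_ace Liability-scale [ace_params()] for enrolment.
#' @param traits_params [cf_params()] for the continuous traits
#'   (entrance-exam achievement, university quality, university
#'   achievement), in that order.
#' @param exam_enrolment_ra Genetic correlation between the exam liability
#'   factor and the enrolment liability factor.
#' @param n_universities Number of ranked institutions (rank 1 = best).
#' @param grade_levels Number of degree-grade levels (1 = lowest pass).
#' @param mean_age,sd_age Age distribution (years) at outcome collection.
#' @param p_female Probability an individual is female (`sex = 1`).
#' @param grade_missing Fraction of enrolled individuals with a missing
#'   degree grade (non-response at follow-up).
#' @return A `"cohort_spec"` list, validated.
#' @export
cohort_spec <- function(n_mz_pairs = 1800, n_dz_pairs = 3200,
                        prevalence = 0.57,
                        enrolment_ace = ace_params(0.51, 0.36, 0.13),
                        traits_params = NULL,
                        exam_enrolment_ra = 0.5,
                        n_universities = 124, grade_levels = 5,
                        mean_age = 22, sd_age = 0.85, p_female = 0.5,
                        grade_missing = 0.45) {
  if (is.null(traits_params)) {
    traits_params <- cf_params(
      rbind(c(0.57, 0.13, 0.30), c(0.57, 0.05, 0.38), c(0.46, 0.00, 0.54)),
      r_a = rbind(c(1, 0.76, 0.49), c(0.76, 1, 0.27), c(0.49, 0.27, 1)),
      r_c = rbind(c(1, 0.81, 0.35), c(0.81, 1, 0.27), c(0.35, 0.27, 1)),
      r_e = rbind(c(1, 0.35, 0.03), c(0.35, 1, 0.09), c(0.03, 0.09, 1)),
      traits = c("exam", "quality", "achievement"))
  }
  check_pair_counts(n_mz_pairs, n_dz_pairs)
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (grade_missing < 0 || grade_missing >= 1)
    stop("grade_missing must be in [0,1)")
  structure(list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
                 prevalence = prevalence, enrolment_ace = enrolment_ace,
                 traits_params = traits_params,
                 exam_enrolment_ra = exam_enrolment_ra,
                 n_universities = n_universities,
                 grade_levels = grade_levels,
                 mean_age = mean_age, sd_age = sd_age,
                 p_female = p_female, grade_missing = grade_missing),
            class = "cohort_spec")
}

#' Simulate a full university-success twin cohort
#'
#' Generates a cohort emulating a UK twin study of university outcomes:
#' MZ/DZ pairs with sex and age; a latent continuous entrance-exam factor
#' mapped to UCAS-style points; a binary enrolment indicator from a
#' correlated liability with specified prevalence; a university quality
#' rank over `n_universities` institutions (rank 1 = best) for enrolled
#' individuals; and a degree grade on a 1-5 scale, observed only for
#' enrolled individuals and subject to follow-up non-response. Degree
#' grades are never present for non-enrolled individuals (logical nesting
#' of the measures).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A long-format `data.frame`: `family_id`, `twin`, `zygosity`,
#'   `sex` (0 male / 1 female), `age`, `exam_points`, `exam`, `enrolled`,
#'   `quality_rank`, `quality`, `degree_grade`, `achievement`. Continuous
#'   latent scores are retained alongside their coarse observed codings.
#' @export
simulate_twin_study_cohort <- function(spec, seed) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  n_mz <- spec$n_mz_pairs; n_dz <- spec$n_dz_pairs
  tab <- simulate_correlated_factors_pairs(spec$traits_params, n_mz, n_dz,
                                           seed = seed)
  with_seed(seed + 1L, {
    n_ind <- nrow(tab)
    n_pairs <- n_mz + n_dz
    ## demographics: same-sex MZ; DZ pairs same- or opposite-sex
    sex_pair1 <- rbinom(n_pairs, 1, spec$p_female)
    sex2_mz <- sex_pair1[seq_len(n_mz)]
    sex2_dz <- rbinom(n_dz, 1, spec$p_female)
    sex <- as.vector(rbind(sex_pair1, c(sex2_mz, sex2_dz)))
    age_pair <- rnorm(n_pairs, spec$mean_age, spec$sd_age)
    tab$sex <- sex
    tab$age <- rep(age_pair, each = 2)

    ## enrolment liability correlated with the exam factor: a weighted
    ## combination of the exam liability and an independent ACE liability
    lp <- spec$enrolment_ace
    extra <- simulate_ace_pairs(lp, n_mz, n_dz, seed = seed + 2L,
                                trait = "z")$z
    w <- spec$exam_enrolment_ra
    liab <- w * tab$exam + sqrt(1 - w^2) * extra  # unit variance
    tab$enrolled <- as.integer(liab > qnorm(1 - spec$prevalence))

    ## exam points: latent exam score mapped to a UCAS-like tariff scale
    ## (three A-levels; mean ~ BBB = 120 points), truncated at [48, 168]
    tab$exam_points <- as.integer(pmin(168, pmax(48,
      round(120 + 24 * tab$exam))))

    ## quality rank among enrolled individuals: best latent quality ->
    ## rank 1; ranks binned onto 1..n_universities
    tab$quality_rank <- NA_integer_
    enr <- tab$enrolled == 1
    if (any(enr)) {
      q <- tab$quality[enr]
      r <- rank(-q, ties.method = "first")
      tab$quality_rank[enr] <-
        as.integer(ceiling(r / length(r) * spec$n_universities))
    }

    ## degree grade 1..grade_levels from the achievement latent, only for
    ## enrolled individuals, with follow-up non-response
    tab$degree_grade <- NA_integer_
    if (any(enr)) {
      cuts <- qnorm(seq(0, 1, length.out = spec$grade_levels + 1))
      g <- cut(tab$achievement[enr], breaks = cuts, labels = FALSE,
               include.lowest = TRUE)
      miss <- rbinom(sum(enr), 1, spec$grade_missing) == 1
      g[miss] <- NA_integer_
      tab$degree_grade[enr] <- g
    }
    tab[, c("family_id", "twin", "zygosity", "sex", "age", "exam_points",
            "exam", "enrolled", "quality_rank", "quality", "degree_grade",
            "achievement")]
  })
}
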