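## Pipeline orchestration: simulate -> preprocess -> twin fits -> polygenic
## scores, with a YAML config, a run manifest (seed, parameters, file
## checksums) and tab-separated reports. A thin command-line wrapper lives
## at inst/cli/twinpgs.R.

#' Read a pipeline run configuration
#'
#' YAML key-value hierarchy; see `run_simulate()`, `run_fit()` and
#' `run_prs()` for the keys each stage reads. A `seed` entry is mandatory
#' for simulation runs.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

manifest_entry <- function(files) {
  data.frame(file = basename(files),
             md5 = unname(tools::md5sum(files)),
             stringsAsFactors = FALSE)
}

write_manifest <- function(out_dir, seed, config, files) {
  yaml::write_yaml(list(seed = seed,
                        config = config,
                        files = split(manifest_entry(files)$md5,
                                      manifest_entry(files)$file)),
                   file.path(out_dir, "manifest.yaml"))
}

#' Simulate a cohort and genotype panel to disk
#'
#' Generates the synthetic twin cohort (and optionally a genotype panel
#' with summary statistics) under the configured parameters and writes
#' them, plus a manifest recording the seed, the configuration and an MD5
#' checksum per emitted file. The same config and seed reproduce
#' byte-identical files. Existing outputs are not overwritten unless
#' `overwrite` is set.
#'
#' @param config List with entries: `seed` (required); `cohort` (list:
#'   `n_mz_pairs`, `n_dz_pairs`, further [cohort_spec()] arguments);
#'   optional `panel` (list: `n_ind`, `n_snps`, `block_size`,
#'   `within_block_r2`, `n_causal`, `discovery_n`, `target_r2`).
#' @param out_dir Output directory (created if needed).
#' @param overwrite Allow replacing existing outputs.
#' @return Invisibly, the vector of written file paths.
#' @export
run_simulate <- function(config, out_dir, overwrite = FALSE) {
  if (is.null(config$seed)) stop("config must set a seed for simulation runs")
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort_path <- file.path(out_dir, "cohort.tsv")
  if (file.exists(cohort_path) && !overwrite)
    stop("outputs exist in ", out_dir, "; pass overwrite = TRUE")
  spec <- do.call(cohort_spec, config$cohort %||% list())
  cohort <- simulate_twin_study_cohort(spec, seed = seed)
  write_cohort(cohort, cohort_path)
  files <- cohort_path
  if (!is.null(config$panel)) {
    pc <- config$panel
    panel <- simulate_genotype_panel(pc$n_ind, pc$n_snps,
                                     pc$block_size %||% 5,
                                     pc$within_block_r2 %||% 0.8,
                                     seed = seed + 1L)
    panel <- simulate_summary_stats(panel, pc$n_causal %||% 500,
                                    pc$discovery_n %||% 1e6,
                                    seed = seed + 2L)
    stem <- file.path(out_dir, "panel")
    files <- c(files, write_panel(panel, stem))
    if (!is.null(pc$target_r2)) {
      phen <- attach_gps_phenotype(panel, pc$target_r2, seed = seed + 3L)
      phen_path <- file.path(out_dir, "gps_phenotype.tsv")
      utils::write.table(format_full(phen), phen_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, phen_path)
    }
  }
  write_manifest(out_dir, seed, config, files)
  invisible(files)
}

#' Fit twin models for every configured trait
#'
#' Reads a cohort file, prepares each continuous trait (age/sex
#' regression + van der Waerden transform when covariates are present),
#' and per trait reports: double-entry intraclass (MZ/DZ) correlations,
#' Falconer estimates, the full ACE fit with its AE/CE/E submodels,
#' likelihood-ratio comparisons and the parsimony-selected model, with
#' profile CIs for the selected model's shares. Binary (0/1) traits are
#' routed to the liability threshold model automatically.
#'
#' @param config List: `cohort` (path), `traits` (character vector),
#'   optional `alpha` (selection level, default 0.05).
#' @param out_dir Output directory.
#' @return Invisibly, the report `data.frame` (also written as
#'   `twin_fits.tsv` and `twin_fits.json`).
#' @export
run_fit <- function(config, out_dir) {
  cohort <- read_cohort(config$cohort)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- config$alpha %||% 0.05
  rows <- list()
  for (tr in config$traits) {
    vals <- cohort[[tr]]
    if (is.null(vals)) stop("trait '", tr, "' not found in cohort")
    binary <- all(na.omit(vals) %in% 0:1)
    if (binary) {
      full <- fit_ltm(cohort, tr, components = "ACE")
      nested <- list(AE = fit_ltm(cohort, tr, components = "AE"),
                     CE = fit_ltm(cohort, tr, components = "CE"))
      sel <- select_model(full, nested, alpha)
      pick <- if (sel == "full") full else nested[[sel]]
      ci <- confint(pick)
      rows[[tr]] <- data.frame(
        trait = tr, model = if (sel == "full") "ACE" else sel,
        scale = "liability",
        a2 = pick$shares["a2"], c2 = pick$shares["c2"],
        e2 = pick$shares["e2"],
        a2_lo = if ("a2" %in% rownames(ci)) ci["a2", 1] else NA,
        a2_hi = if ("a2" %in% rownames(ci)) ci["a2", 2] else NA,
        minus2ll = pick$minus2ll, df = pick$df, aic = pick$aic,
        r_mz = pick$tetrachoric["MZ"], r_dz = pick$tetrachoric["DZ"],
        stringsAsFactors = FALSE)
    } else {
      prepared <- if (!is.null(config$covariates))
        as.numeric(prepare_trait(vals, cohort[config$covariates]))
      else vals
      dat <- cohort
      dat[[tr]] <- prepared
      icc_mz <- intraclass_correlation(dat, tr, "MZ")
      icc_dz <- intraclass_correlation(dat, tr, "DZ")
      falc <- falconer_estimates(icc_mz$r, icc_dz$r)
      full <- fit_ace(dat, tr, "ACE")
      nested <- list(AE = fit_ace(dat, tr, "AE"),
                     CE = fit_ace(dat, tr, "CE"),
                     E = fit_ace(dat, tr, "E"))
      sel <- select_model(full, nested, alpha)
      pick <- if (sel == "full") full else nested[[sel]]
      ci <- confint(pick)
      rows[[tr]] <- data.frame(
        trait = tr, model = pick$submodel, scale = "continuous",
        a2 = pick$shares["a2"], c2 = pick$shares["c2"],
        e2 = pick$shares["e2"],
        a2_lo = if ("a2" %in% rownames(ci)) ci["a2", 1] else NA,
        a2_hi = if ("a2" %in% rownames(ci)) ci["a2", 2] else NA,
        minus2ll = pick$minus2ll, df = pick$df, aic = pick$aic,
        r_mz = icc_mz$r, r_dz = icc_dz$r,
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  utils::write.table(format_full(report), file.path(out_dir, "twin_fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "twin_fits.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(report)
}

#' Clump, score and report polygenic prediction
#'
#' Reads a genotype panel (stem) and a phenotype table, clumps the SNPs,
#' runs the high-resolution threshold scan, optionally removes ancestry
#' principal components from the best score, and reports variance
#' explained with a bootstrap percentile CI. Phenotype and panel
#' individuals are matched by row order (ids intersected when both carry
#' `id` columns, with the dropped count logged).
#'
#' @param config List: `panel` (stem), `phenotype` (path to TSV with
#'   `phenotype` column, or numeric vector), optional `outcome_type`,
#'   `r2_cutoff`, `window_bp`, `n_pcs` (0 disables PC correction),
#'   `n_boot` (default 1000).
#' @param out_dir Output directory.
#' @param seed Seed for the bootstrap resamples.
#' @return Invisibly, a list: `gps` (the `"gps_result"`), `ci`
#'   (bootstrap CI for the best-threshold variance explained); the
#'   threshold curve is written as `gps_curve.tsv`, the summary as
#'   `gps_report.yaml`.
#' @export
run_prs <- function(config, out_dir, seed = 1L) {
  panel <- read_panel(config$panel)
  phen_tab <- if (is.character(config$phenotype))
    utils::read.table(config$phenotype, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  else data.frame(phenotype = config$phenotype)
  phen <- phen_tab$phenotype
  if (length(phen) != nrow(panel$dosages)) {
    n <- min(length(phen), nrow(panel$dosages))
    message("phenotype/panel size mismatch; intersecting to ", n,
            " individuals")
    phen <- phen[seq_len(n)]
    panel$dosages <- panel$dosages[seq_len(n), , drop = FALSE]
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- prune_config(config$r2_cutoff %||% 0.1,
                      config$window_bp %||% 250000)
  kept <- clump_snps(panel, cfg)
  outcome_type <- config$outcome_type %||%
    (if (all(na.omit(phen) %in% 0:1)) "binary" else "continuous")
  gps <- high_resolution_scoring(panel, phen, outcome_type,
                                 retained_ids = kept)
  n_pcs <- config$n_pcs %||% 0
  score <- gps$best_scores
  if (n_pcs > 0) score <- pc_correct(score, panel, n_pcs)
  ## bootstrap CI for the best-threshold variance explained
  n_boot <- config$n_boot %||% 1000
  r2_of <- function(idx) {
    s <- score[idx]; y <- phen[idx]
    if (sd(s) == 0) return(0)
    if (outcome_type == "continuous") cor(y, s)^2 else nagelkerke_r2(y, s)
  }
  boots <- with_seed(seed, replicate(n_boot,
    r2_of(sample.int(length(phen), replace = TRUE))))
  ci <- unname(quantile(boots, c(0.025, 0.975)))
  utils::write.table(format_full(gps$curve),
                     file.path(out_dir, "gps_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(n = gps$n, n_snps_clumped = length(kept),
                        best_threshold = gps$best_threshold,
                        variance_explained = gps$best_r2,
                        ci95 = ci, n_pcs = n_pcs, seed = seed,
                        note = "best threshold maximises in-sample variance explained"),
                   file.path(out_dir, "gps_report.yaml"))
  invisible(list(gps = gps, ci = ci, retained = kept))
}
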