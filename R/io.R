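#' Read and write the tab-separated cohort format
#'
#' One row per individual; columns `family_id`, `twin` (1|2), `zygosity`
#' (MZ|DZ), then any phenotype columns; missing values are empty fields.
#' The round trip is lossless for numeric phenotypes up to full double
#' precision.
#'
#' @param cohort A twin-pair table.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(format_full(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

## full-precision text rendering so read -> write -> read is exact
format_full <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- NA_character_
      out
    } else col
  }), stringsAsFactors = FALSE)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                    stringsAsFactors = FALSE)
}

#' Write and read a genotype panel as plain text
#'
#' Three tab-separated files under a common stem: `<stem>_dosages.tsv`
#' (individuals x SNPs, SNP ids as header), `<stem>_map.tsv` (`chr`,
#' `pos`, `id`, `effect_allele`, `other_allele`, `freq`) and, when
#' present, `<stem>_sumstats.tsv` (`id`, `effect_allele`, `beta`, `p` —
#' PRSice-style base format).
#'
#' @param panel A `"genotype_panel"`.
#' @param stem Path stem (directory + prefix).
#' @return `write_panel` returns the written paths invisibly;
#'   `read_panel` reconstructs the panel.
#' @export
write_panel <- function(panel, stem) {
  stopifnot(inherits(panel, "genotype_panel"))
  dos_path <- paste0(stem, "_dosages.tsv")
  map_path <- paste0(stem, "_map.tsv")
  d <- as.data.frame(panel$dosages)
  names(d) <- panel$snp_map$id
  utils::write.table(d, dos_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(format_full(panel$snp_map), map_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(dos_path, map_path)
  if (!is.null(panel$summary_stats)) {
    ss_path <- paste0(stem, "_sumstats.tsv")
    utils::write.table(format_full(panel$summary_stats[, c("id", "effect_allele",
                                                           "beta", "p")]),
                       ss_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, ss_path)
  }
  invisible(paths)
}

#' @rdname write_panel
#' @export
read_panel <- function(stem) {
  dos <- as.matrix(utils::read.table(paste0(stem, "_dosages.tsv"),
                                     sep = "\t", header = TRUE,
                                     check.names = FALSE))
  map <- utils::read.table(paste0(stem, "_map.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  ss_path <- paste0(stem, "_sumstats.tsv")
  ss <- if (file.exists(ss_path))
    utils::read.table(ss_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  else NULL
  dimnames(dos) <- NULL
  structure(list(dosages = dos, snp_map = map, summary_stats = ss),
            class = "genotype_panel")
}

#' Write a provenance sidecar for prepared traits
#'
#' Records, per trait, the ordered list of transforms applied (as carried
#' in each `"residualized_trait"`'s provenance attribute) as structured
#' YAML next to the data.
#'
#' @param traits Named list of `"residualized_trait"` objects.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(traits, path) {
  prov <- lapply(traits, function(t) as.list(attr(t, "provenance")))
  yaml::write_yaml(prov, path)
  invisible(path)
}
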