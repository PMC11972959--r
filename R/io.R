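# Cohort panel persistence.
#
# A panel directory holds plain-text tables only:
#   genotypes.tsv  subjects x SNPs additive dosages, "NA" for missing
#   variants.tsv   per-SNP metadata
#   baseline.tsv   per-subject covariates, baseline phenotypes, true label
#   visits.tsv     long format (subject_id, visit, time_years, fbs, sbp)
#   events.tsv     event/censoring times, indicators, prevalence flags
#   config.yaml    the generating configuration
# Doubles are serialized with 17 significant digits so a round trip is
# bit-identical.

#' Write a cohort panel to a directory of TSV files
#'
#' @param panel a `cohort_panel`.
#' @param directory output directory (created if needed).
#' @return the directory, invisibly.
#' @seealso [read_cohort()] for the inverse; `read(write(p))` reproduces
#'   `p` field for field, including the genotype missingness pattern.
#' @export
write_cohort <- function(panel, directory) {
  stopifnot(inherits(panel, "cohort_panel"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  geno <- as.data.frame(panel$genotypes)
  geno <- cbind(data.frame(subject_id = panel$subject_ids,
                           stringsAsFactors = FALSE), geno)
  write_tsv(geno, file.path(directory, "genotypes.tsv"))
  write_tsv(panel$variant_meta, file.path(directory, "variants.tsv"))
  write_tsv(panel$baseline, file.path(directory, "baseline.tsv"))
  write_tsv(panel$visits, file.path(directory, "visits.tsv"))
  write_tsv(panel$events, file.path(directory, "events.tsv"))
  cfg <- panel$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(directory, "config.yaml"),
                   precision = 17)
  invisible(directory)
}

#' Read a cohort panel written by [write_cohort()]
#'
#' Malformed files raise a parse error naming the offending file and line.
#'
#' @param directory a panel directory.
#' @return a `cohort_panel`.
#' @export
read_cohort <- function(directory) {
  geno_df <- read_tsv_checked(file.path(directory, "genotypes.tsv"))
  if (!"subject_id" %in% names(geno_df))
    stop(sprintf("parse error in %s, line 1: missing 'subject_id' column",
                 file.path(directory, "genotypes.tsv")), call. = FALSE)
  subject_ids <- geno_df$subject_id
  G <- as.matrix(geno_df[, setdiff(names(geno_df), "subject_id"), drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- NULL
  variant_meta <- read_tsv_checked(
    file.path(directory, "variants.tsv"),
    numeric_cols = c("pos", "true_maf", "true_beta_fbs", "true_beta_sbp"))
  baseline <- read_tsv_checked(
    file.path(directory, "baseline.tsv"),
    numeric_cols = c("age", "bmi", "fbs", "sbp"))
  visits <- read_tsv_checked(
    file.path(directory, "visits.tsv"),
    numeric_cols = c("time_years", "fbs", "sbp"))
  events <- read_tsv_checked(
    file.path(directory, "events.tsv"),
    numeric_cols = c("t2d_time", "htn_time"))
  cfg <- yaml::read_yaml(file.path(directory, "config.yaml"))
  cfg$maf_range <- as.numeric(cfg$maf_range)
  cfg$traj_group_shares <- as.numeric(cfg$traj_group_shares)
  cfg$prevalence <- unlist(cfg$prevalence)
  cfg$traj_coefficients <- lapply(cfg$traj_coefficients,
                                  function(ph) lapply(ph, as.numeric))
  class(cfg) <- "sim_config"
  structure(list(subject_ids = subject_ids, genotypes = G,
                 variant_meta = variant_meta, baseline = baseline,
                 visits = visits, true_labels = baseline$true_label,
                 events = events, config = cfg),
            class = "cohort_panel")
}

#' Export panel genotypes as a minimal VCF
#'
#' Additive dosages are written as GT calls with the effect allele as ALT:
#' 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, missing -> `./.`.
#'
#' @param panel a `cohort_panel`.
#' @param file output VCF path (uncompressed).
#' @return the file path, invisibly.
#' @export
write_vcf <- function(panel, file) {
  stopifnot(inherits(panel, "cohort_panel"))
  vm <- panel$variant_meta
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=bidirmr synthetic cohort",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$subject_ids), collapse = "\t")),
             con)
  for (j in seq_len(nrow(vm))) {
    dos <- panel$genotypes[, j]
    gt <- ifelse(is.na(dos), "./.", gt_code[dos + 1L])
    writeLines(paste(c(vm$chr[j], vm$pos[j], vm$snp_id[j], vm$other_allele[j],
                       vm$effect_allele[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(file)
}
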