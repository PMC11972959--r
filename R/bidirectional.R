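# Bidirectional MR driver: five estimators in both directions, with the
# shared-variant-excluded re-analysis and instrument diagnostics.

subset_subjects <- function(panel, keep) {
  out <- panel
  out$subject_ids <- panel$subject_ids[keep]
  out$genotypes <- panel$genotypes[keep, , drop = FALSE]
  out$baseline <- panel$baseline[keep, , drop = FALSE]
  rownames(out$baseline) <- NULL
  out$true_labels <- panel$true_labels[keep]
  out$events <- panel$events[keep, , drop = FALSE]
  rownames(out$events) <- NULL
  out$visits <- panel$visits[panel$visits$subject_id %in% out$subject_ids, ,
                             drop = FALSE]
  rownames(out$visits) <- NULL
  out
}

subset_variants <- function(panel, snp_ids) {
  out <- panel
  out$genotypes <- panel$genotypes[, snp_ids, drop = FALSE]
  out$variant_meta <- panel$variant_meta[match(snp_ids, panel$variant_meta$snp_id), ,
                                         drop = FALSE]
  rownames(out$variant_meta) <- NULL
  out
}

summary_methods_rows <- function(dat, direction, excluded_shared, n_boot, seed) {
  ests <- list(
    mr_ivw(dat),
    mr_median(dat, weighted = FALSE, n_boot = n_boot, seed = seed),
    mr_median(dat, weighted = TRUE, n_boot = n_boot, seed = seed + 1L),
    mr_egger(dat)
  )
  do.call(rbind, lapply(ests, function(e) {
    data.frame(direction = direction, method = e$method,
               excluded_shared = excluded_shared,
               effect = e$effect, se = e$se, p = e$p,
               intercept = e$intercept %||% NA_real_,
               intercept_se = e$intercept_se %||% NA_real_,
               intercept_p = e$intercept_p %||% NA_real_,
               n_instruments = e$n_instruments, stringsAsFactors = FALSE)
  }))
}

#' Run the full bidirectional MR analysis
#'
#' For each direction (FBS to SBP and SBP to FBS) this runs the four
#' summary-statistic estimators (IVW, simple median, weighted median,
#' MR-Egger) on a two-sample input built by split-sample GWAS — exposure
#' coefficients from odd-indexed subjects, outcome coefficients from
#' even-indexed subjects, so the two-sample independence assumption holds —
#' plus individual-level 2SLS with the wGRS instrument (full sample and sex
#' strata, instruments not re-selected per stratum). Variants shared by the
#' two instrument sets are then excluded and the summary estimators re-run
#' (the analog of dropping a known pleiotropic outlier). Effects are also
#' rescaled to clinical increments: per 0.5 mmol/L of FBS and per 10 mmHg
#' of SBP, and per 1 SD of the exposure.
#'
#' @param panel a QC-filtered `cohort_panel`.
#' @param instruments_fbs,instruments_sbp `instrument_set`s for the two
#'   phenotypes (their betas weight the wGRS).
#' @param covariates covariate columns for GWAS and 2SLS.
#' @param n_boot bootstrap replicates for median SEs.
#' @param seed seed for the bootstrap.
#' @param split_sample logical; `FALSE` uses the full sample for both sides
#'   of the two-sample input (for comparisons against 2SLS).
#' @return an `mr_report`: `mr_table`, `diagnostics`, `scalings`.
#' @export
run_bidirectional <- function(panel, instruments_fbs, instruments_sbp,
                              covariates = c("age", "sex"),
                              n_boot = 1000, seed = 1L, split_sample = TRUE) {
  if (nrow(instruments_fbs$variants) == 0 || nrow(instruments_sbp$variants) == 0)
    stop("both instrument sets must be nonempty", call. = FALSE)
  shared_ids <- intersect(instruments_fbs$variants$snp_id,
                          instruments_sbp$variants$snp_id)
  n <- length(panel$subject_ids)
  idx_a <- seq_len(n) %% 2 == 1
  if (!split_sample) idx_a <- rep(TRUE, n)
  idx_b <- if (split_sample) !idx_a else rep(TRUE, n)

  dirs <- list(
    list(tag = "FBS->SBP", exposure = "fbs", outcome = "sbp",
         instruments = instruments_fbs),
    list(tag = "SBP->FBS", exposure = "sbp", outcome = "fbs",
         instruments = instruments_sbp)
  )
  mr_rows <- list(); diag_rows <- list(); scale_rows <- list()
  for (d in dirs) {
    ids <- d$instruments$variants$snp_id
    sub <- subset_variants(panel, ids)
    gw_exp <- run_gwas(subset_subjects(sub, idx_a), d$exposure, covariates)
    gw_out <- run_gwas(subset_subjects(sub, idx_b), d$outcome, covariates)
    ok <- !is.na(gw_exp$beta) & !is.na(gw_out$beta)
    dat <- two_sample_input(gw_exp$beta[ok], gw_exp$se[ok],
                            gw_out$beta[ok], gw_out$se[ok],
                            gw_exp$snp_id[ok], d$tag)
    mr_rows[[length(mr_rows) + 1]] <-
      summary_methods_rows(dat, d$tag, FALSE, n_boot, seed)
    in_shared <- dat$snp_id %in% shared_ids
    if (any(in_shared) && sum(!in_shared) >= 3) {
      mr_rows[[length(mr_rows) + 1]] <-
        summary_methods_rows(subset_tsi(dat, !in_shared), d$tag, TRUE,
                             n_boot, seed)
    }

    wgrs <- build_wgrs(panel, d$instruments)
    cov_df <- panel$baseline[, covariates, drop = FALSE]
    run_strata <- list(all = rep(TRUE, n),
                       male = panel$baseline$sex == "male",
                       female = panel$baseline$sex == "female")
    for (snm in names(run_strata)) {
      keep <- run_strata[[snm]]
      cvs <- cov_df[keep, setdiff(covariates, if (snm != "all") "sex" else NULL),
                    drop = FALSE]
      fit <- fit_2sls(panel$baseline[[d$exposure]][keep],
                      panel$baseline[[d$outcome]][keep],
                      wgrs[keep], if (ncol(cvs)) cvs else NULL)
      diag_rows[[length(diag_rows) + 1]] <- data.frame(
        direction = d$tag, stratum = snm, effect = fit$estimate$effect,
        se = fit$estimate$se, p = fit$estimate$p,
        first_stage_F = fit$diagnostics$first_stage_F,
        weak_flag = fit$diagnostics$weak_flag,
        wu_hausman_p = fit$diagnostics$wu_hausman_p,
        n = sum(keep), stringsAsFactors = FALSE)
      if (snm == "all") {
        mr_rows[[length(mr_rows) + 1]] <- data.frame(
          direction = d$tag, method = "2SLS", excluded_shared = FALSE,
          effect = fit$estimate$effect, se = fit$estimate$se,
          p = fit$estimate$p, intercept = NA_real_, intercept_se = NA_real_,
          intercept_p = NA_real_, n_instruments = 1L,
          stringsAsFactors = FALSE)
        incr <- if (d$exposure == "fbs") 0.5 else 10   # 0.5 mmol/L or 10 mmHg
        sd_exp <- stats::sd(panel$baseline[[d$exposure]])
        scale_rows[[length(scale_rows) + 1]] <- data.frame(
          direction = d$tag, method = "2SLS",
          per_exposure_unit = fit$estimate$effect,
          per_clinical_increment = fit$estimate$effect * incr,
          clinical_increment = incr,
          per_exposure_sd = fit$estimate$effect * sd_exp,
          exposure_sd = sd_exp, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(mr_table = do.call(rbind, mr_rows),
                 diagnostics = do.call(rbind, diag_rows),
                 scalings = do.call(rbind, scale_rows),
                 shared_ids = shared_ids,
                 split_sample = split_sample, seed = seed),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Bidirectional MR report\n")
  print(x$mr_table, digits = 4)
  invisible(x)
}

#' Write / read the MR report tables
#'
#' @param report an `mr_report`.
#' @param directory output directory; writes `mr_report.tsv` (method by
#'   direction effects) and `mr_diagnostics.tsv` (F, endogeneity, strata).
#' @return the directory, invisibly.
#' @export
write_mr_report <- function(report, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$mr_table, file.path(directory, "mr_report.tsv"))
  write_tsv(report$diagnostics, file.path(directory, "mr_diagnostics.tsv"))
  write_tsv(report$scalings, file.path(directory, "mr_scalings.tsv"))
  invisible(directory)
}

#' @rdname write_mr_report
#' @export
read_mr_report <- function(directory) {
  structure(list(
    mr_table = read_tsv_checked(
      file.path(directory, "mr_report.tsv"),
      numeric_cols = c("effect", "se", "p", "intercept", "intercept_se",
                       "intercept_p")),
    diagnostics = read_tsv_checked(
      file.path(directory, "mr_diagnostics.tsv"),
      numeric_cols = c("effect", "se", "p", "first_stage_F", "wu_hausman_p")),
    scalings = read_tsv_checked(
      file.path(directory, "mr_scalings.tsv"),
      numeric_cols = c("per_exposure_unit", "per_clinical_increment",
                       "per_exposure_sd"))),
    class = "mr_report")
}
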