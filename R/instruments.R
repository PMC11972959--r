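# Instrument selection: variant QC, per-SNP GWAS, greedy LD clumping,
# and weighted genetic risk scores.

#' Variant and subject quality control
#'
#' Subjects with more than `subject_missing_max` missing genotypes are
#' dropped first; variants are then dropped when call rate falls below
#' `call_rate_min`, when the exact Hardy-Weinberg p-value falls below
#' `hwe_p_min`, or when minor allele frequency falls below `maf_min`.
#' A variant with no calls at all is dropped with reason `"no_calls"`.
#'
#' @param panel a `cohort_panel`.
#' @param call_rate_min minimum variant call rate (default 0.96).
#' @param hwe_p_min minimum exact HWE p-value (default 1e-4).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param subject_missing_max maximum per-subject missing fraction (0.05).
#' @return list with the filtered `panel`, the kept `snp_ids` and
#'   `subject_ids`, and a per-variant `report` data frame recording call
#'   rate, MAF, HWE p, and the failing rule for each dropped variant.
#' @export
qc_filter <- function(panel, call_rate_min = 0.96, hwe_p_min = 1e-4,
                      maf_min = 0.01, subject_missing_max = 0.05) {
  stopifnot(inherits(panel, "cohort_panel"))
  G <- panel$genotypes
  if (ncol(G) < 1) stop("panel has no variants", call. = FALSE)

  subj_miss <- rowMeans(is.na(G))
  keep_subj <- subj_miss <= subject_missing_max
  G <- G[keep_subj, , drop = FALSE]

  m <- ncol(G)
  call_rate <- colMeans(!is.na(G))
  maf <- hwe_p <- numeric(m)
  reason <- character(m)
  for (j in seq_len(m)) {
    g <- G[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0) {
      maf[j] <- NA_real_; hwe_p[j] <- NA_real_; reason[j] <- "no_calls"
      next
    }
    p <- mean(g) / 2
    maf[j] <- min(p, 1 - p)
    hwe_p[j] <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
    if (call_rate[j] < call_rate_min) reason[j] <- "call_rate"
    else if (hwe_p[j] < hwe_p_min) reason[j] <- "hwe"
    else if (maf[j] < maf_min) reason[j] <- "maf"
  }
  kept <- reason == ""
  report <- data.frame(snp_id = colnames(G), call_rate = call_rate,
                       maf = maf, hwe_p = hwe_p, kept = kept,
                       reason = ifelse(kept, NA_character_, reason),
                       stringsAsFactors = FALSE)

  out <- panel
  out$subject_ids <- panel$subject_ids[keep_subj]
  out$genotypes <- G[, kept, drop = FALSE]
  out$variant_meta <- panel$variant_meta[kept, , drop = FALSE]
  rownames(out$variant_meta) <- NULL
  out$baseline <- panel$baseline[keep_subj, , drop = FALSE]
  rownames(out$baseline) <- NULL
  out$true_labels <- panel$true_labels[keep_subj]
  out$events <- panel$events[keep_subj, , drop = FALSE]
  rownames(out$events) <- NULL
  out$visits <- panel$visits[panel$visits$subject_id %in% out$subject_ids, ,
                             drop = FALSE]
  rownames(out$visits) <- NULL
  list(panel = out, snp_ids = colnames(G)[kept],
       subject_ids = out$subject_ids, report = report)
}

#' Per-SNP association scan (additive model)
#'
#' Ordinary least squares of the phenotype on each SNP's additive dosage
#' plus covariates (age and sex by default), subjects with a missing dosage
#' excluded per SNP; two-sided p-values from the t distribution. A SNP
#' whose dosage has zero variance after exclusions gets `beta = NA`,
#' `p = 1`, and flag `"zero_variance"`.
#'
#' @param panel a QC-filtered `cohort_panel`.
#' @param phenotype `"fbs"` or `"sbp"` (baseline value).
#' @param covariates baseline covariate columns to adjust for.
#' @return data frame of per-variant summaries: snp_id, chr, pos, alleles,
#'   beta, se, p, n_used, maf, hwe_p, call_rate, flag.
#' @export
run_gwas <- function(panel, phenotype = c("fbs", "sbp"),
                     covariates = c("age", "sex")) {
  phenotype <- match.arg(phenotype)
  y_all <- panel$baseline[[phenotype]]
  if (is.null(y_all)) stop("phenotype column not present", call. = FALSE)
  G <- panel$genotypes
  n <- nrow(G); m <- ncol(G)
  C <- matrix(1, n, 1)
  colnames(C) <- "(Intercept)"
  for (cv in covariates) {
    v <- panel$baseline[[cv]]
    if (is.character(v) || is.factor(v)) {
      mm <- stats::model.matrix(~ v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, seq_len(ncol(mm)))
      C <- cbind(C, mm)
    } else C <- cbind(C, v)
  }
  beta <- se <- pval <- rep(NA_real_, m)
  n_used <- integer(m)
  maf <- call_rate <- hwe_p <- rep(NA_real_, m)
  flag <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    g <- G[, j]
    ok <- !is.na(g) & !is.na(y_all)
    call_rate[j] <- mean(!is.na(g))
    n_used[j] <- sum(ok)
    if (n_used[j] == 0) { flag[j] <- "no_calls"; pval[j] <- 1; next }
    gj <- g[ok]
    pfreq <- mean(gj) / 2
    maf[j] <- min(pfreq, 1 - pfreq)
    hwe_p[j] <- hwe_exact_test(sum(gj == 0), sum(gj == 1), sum(gj == 2))
    if (stats::var(gj) == 0) { flag[j] <- "zero_variance"; pval[j] <- 1; next }
    X <- cbind(gj, C[ok, , drop = FALSE])
    fit <- stats::lm.fit(X, y_all[ok])
    df <- n_used[j] - fit$rank
    if (df <= 0) { flag[j] <- "insufficient_df"; pval[j] <- 1; next }
    sigma2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(chol(crossprod(X)))
    beta[j] <- fit$coefficients[1]
    se[j] <- sqrt(sigma2 * XtXinv[1, 1])
    tstat <- beta[j] / se[j]
    pval[j] <- 2 * stats::pt(-abs(tstat), df)
  }
  vm <- panel$variant_meta
  data.frame(snp_id = vm$snp_id, chr = vm$chr, pos = vm$pos,
             effect_allele = vm$effect_allele, other_allele = vm$other_allele,
             beta = beta, se = se, p = pval, n_used = n_used, maf = maf,
             hwe_p = hwe_p, call_rate = call_rate, flag = flag,
             stringsAsFactors = FALSE)
}

#' Greedy LD clumping of association summaries
#'
#' Variants with `p < p_threshold` are visited in order of ascending
#' p-value (ties broken by snp_id); a variant is retained unless an
#' already-retained variant on the same chromosome within `window_bp`
#' (inclusive at both ends, 1-based coordinates) has squared dosage
#' correlation at least `r2_threshold` with it. With `relax = TRUE` the
#' threshold is stepped through `r2_steps` until `target_count` instruments
#' are retained (or the steps are exhausted).
#'
#' @param summaries a GWAS summary data frame from [run_gwas()].
#' @param genotypes dosage matrix with columns named by snp_id (r-squared
#'   is computed from these dosages, pairwise-complete).
#' @param r2_threshold squared-correlation threshold (default 0.01).
#' @param window_bp window in base pairs (default 1e6).
#' @param p_threshold significance cutoff (default 5e-8).
#' @param relax,target_count,r2_steps optional relaxation loop.
#' @return an `instrument_set`: retained summaries plus the thresholds used.
#' @export
ld_clump <- function(summaries, genotypes, r2_threshold = 0.01,
                     window_bp = 1e6, p_threshold = 5e-8,
                     relax = FALSE, target_count = NULL,
                     r2_steps = c(0.01, 0.02, 0.03)) {
  steps <- if (relax) r2_steps else r2_threshold
  res <- NULL
  for (r2t in steps) {
    res <- clump_once(summaries, genotypes, r2t, window_bp, p_threshold)
    if (!relax || is.null(target_count) || nrow(res) >= target_count) {
      r2_threshold <- r2t
      break
    }
    r2_threshold <- r2t
  }
  if (nrow(res) == 0) warning("LD clumping retained no variants")
  structure(list(variants = res, clump_r2 = r2_threshold,
                 window_bp = window_bp, p_threshold = p_threshold),
            class = "instrument_set")
}

clump_once <- function(summaries, genotypes, r2_threshold, window_bp,
                       p_threshold) {
  cand <- summaries[!is.na(summaries$p) & summaries$p < p_threshold &
                      !is.na(summaries$beta), , drop = FALSE]
  cand <- cand[order(cand$p, cand$snp_id), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (k in kept) {
      if (cand$chr[i] != cand$chr[k]) next
      if (abs(cand$pos[i] - cand$pos[k]) > window_bp) next
      r <- stats::cor(genotypes[, cand$snp_id[i]], genotypes[, cand$snp_id[k]],
                      use = "pairwise.complete.obs")
      if (!is.na(r) && r^2 >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- cand[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set: %d variants (r2 < %g within %g bp, p < %g)\n",
              nrow(x$variants), x$clump_r2, x$window_bp, x$p_threshold))
  invisible(x)
}

#' Weighted genetic risk score
#'
#' `score_i = sum_k beta_k * dosage_ik`, with each SNP oriented to its
#' trait-increasing allele so all weights are nonnegative (a SNP with a
#' negative weight has its dosage reflected to `2 - dosage` and the weight
#' negated). Missing dosages are imputed with the expected dosage
#' `2 * effect-allele frequency` computed from the panel after orientation.
#'
#' @param panel a `cohort_panel`.
#' @param instruments an `instrument_set` (or a data frame with `snp_id`
#'   and `beta` columns).
#' @return named numeric vector of per-subject scores.
#' @export
build_wgrs <- function(panel, instruments) {
  vars <- if (inherits(instruments, "instrument_set")) instruments$variants
          else instruments
  missing_ids <- setdiff(vars$snp_id, colnames(panel$genotypes))
  if (length(missing_ids))
    stop("instrument SNPs absent from panel: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  score <- numeric(length(panel$subject_ids))
  for (k in seq_len(nrow(vars))) {
    b <- vars$beta[k]
    if (is.na(b)) next
    dos <- panel$genotypes[, vars$snp_id[k]]
    if (b < 0) { dos <- 2 - dos; b <- -b }   # orient to trait-increasing allele
    eaf <- mean(dos, na.rm = TRUE) / 2
    dos[is.na(dos)] <- 2 * eaf
    score <- score + b * dos
  }
  names(score) <- panel$subject_ids
  score
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests, at least 1.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  alpha / m
}
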