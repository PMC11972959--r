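# Shared fixtures and independent oracles, all built in code.

# hand-built panel: n subjects x m SNPs with specified dosages
make_panel <- function(genotypes, baseline = NULL, visits = NULL,
                       events = NULL, variant_meta = NULL, config = NULL) {
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  ids <- sprintf("S%03d", seq_len(n))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- sprintf("snp%03d", seq_len(m))
  if (is.null(variant_meta)) {
    variant_meta <- data.frame(
      snp_id = colnames(genotypes), chr = rep_len(1:2, m),
      pos = seq_len(m) * 1000, effect_allele = "A", other_allele = "G",
      true_maf = 0.3, true_beta_fbs = 0, true_beta_sbp = 0,
      in_fbs_set = TRUE, in_sbp_set = FALSE, shared = FALSE,
      stringsAsFactors = FALSE)
  }
  if (is.null(baseline)) {
    baseline <- data.frame(
      subject_id = ids, age = 50 + seq_len(n), sex = rep(c("male", "female"),
      length.out = n), bmi = 24, smoking = "never", alcohol = "none",
      exercise = "no", med_antidiabetic = 0L, med_antihypertensive = 0L,
      fbs = 5, sbp = 120, true_label = 1L, stringsAsFactors = FALSE)
  } else baseline$subject_id <- ids
  if (is.null(visits)) {
    visits <- expand.grid(visit = 1:2, subject_id = ids,
                          stringsAsFactors = FALSE)[, 2:1]
    visits$time_years <- (visits$visit - 1) * 2
    visits$fbs <- 5
    visits$sbp <- 120
  }
  if (is.null(events)) {
    events <- data.frame(subject_id = ids, t2d_time = 10, t2d_event = 0L,
                         htn_time = 10, htn_event = 0L, prev_t2d = 0L,
                         prev_htn = 0L, prev_stroke = 0L,
                         stringsAsFactors = FALSE)
  }
  structure(list(subject_ids = ids, genotypes = genotypes,
                 variant_meta = variant_meta, baseline = baseline,
                 visits = visits, true_labels = baseline$true_label,
                 events = events,
                 config = config %||% sim_config(n_subjects = n,
                                                 n_snps_fbs = max(m, 1),
                                                 n_snps_sbp = 1, n_shared = 0,
                                                 seed = 1)),
            class = "cohort_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent HWE oracle: direct enumeration of the conditional multinomial
# distribution of heterozygote counts given the minor allele count
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na_ <- 2 * n_aa + n_ab
  rare <- min(na_, 2 * n - na_)
  if (rare == 0) return(1)
  h <- seq(rare %% 2, rare, by = 2)
  n1 <- (rare - h) / 2
  n3 <- n - n1 - h
  lp <- lfactorial(n) - lfactorial(n1) - lfactorial(h) - lfactorial(n3) +
    h * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n_ab, h)] * (1 + 1e-10)])
}

# weighted least squares by explicit normal equations (oracle for IVW/Egger)
wls_oracle <- function(X, y, w) {
  solve(crossprod(X, w * X), crossprod(X, w * y))
}

# instrument set straight from the generator's true variant sets, weighted
# by externally supplied (true) per-allele effects
instruments_from_truth <- function(panel, phenotype) {
  vm <- panel$variant_meta
  sel <- vm[[paste0("in_", phenotype, "_set")]]
  vars <- data.frame(snp_id = vm$snp_id[sel], chr = vm$chr[sel],
                     pos = vm$pos[sel],
                     beta = vm[[paste0("true_beta_", phenotype)]][sel],
                     se = 1e-3, p = 1e-10, stringsAsFactors = FALSE)
  structure(list(variants = vars, clump_r2 = 0.01, window_bp = 1e6,
                 p_threshold = 5e-8), class = "instrument_set")
}

# planted two-class trajectory data: flat vs reverse-U, wide matrix
make_planted_series <- function(n, share2 = 0.3, sep_sd = 2, seed = 1) {
  set.seed(seed)
  times <- seq(0, 14, 2)
  lab <- stats::rbinom(n, 1, share2) + 1L
  mu <- rbind(rep(100, length(times)),
              100 + 3.5 * times - 0.25 * times^2)
  Y <- mu[lab, ] + matrix(stats::rnorm(n * length(times), 0, sep_sd),
                          n, length(times))
  attr(Y, "times") <- times
  list(Y = Y, labels = lab, times = times)
}

# subset a two_sample_input by index (negative indices supported)
subset_tsi_test <- function(d, idx) {
  two_sample_input(d$beta_exposure[idx], d$se_exposure[idx],
                   d$beta_outcome[idx], d$se_outcome[idx],
                   d$snp_id[idx], d$direction)
}
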