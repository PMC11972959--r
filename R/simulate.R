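# Synthetic cohort generator.
#
# Emulates a biennial middle-aged cohort (ages 40-69, 8 visits over 14
# years) genotyped on a SNP array, with two phenotypes linked by a
# bidirectional structural model: fasting blood sugar (FBS, mmol/L) and
# systolic blood pressure (SBP, mmHg). Each phenotype has its own set of
# associated variants; one variant (an analog of the ALDH2 locus) carries
# large direct effects on both phenotypes and is a deliberate pleiotropic
# outlier. Latent trajectory classes drive visit-level departures from the
# subject baseline, and incident type-2-diabetes / hypertension times are
# drawn from proportional hazards tied to the risk class.

# internal scale constants (chosen once; see the methods vignette)
.SIM <- list(
  mean_fbs = 4.9, mean_sbp = 117.4,     # population means, mmol/L and mmHg
  resid_sd_fbs = 0.35, resid_sd_sbp = 14,   # structural residual SDs
  conf_load_fbs = 0.2, conf_load_sbp = 8,   # phenotype loadings per unit confounder
  age_eff_fbs = 0.008, age_eff_sbp = 0.35,  # per year of age (centered at 55)
  sex_eff_fbs = 0.15, sex_eff_sbp = 3,      # male vs female
  visit_noise_fbs = 0.25, visit_noise_sbp = 8,
  shared_effect_mult = 3,               # shared variant's effect inflation
  prop_male = 0.474
)

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the emulated study design: ~8,500 genotyped subjects aged
#' 40-69, 91 FBS-associated and 68 SBP-associated variants sharing exactly
#' one SNP, 8 biennial visits spanning 14 years, two latent trajectory
#' classes (the smaller, "uncontrolled" class follows a reverse-U-shaped
#' departure), and administrative censoring 16 years after baseline.
#'
#' @param n_subjects number of subjects.
#' @param n_snps_fbs,n_snps_sbp,n_shared counts of FBS-associated,
#'   SBP-associated, and shared variants (`n_shared <= min` of the two).
#' @param maf_range minor-allele-frequency range, inside (0.01, 0.5].
#' @param beta_scale_x,beta_scale_y SD of per-allele effects on FBS (mmol/L)
#'   and SBP (mmHg).
#' @param causal_fbs_to_sbp causal effect, mmHg per mmol/L.
#' @param causal_sbp_to_fbs causal effect, mmol/L per mmHg.
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct effects of
#'   exposure SNPs on the other phenotype) or `"directional"` (nonzero mean).
#' @param pleiotropy_sd,pleiotropy_mean scale and mean of the direct effects,
#'   in units of the affected phenotype per allele.
#' @param confounder_sd SD of the shared latent confounder (unitless; it
#'   loads on both phenotypes with fixed internal loadings).
#' @param n_visits number of visits (default 8).
#' @param visit_spacing_years years between visits (default 2).
#' @param traj_group_shares latent class shares, summing to 1.
#' @param traj_genetic_link log-odds of membership in the last (risk) class
#'   per SD of combined genetic burden (default 1). The class
#'   probability is calibrated so the population share still matches
#'   `traj_group_shares`; set 0 for genotype-independent classes.
#' @param traj_coefficients list with elements `fbs` and `sbp`, each a list
#'   (one per class) of polynomial coefficients (intercept, linear,
#'   quadratic, cubic) describing the class's departure from the subject
#'   baseline as a function of years since baseline.
#' @param event_model list with elements `t2d` and `htn`, each a list of
#'   `baseline_hazard` (events per person-year) and log hazard ratios
#'   `log_hr_group` (uncontrolled class), `log_hr_age` (per year),
#'   `log_hr_sex` (male), `log_hr_bmi` (per kg/m^2).
#' @param prevalence baseline prevalence probabilities for T2D,
#'   hypertension, and stroke history flags.
#' @param missing_rate genotype missingness fraction.
#' @param censor_date_years administrative censoring horizon, years.
#' @param seed integer seed; the generator is deterministic given it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 8500,
                       n_snps_fbs = 91, n_snps_sbp = 68, n_shared = 1,
                       maf_range = c(0.05, 0.5),
                       beta_scale_x = 0.02, beta_scale_y = 0.6,
                       causal_fbs_to_sbp = 3.26,
                       causal_sbp_to_fbs = 0.063,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0.05, pleiotropy_mean = 0,
                       confounder_sd = 1,
                       n_visits = 8, visit_spacing_years = 2,
                       traj_group_shares = c(0.95, 0.05),
                       traj_genetic_link = 1,
                       traj_coefficients = NULL,
                       event_model = NULL,
                       prevalence = c(t2d = 892 / 8510, htn = 1293 / 8510,
                                      stroke = 34 / 8510),
                       missing_rate = 0.02,
                       censor_date_years = 16,
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  K <- length(traj_group_shares)
  if (is.null(traj_coefficients)) {
    # class K fluctuates: rises then falls back (reverse U over 14 years)
    traj_coefficients <- list(
      fbs = c(list(c(0, 0, 0, 0))[rep(1, K - 1)], list(c(0.4, 0.12, -0.009, 0))),
      sbp = c(list(c(0, 0, 0, 0))[rep(1, K - 1)], list(c(8, 3.5, -0.25, 0)))
    )
    if (K == 1) traj_coefficients <- list(fbs = list(c(0, 0, 0, 0)),
                                          sbp = list(c(0, 0, 0, 0)))
  }
  if (is.null(event_model)) {
    event_model <- list(
      t2d = list(baseline_hazard = 0.055, log_hr_group = log(1.25),
                 log_hr_age = 0.015, log_hr_sex = 0.10, log_hr_bmi = 0.04),
      htn = list(baseline_hazard = 0.075, log_hr_group = log(1.77),
                 log_hr_age = 0.02, log_hr_sex = 0.12, log_hr_bmi = 0.05)
    )
  }
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_snps_fbs = as.integer(n_snps_fbs),
              n_snps_sbp = as.integer(n_snps_sbp),
              n_shared = as.integer(n_shared),
              maf_range = maf_range,
              beta_scale_x = beta_scale_x, beta_scale_y = beta_scale_y,
              causal_fbs_to_sbp = causal_fbs_to_sbp,
              causal_sbp_to_fbs = causal_sbp_to_fbs,
              pleiotropy_mode = pleiotropy_mode,
              pleiotropy_sd = pleiotropy_sd, pleiotropy_mean = pleiotropy_mean,
              confounder_sd = confounder_sd,
              n_visits = as.integer(n_visits),
              visit_spacing_years = visit_spacing_years,
              traj_group_shares = traj_group_shares,
              traj_genetic_link = traj_genetic_link,
              traj_coefficients = traj_coefficients,
              event_model = event_model,
              prevalence = prevalence,
              missing_rate = missing_rate,
              censor_date_years = censor_date_years,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(cfg$n_subjects, cfg$n_snps_fbs, cfg$n_snps_sbp, cfg$n_visits)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (cfg$n_shared < 0 || cfg$n_shared > min(cfg$n_snps_fbs, cfg$n_snps_sbp))
    stop("n_shared must be in [0, min(n_snps_fbs, n_snps_sbp)]", call. = FALSE)
  if (cfg$maf_range[1] <= 0.01 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0.01, 0.5]", call. = FALSE)
  if (abs(sum(cfg$traj_group_shares) - 1) > 1e-12)
    stop("traj_group_shares must sum to 1", call. = FALSE)
  if (any(cfg$traj_group_shares < 0))
    stop("traj_group_shares must be nonnegative", call. = FALSE)
  if (abs(cfg$causal_fbs_to_sbp * cfg$causal_sbp_to_fbs) >= 1)
    stop("structural system is singular: |causal_fbs_to_sbp * causal_sbp_to_fbs| >= 1",
         call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  K <- length(cfg$traj_group_shares)
  if (length(cfg$traj_coefficients$fbs) != K ||
      length(cfg$traj_coefficients$sbp) != K)
    stop("traj_coefficients must supply one coefficient vector per class and phenotype",
         call. = FALSE)
  invisible(cfg)
}

#' Generate a synthetic cohort panel
#'
#' Draws genotypes in Hardy-Weinberg proportions (`Binomial(2, maf)` per
#' SNP), solves the bidirectional structural model for baseline FBS and SBP
#' as a 2x2 linear simultaneous system (so both stated causal effects hold
#' at once), layers latent-class polynomial trajectories and visit noise on
#' top of the baseline, and draws incident T2D / hypertension times from
#' exponential hazards with class, age, sex and BMI log hazard ratios.
#' Administrative censoring applies at `censor_date_years`. Deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `cohort_panel`: list with `subject_ids`, `genotypes` (additive
#'   dosage matrix, `NA` for missing), `variant_meta`, `baseline`, `visits`
#'   (long format), `true_labels`, `events`, and the generating `config`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  n_total <- config$n_snps_fbs + config$n_snps_sbp - config$n_shared
  idx_fbs <- seq_len(config$n_snps_fbs)
  idx_sbp <- seq(config$n_snps_fbs - config$n_shared + 1, n_total)
  idx_shared <- intersect(idx_fbs, idx_sbp)

  # variant metadata: positions spread over 22 chromosomes so that the
  # clumping window is exercised but unlinked draws dominate
  chr <- rep_len(1:22, n_total)
  pos <- sample.int(2.4e8, n_total, replace = TRUE)
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n_total, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), "")
  maf <- stats::runif(n_total, config$maf_range[1], config$maf_range[2])

  beta_fbs <- numeric(n_total)
  beta_sbp <- numeric(n_total)
  beta_fbs[idx_fbs] <- stats::rnorm(length(idx_fbs), 0, config$beta_scale_x)
  beta_sbp[idx_sbp] <- stats::rnorm(length(idx_sbp), 0, config$beta_scale_y)
  if (length(idx_shared)) {  # shared variants: large effects on both traits
    beta_fbs[idx_shared] <- beta_fbs[idx_shared] * .SIM$shared_effect_mult
    beta_sbp[idx_shared] <- beta_sbp[idx_shared] * .SIM$shared_effect_mult
  }

  # horizontal pleiotropy: direct effects of each exposure set's non-shared
  # SNPs on the *other* phenotype
  plei_on_sbp <- numeric(n_total)  # FBS instruments acting on SBP
  plei_on_fbs <- numeric(n_total)  # SBP instruments acting on FBS
  if (config$pleiotropy_mode != "none") {
    mu <- if (config$pleiotropy_mode == "directional") config$pleiotropy_mean else 0
    own_fbs <- setdiff(idx_fbs, idx_shared)
    own_sbp <- setdiff(idx_sbp, idx_shared)
    plei_on_sbp[own_fbs] <- stats::rnorm(length(own_fbs), mu, config$pleiotropy_sd)
    plei_on_fbs[own_sbp] <- stats::rnorm(length(own_sbp), mu, config$pleiotropy_sd)
  }

  variant_meta <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(n_total)),
    chr = chr, pos = pos, effect_allele = ea, other_allele = oa,
    true_maf = maf, true_beta_fbs = beta_fbs, true_beta_sbp = beta_sbp,
    in_fbs_set = seq_len(n_total) %in% idx_fbs,
    in_sbp_set = seq_len(n_total) %in% idx_sbp,
    shared = seq_len(n_total) %in% idx_shared,
    stringsAsFactors = FALSE
  )

  G <- matrix(stats::rbinom(n * n_total, 2L, rep(maf, each = n)),
              nrow = n, ncol = n_total)
  colnames(G) <- variant_meta$snp_id

  subject_ids <- sprintf("S%06d", seq_len(n))
  age <- round(stats::runif(n, 40, 69))
  sex <- ifelse(stats::rbinom(n, 1, .SIM$prop_male) == 1, "male", "female")
  male <- as.integer(sex == "male")
  bmi <- stats::rnorm(n, 24.5, 3.1)
  smoking <- sample(c("never", "former", "current"), n, TRUE, c(0.60, 0.15, 0.25))
  alcohol <- sample(c("none", "moderate", "heavy"), n, TRUE, c(0.45, 0.40, 0.15))
  exercise <- sample(c("no", "yes"), n, TRUE, c(0.70, 0.30))
  prev_t2d <- stats::rbinom(n, 1, config$prevalence[["t2d"]])
  prev_htn <- stats::rbinom(n, 1, config$prevalence[["htn"]])
  prev_stroke <- stats::rbinom(n, 1, config$prevalence[["stroke"]])
  med_antidiabetic <- stats::rbinom(n, 1, ifelse(prev_t2d == 1, 0.7, 0.02))
  med_antihypertensive <- stats::rbinom(n, 1, ifelse(prev_htn == 1, 0.7, 0.05))

  U <- stats::rnorm(n, 0, config$confounder_sd)

  # structural system: F = fx + b_sf * S ; S = sy + b_fs * F
  gx <- G %*% beta_fbs + G %*% plei_on_fbs
  gy <- G %*% beta_sbp + G %*% plei_on_sbp
  fx <- as.numeric(gx) + .SIM$conf_load_fbs * U +
    .SIM$age_eff_fbs * (age - 55) + .SIM$sex_eff_fbs * male +
    stats::rnorm(n, 0, .SIM$resid_sd_fbs)
  sy <- as.numeric(gy) + .SIM$conf_load_sbp * U +
    .SIM$age_eff_sbp * (age - 55) + .SIM$sex_eff_sbp * male +
    stats::rnorm(n, 0, .SIM$resid_sd_sbp)
  b_sf <- config$causal_sbp_to_fbs
  b_fs <- config$causal_fbs_to_sbp
  det <- 1 - b_sf * b_fs
  fbs0 <- (fx + b_sf * sy) / det
  sbp0 <- (sy + b_fs * fx) / det
  fbs0 <- fbs0 - mean(fbs0) + .SIM$mean_fbs
  sbp0 <- sbp0 - mean(sbp0) + .SIM$mean_sbp

  # latent classes; the last class ("uncontrolled") is tilted toward high
  # blood-pressure genetic burden, with the population share calibrated to
  # traj_group_shares
  K <- length(config$traj_group_shares)
  share_K <- config$traj_group_shares[K]
  std0 <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v)
                      else rep(0, length(v))
  liab <- std0(as.numeric(G %*% beta_sbp)) + std0(as.numeric(G %*% beta_fbs))
  b_link <- config$traj_genetic_link %||% 1
  if (stats::sd(liab) > 0 && b_link != 0 && K > 1 &&
      share_K > 0 && share_K < 1) {
    l <- (liab - mean(liab)) / stats::sd(liab)
    a <- stats::uniroot(function(a) mean(stats::plogis(a + b_link * l)) -
                          share_K, c(-30, 30))$root
    p_K <- stats::plogis(a + b_link * l)
  } else {
    p_K <- rep(share_K, n)
  }
  labels <- integer(n)
  in_K <- stats::runif(n) < p_K
  labels[in_K] <- K
  if (K > 1) {
    rest <- config$traj_group_shares[-K]
    rest <- if (sum(rest) > 0) rest / sum(rest) else rep(1 / (K - 1), K - 1)
    labels[!in_K] <- sample.int(K - 1, sum(!in_K), replace = TRUE,
                                prob = rest)
  } else labels[] <- 1L

  times <- (seq_len(config$n_visits) - 1) * config$visit_spacing_years
  poly_at <- function(coefs, t) {
    coefs[1] + coefs[2] * t + coefs[3] * t^2 + coefs[4] * t^3
  }
  dev_fbs <- vapply(times, function(t)
    vapply(config$traj_coefficients$fbs, poly_at, 0, t = t)[labels], numeric(n))
  dev_sbp <- vapply(times, function(t)
    vapply(config$traj_coefficients$sbp, poly_at, 0, t = t)[labels], numeric(n))
  Tn <- config$n_visits
  fbs_visits <- fbs0 + dev_fbs + matrix(stats::rnorm(n * Tn, 0, .SIM$visit_noise_fbs), n, Tn)
  sbp_visits <- sbp0 + dev_sbp + matrix(stats::rnorm(n * Tn, 0, .SIM$visit_noise_sbp), n, Tn)
  visits <- data.frame(
    subject_id = rep(subject_ids, times = Tn),
    visit = rep(seq_len(Tn), each = n),
    time_years = rep(times, each = n),
    fbs = as.numeric(fbs_visits),
    sbp = as.numeric(sbp_visits),
    stringsAsFactors = FALSE
  )
  visits <- visits[order(visits$subject_id, visits$visit), ]
  rownames(visits) <- NULL

  draw_events <- function(em) {
    lp <- em$log_hr_group * (labels == K) + em$log_hr_age * (age - 55) +
      em$log_hr_sex * male + em$log_hr_bmi * (bmi - 24.5)
    raw <- stats::rexp(n, rate = em$baseline_hazard * exp(lp))
    event <- as.integer(raw <= config$censor_date_years)
    time <- pmin(raw, config$censor_date_years)
    list(time = time, event = event)
  }
  ev_t2d <- draw_events(config$event_model$t2d)
  ev_htn <- draw_events(config$event_model$htn)
  events <- data.frame(
    subject_id = subject_ids,
    t2d_time = ev_t2d$time, t2d_event = ev_t2d$event,
    htn_time = ev_htn$time, htn_event = ev_htn$event,
    prev_t2d = prev_t2d, prev_htn = prev_htn, prev_stroke = prev_stroke,
    stringsAsFactors = FALSE
  )

  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * n_total) < config$missing_rate, n, n_total)
    G[miss] <- NA_integer_
  }

  baseline <- data.frame(
    subject_id = subject_ids, age = age, sex = sex, bmi = bmi,
    smoking = smoking, alcohol = alcohol, exercise = exercise,
    med_antidiabetic = med_antidiabetic,
    med_antihypertensive = med_antihypertensive,
    fbs = fbs0, sbp = sbp0, true_label = labels,
    stringsAsFactors = FALSE
  )

  structure(list(subject_ids = subject_ids, genotypes = G,
                 variant_meta = variant_meta, baseline = baseline,
                 visits = visits, true_labels = labels, events = events,
                 config = config),
            class = "cohort_panel")
}

#' @export
print.cohort_panel <- function(x, ...) {
  cat(sprintf("cohort_panel: %d subjects, %d variants, %d visits\n",
              length(x$subject_ids), ncol(x$genotypes),
              length(unique(x$visits$visit))))
  cat(sprintf("  FBS-set %d SNPs, SBP-set %d SNPs, shared %d\n",
              sum(x$variant_meta$in_fbs_set), sum(x$variant_meta$in_sbp_set),
              sum(x$variant_meta$shared)))
  invisible(x)
}
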