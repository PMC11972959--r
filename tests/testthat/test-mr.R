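test_that("2SLS reduces to OLS with a perfect instrument and to the Wald ratio without covariates", {
  set.seed(21)
  n <- 200
  x <- stats::rnorm(n)
  y <- 1.5 * x + stats::rnorm(n)
  cov <- data.frame(age = stats::rnorm(n, 50, 4))
  f_iv <- fit_2sls(x, y, instrument = x, covariates = cov)
  ols <- stats::lm(y ~ x + cov$age)
  expect_equal(f_iv$estimate$effect, unname(stats::coef(ols)[2]),
               tolerance = 1e-10)

  # 12-subject fixture: point estimate = cov(Z,Y)/cov(Z,X)
  set.seed(22)
  z <- stats::rnorm(12)
  x12 <- 0.8 * z + stats::rnorm(12)
  y12 <- 0.5 * x12 + stats::rnorm(12)
  f <- fit_2sls(x12, y12, z)
  expect_equal(f$estimate$effect, stats::cov(z, y12) / stats::cov(z, x12),
               tolerance = 1e-12)
})

test_that("2SLS rejects degenerate instruments and flags weak ones", {
  set.seed(23)
  n <- 60
  x <- stats::rnorm(n); y <- stats::rnorm(n)
  expect_error(fit_2sls(x, y, rep(1, n)), "zero variance")
  cov <- data.frame(a = stats::rnorm(n))
  expect_error(fit_2sls(x, y, 2 * cov$a + 3, cov), "collinear")
  f <- fit_2sls(x, y, stats::rnorm(n))   # junk instrument
  expect_true(f$diagnostics$weak_flag)
})

test_that("2SLS removes confounding bias that OLS retains", {
  # structural truth: y = 0.05 x + confounder; instrument only drives x
  reps <- 60
  est_iv <- est_ols <- numeric(reps)
  set.seed(24)
  for (r in seq_len(reps)) {
    n <- 1500
    z <- stats::rnorm(n)
    u <- stats::rnorm(n)
    x <- z + 2 * u + stats::rnorm(n)
    y <- 0.05 * x - 0.5 * u + stats::rnorm(n)
    est_iv[r] <- fit_2sls(x, y, z)$estimate$effect
    est_ols[r] <- stats::coef(stats::lm(y ~ x))[2]
  }
  mcse <- stats::sd(est_iv) / sqrt(reps)
  expect_lt(abs(mean(est_iv) - 0.05), 3 * mcse)
  expect_gt(abs(mean(est_ols) - 0.05), 10 * mcse)  # OLS visibly biased
})

test_that("IVW equals the Wald ratio for one variant and the WLS oracle in general", {
  d1 <- two_sample_input(2, 0.1, 1, 0.1)
  e1 <- mr_ivw(d1)
  expect_equal(e1$effect, 0.5, tolerance = 1e-12)

  # identical ratios collapse to that ratio regardless of weights
  d2 <- two_sample_input(c(1, 2, 4), c(0.1, 0.2, 0.1),
                         c(0.7, 1.4, 2.8), c(0.3, 0.1, 0.2))
  expect_equal(mr_ivw(d2)$effect, 0.7, tolerance = 1e-12)

  set.seed(25)
  m <- 20
  bx <- stats::rnorm(m, 0.1, 0.05)
  by <- 0.4 * bx + stats::rnorm(m, 0, 0.02)
  sey <- stats::runif(m, 0.01, 0.05)
  d3 <- two_sample_input(bx, rep(0.01, m), by, sey)
  est <- mr_ivw(d3)
  oracle <- wls_oracle(matrix(bx), by, 1 / sey^2)
  expect_equal(est$effect, oracle[1, 1], tolerance = 1e-10)
  expect_equal(est$se, sqrt(1 / sum(bx^2 / sey^2)), tolerance = 1e-12)

  d4 <- two_sample_input(c(0, bx), rep(0.01, m + 1), c(0.5, by),
                         c(0.1, sey))
  expect_warning(e4 <- mr_ivw(d4), "zero exposure")
  expect_equal(e4$effect, est$effect, tolerance = 1e-12)
})

test_that("median estimators: simple median, weight degeneracy, breakdown, duplication invariance", {
  rat <- c(1, 1, 1, 5, 9)
  d <- two_sample_input(rep(1, 5), rep(0.1, 5), rat, rep(0.1, 5))
  expect_equal(mr_median(d, weighted = FALSE, n_boot = 100)$effect, 1)
  # equal weights make the weighted median equal the simple median
  expect_equal(mr_median(d, weighted = TRUE, n_boot = 100)$effect,
               mr_median(d, weighted = FALSE, n_boot = 100)$effect,
               tolerance = 1e-12)

  # slight majority of valid instruments at ratio 0.4, invalid at 2.0
  bx <- rep(1, 21)
  by <- c(rep(0.4, 11), rep(2.0, 10))
  sey <- c(rep(0.095, 11), rep(0.1, 10))   # valid ones slightly up-weighted
  db <- two_sample_input(bx, rep(0.01, 21), by, sey)
  est <- mr_median(db, weighted = TRUE, n_boot = 1000, seed = 4)
  expect_lt(abs(est$effect - 0.4), 0.05)

  # duplicating the median-carrying variant with its weight split in half
  # leaves the point estimate unchanged (the half-weight copies bracket the
  # 50% crossing, where the interpolation estimator is flat)
  dd <- two_sample_input(c(1, 1, 1), rep(0.01, 3),
                         c(0.2, 0.5, 0.9), c(0.3, 0.1, 0.3))
  dd2 <- two_sample_input(c(1, 1, 1, 1), rep(0.01, 4),
                          c(0.2, 0.5, 0.5, 0.9),
                          c(0.3, 0.1 * sqrt(2), 0.1 * sqrt(2), 0.3))
  expect_equal(mr_median(dd, weighted = TRUE, n_boot = 100)$effect,
               mr_median(dd2, weighted = TRUE, n_boot = 100)$effect,
               tolerance = 1e-12)
  expect_warning(mr_median(dd, weighted = FALSE, n_boot = 50), "unstable")
  expect_error(mr_median(two_sample_input(1, 1, 1, 1)), "at least 3")
})

test_that("MR-Egger matches the weighted normal-equations oracle and detects exact lines", {
  # points exactly on a line through the origin: intercept 0, p = 1
  bx <- c(0.05, 0.1, 0.2, 0.4)
  d0 <- two_sample_input(bx, rep(0.01, 4), 0.7 * bx, rep(0.05, 4))
  e0 <- mr_egger(d0)
  expect_equal(e0$intercept, 0, tolerance = 1e-12)
  expect_equal(e0$effect, 0.7, tolerance = 1e-12)
  expect_equal(e0$intercept_p, 1, tolerance = 1e-10)

  set.seed(26)
  m <- 15
  bxm <- abs(stats::rnorm(m, 0.15, 0.05))
  sey <- stats::runif(m, 0.02, 0.06)
  bym <- 0.02 + 0.5 * bxm + stats::rnorm(m, 0, 0.03)
  dm <- two_sample_input(bxm, rep(0.01, m), bym, sey)
  em <- mr_egger(dm)
  oracle <- wls_oracle(cbind(1, bxm), bym, 1 / sey^2)
  expect_equal(as.numeric(em$intercept), as.numeric(oracle[1, 1]),
               tolerance = 1e-10)
  expect_equal(as.numeric(em$effect), as.numeric(oracle[2, 1]),
               tolerance = 1e-10)

  # orientation: flipping a variant's signs leaves the fit unchanged
  dm2 <- dm
  dm2$beta_exposure[3] <- -dm2$beta_exposure[3]
  dm2$beta_outcome[3] <- -dm2$beta_outcome[3]
  em2 <- mr_egger(dm2)
  expect_equal(em2$effect, em$effect, tolerance = 1e-12)

  expect_error(mr_egger(two_sample_input(c(1, 1, 1), rep(0.1, 3),
                                         c(1, 2, 3), rep(0.1, 3))),
               "unidentifiable")
})

test_that("Egger intercept test has power against planted directional pleiotropy", {
  set.seed(27)
  reps <- 150; m <- 60
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    bx <- abs(stats::rnorm(m, 0.12, 0.04))
    sey <- rep(0.05, m)
    alpha <- 0.08                      # directional pleiotropy, outcome units
    by <- alpha + 0.5 * bx + stats::rnorm(m, 0, sey)
    est <- mr_egger(two_sample_input(bx, rep(0.01, m), by, sey))
    rej[r] <- est$intercept_p < 0.05
  }
  expect_gte(mean(rej), 0.8)
})

test_that("leave-one-out pinpoints a planted pleiotropic outlier", {
  # one low-exposure-coefficient variant with a direct outcome effect: high
  # leverage on the Egger intercept, so its exclusion flips the pleiotropy
  # verdict
  bx <- c(0.02, seq(0.2, 0.38, by = 0.01))
  m <- length(bx)
  sey <- rep(0.02, m)
  by <- 0.5 * bx
  by[1] <- by[1] + 0.08
  d <- two_sample_input(bx, rep(0.01, m), by, sey,
                        snp_id = sprintf("rs%02d", 1:m))
  full <- mr_egger(d)
  expect_lt(full$intercept_p, 0.05)
  loo <- leave_one_out(d, "egger")
  expect_identical(loo$excluded[loo$flagged], "rs01")

  # homogeneous ratios: nothing flagged
  dh <- two_sample_input(bx, rep(0.01, m), 0.5 * bx, sey)
  expect_false(any(leave_one_out(dh, "egger")$flagged))

  # excluding a variant from IVW equals IVW on the subset, by definition
  loo_ivw <- leave_one_out(d, "ivw")
  direct <- mr_ivw(subset_tsi_test(d, -3))
  expect_equal(loo_ivw$effect[3], direct$effect, tolerance = 1e-14)
})

test_that("single-variant IVW and 2SLS coincide on a shared fixture", {
  set.seed(29)
  n <- 400
  g <- stats::rbinom(n, 2, 0.3)
  x <- 0.4 * g + stats::rnorm(n)
  y <- 0.6 * x + stats::rnorm(n)
  f2 <- fit_2sls(x, y, g)
  # summary coefficients from the same sample, same single variant
  sx <- summary(stats::lm(x ~ g))$coefficients[2, 1:2]
  sy <- summary(stats::lm(y ~ g))$coefficients[2, 1:2]
  ivw <- mr_ivw(two_sample_input(sx[1], sx[2], sy[1], sy[2]))
  expect_equal(ivw$effect, f2$estimate$effect, tolerance = 1e-6)
})

test_that("bidirectional driver is calibrated under the causal null", {
  seeds <- 1:30
  pvals <- matrix(NA_real_, length(seeds), 10)
  fbs_sbp_cover <- logical(length(seeds))
  for (i in seq_along(seeds)) {
    cfg <- sim_config(n_subjects = 600, n_snps_fbs = 12, n_snps_sbp = 12,
                      n_shared = 0, beta_scale_x = 0.3, beta_scale_y = 4,
                      causal_fbs_to_sbp = 0, causal_sbp_to_fbs = 0,
                      missing_rate = 0, seed = 1000 + seeds[i])
    panel <- generate_cohort(cfg)
    rep_ <- run_bidirectional(panel,
                              instruments_from_truth(panel, "fbs"),
                              instruments_from_truth(panel, "sbp"),
                              n_boot = 200, seed = seeds[i])
    tab <- rep_$mr_table[!rep_$mr_table$excluded_shared, ]
    pvals[i, ] <- tab$p
    r2sls <- tab[tab$method == "2SLS" & tab$direction == "FBS->SBP", ]
    ci <- r2sls$effect + c(-1.96, 1.96) * r2sls$se
    fbs_sbp_cover[i] <- ci[1] <= 0 && ci[2] >= 0
  }
  # pooled type-I error across methods and directions near nominal
  frac <- mean(pvals < 0.05)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.12)
  # the null-direction 2SLS interval covers zero at roughly 95%
  expect_gte(mean(fbs_sbp_cover), 0.85)
})

test_that("bidirectional report has the expected shape and round-trips", {
  cfg <- sim_config(n_subjects = 500, n_snps_fbs = 10, n_snps_sbp = 10,
                    n_shared = 1, beta_scale_x = 0.3, beta_scale_y = 4,
                    missing_rate = 0, seed = 77)
  panel <- generate_cohort(cfg)
  rep_ <- run_bidirectional(panel, instruments_from_truth(panel, "fbs"),
                            instruments_from_truth(panel, "sbp"),
                            n_boot = 150, seed = 2)
  tab <- rep_$mr_table
  expect_setequal(unique(tab$direction), c("FBS->SBP", "SBP->FBS"))
  expect_setequal(unique(tab$method),
                  c("IVW", "simple_median", "weighted_median", "MR_Egger",
                    "2SLS"))
  # shared variant present in both sets triggers the excluded re-analysis
  expect_true(any(tab$excluded_shared))
  expect_true(all(tab$n_instruments[tab$excluded_shared] <
                    max(tab$n_instruments[!tab$excluded_shared])))
  # Egger rows carry intercepts, others do not
  expect_true(all(!is.na(tab$intercept[tab$method == "MR_Egger"])))
  expect_true(all(is.na(tab$intercept[tab$method == "IVW"])))
  d <- withr::local_tempdir()
  write_mr_report(rep_, d)
  back <- read_mr_report(d)
  expect_equal(back$mr_table$effect, tab$effect, tolerance = 1e-15)
  expect_equal(back$diagnostics$first_stage_F, rep_$diagnostics$first_stage_F,
               tolerance = 1e-15)
})
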