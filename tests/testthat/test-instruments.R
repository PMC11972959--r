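test_that("HWE exact test matches the full-enumeration oracle", {
  # frozen value computed with the enumeration oracle for the worked counts
  expect_equal(hwe_exact_test(298, 489, 213), 0.6556635, tolerance = 1e-6)
  cases <- rbind(
    c(298, 489, 213), c(0, 0, 50), c(50, 0, 0), c(10, 1, 0), c(968, 31, 1),
    c(5, 10, 5), c(900, 95, 5), c(100, 200, 100), c(3, 0, 3), c(0, 20, 0))
  for (i in seq_len(nrow(cases))) {
    expect_equal(hwe_exact_test(cases[i, 1], cases[i, 2], cases[i, 3]),
                 hwe_oracle(cases[i, 1], cases[i, 2], cases[i, 3]),
                 tolerance = 1e-10,
                 info = paste("counts", paste(cases[i, ], collapse = "/")))
  }
  set.seed(31)
  for (r in 1:30) {
    maf <- stats::runif(1, 0.01, 0.5)
    g <- stats::rbinom(200, 2, maf)
    cnt <- tabulate(g + 1L, 3L)
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
})

test_that("qc_filter applies the call-rate, HWE and MAF rules and is idempotent", {
  set.seed(8)
  n <- 1000
  # enough clean variants that the special-case columns cannot push any
  # subject over the 5% missing rule
  clean <- matrix(stats::rbinom(n * 100, 2, 0.3), n, 100,
                  dimnames = list(NULL, sprintf("ok%03d", 1:100)))
  good <- stats::rbinom(n, 2, 0.3)
  mono <- rep(0L, n)                            # MAF 0
  low_call <- good; low_call[seq_len(50)] <- NA # call rate 0.95 < 0.96
  hwe_bad <- c(rep(0L, 500), rep(2L, 500))      # no heterozygotes
  all_miss <- rep(NA_integer_, n)
  G <- cbind(clean, good = good, mono = mono, low_call = low_call,
             hwe_bad = hwe_bad, all_miss = all_miss)
  panel <- make_panel(G)
  res <- qc_filter(panel)
  expect_setequal(res$snp_ids, c(colnames(clean), "good"))
  rep_ <- res$report
  expect_identical(rep_$reason[rep_$snp_id == "mono"], "maf")
  expect_identical(rep_$reason[rep_$snp_id == "low_call"], "call_rate")
  expect_identical(rep_$reason[rep_$snp_id == "hwe_bad"], "hwe")
  expect_identical(rep_$reason[rep_$snp_id == "all_miss"], "no_calls")
  # idempotence
  res2 <- qc_filter(res$panel)
  expect_identical(res2$snp_ids, res$snp_ids)
  expect_identical(res2$subject_ids, res$subject_ids)
})

test_that("qc_filter drops subjects with more than 5% missing genotypes", {
  set.seed(9)
  G <- matrix(stats::rbinom(20 * 40, 2, 0.3), 20, 40)
  G[1, 1:3] <- NA     # 7.5% missing -> dropped
  G[2, 1:2] <- NA     # 5% missing -> kept (rule is strictly greater)
  panel <- make_panel(G)
  res <- qc_filter(panel)
  expect_false("S001" %in% res$subject_ids)
  expect_true("S002" %in% res$subject_ids)
})

test_that("per-SNP GWAS matches the least-squares oracle", {
  set.seed(11)
  n <- 30
  G <- matrix(stats::rbinom(n * 4, 2, 0.4), n, 4)
  base <- data.frame(age = stats::rnorm(n, 50, 5),
                     sex = sample(c("male", "female"), n, TRUE))
  base$fbs <- 5 + 0.3 * G[, 1] - 0.2 * G[, 2] + 0.01 * base$age +
    0.1 * (base$sex == "male") + stats::rnorm(n, 0, 0.4)
  base$sbp <- 120
  base$bmi <- 24; base$smoking <- "never"; base$alcohol <- "none"
  base$exercise <- "no"; base$med_antidiabetic <- 0L
  base$med_antihypertensive <- 0L; base$true_label <- 1L
  panel <- make_panel(G, baseline = base)
  gw <- run_gwas(panel, "fbs")
  for (j in 1:4) {
    fit <- stats::lm(base$fbs ~ G[, j] + base$age + base$sex)
    sm <- summary(fit)$coefficients
    expect_equal(gw$beta[j], unname(sm[2, 1]), tolerance = 1e-10)
    expect_equal(gw$se[j], unname(sm[2, 2]), tolerance = 1e-10)
    expect_equal(gw$p[j], unname(sm[2, 4]), tolerance = 1e-10)
  }
})

test_that("GWAS handles exact fits, zero-variance dosages and missing calls", {
  n <- 40
  set.seed(12)
  G <- cbind(a = stats::rbinom(n, 2, 0.5), b = rep(1L, n),
             c = stats::rbinom(n, 2, 0.4))
  G[1:5, "c"] <- NA
  base <- make_panel(G)$baseline
  base$fbs <- 0.5 * G[, "a"]          # exact linear in dosage
  panel <- make_panel(G, baseline = base)
  gw <- run_gwas(panel, "fbs", covariates = character(0))
  expect_equal(gw$beta[1], 0.5, tolerance = 1e-12)
  expect_lt(gw$se[1], 1e-8)
  expect_identical(gw$flag[2], "zero_variance")
  expect_true(is.na(gw$beta[2]))
  expect_equal(gw$p[2], 1)
  expect_equal(gw$n_used[3], n - 5L)
})

test_that("GWAS p-values are calibrated under a permuted phenotype", {
  set.seed(13)
  n <- 500
  G <- matrix(stats::rbinom(n * 400, 2, 0.3), n, 400)
  base <- make_panel(G)$baseline
  base$fbs <- sample(stats::rnorm(n, 5, 0.5))
  panel <- make_panel(G, baseline = base)
  gw <- run_gwas(panel, "fbs")
  frac <- mean(gw$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("LD clumping is greedy by p, window- and chromosome-aware", {
  set.seed(14)
  n <- 300
  g1 <- stats::rbinom(n, 2, 0.4)
  G <- cbind(s1 = g1, s2 = g1,                       # perfect LD pair
             s3 = stats::rbinom(n, 2, 0.4))          # other chromosome
  summaries <- data.frame(
    snp_id = c("s1", "s2", "s3"), chr = c(1, 1, 2),
    pos = c(1e5, 1.01e5, 1e5), beta = 0.5, se = 0.1,
    p = c(1e-10, 1e-9, 1e-9), stringsAsFactors = FALSE)
  res <- ld_clump(summaries, G)
  expect_identical(res$variants$snp_id, c("s1", "s3"))

  # same pair placed beyond the window is never clumped
  summaries$pos <- c(1e5, 1e5 + 1.5e6, 1e5)
  res2 <- ld_clump(summaries, G)
  expect_setequal(res2$variants$snp_id, c("s1", "s2", "s3"))
})

test_that("clumping output matches the greedy characterization oracle and is order-invariant", {
  set.seed(15)
  n <- 400; m <- 10
  base_g <- matrix(stats::rbinom(n * m, 2, 0.3), n, m)
  # induce block correlation among SNPs 1-4 and 5-6
  for (j in 2:4) base_g[, j] <- ifelse(stats::runif(n) < 0.8, base_g[, 1],
                                       base_g[, j])
  base_g[, 6] <- ifelse(stats::runif(n) < 0.9, base_g[, 5], base_g[, 6])
  colnames(base_g) <- sprintf("v%02d", 1:m)
  summaries <- data.frame(
    snp_id = colnames(base_g), chr = 1, pos = seq_len(m) * 1e4,
    beta = 0.2, se = 0.05, p = stats::runif(m, 1e-12, 1e-9),
    stringsAsFactors = FALSE)
  res <- ld_clump(summaries, base_g, r2_threshold = 0.1)
  kept <- res$variants$snp_id
  r2 <- stats::cor(base_g)^2
  # (a) no retained pair conflicts
  for (a in kept) for (b in setdiff(kept, a))
    expect_lt(r2[a, b], 0.1)
  # (b) every dropped candidate conflicts with a retained, more significant one
  dropped <- setdiff(summaries$snp_id, kept)
  for (d in dropped) {
    conf <- kept[r2[d, kept] >= 0.1 &
                   summaries$p[match(kept, summaries$snp_id)] <=
                   summaries$p[summaries$snp_id == d]]
    expect_gt(length(conf), 0)
  }
  # row-order invariance
  perm <- sample(m)
  res_perm <- ld_clump(summaries[perm, ], base_g, r2_threshold = 0.1)
  expect_identical(sort(res_perm$variants$snp_id), sort(kept))
})

test_that("wGRS computes weighted allele scores with orientation and mean imputation", {
  G <- matrix(c(0, 1, 2, 0,
                2, 2, 0, 1,
                1, 0, 1, 2,
                0, 0, NA, 2,
                1, 1, 1, 1), 4, 5)
  colnames(G) <- paste0("snp", 1:5)
  panel <- make_panel(G)
  # all-zero weights
  ins0 <- data.frame(snp_id = colnames(G), beta = 0)
  expect_equal(unname(build_wgrs(panel, ins0)), rep(0, 4))
  # single positive SNP
  ins1 <- data.frame(snp_id = "snp1", beta = 0.3)
  expect_equal(unname(build_wgrs(panel, ins1)), c(0, 0.3, 0.6, 0))
  # hand-computed 5-SNP score with one missing call on snp4
  betas <- c(0.3, -0.2, 0.1, 0.25, 0)
  ins <- data.frame(snp_id = colnames(G), beta = betas)
  # orientation: snp2 flips to dosage 2-d with weight 0.2
  # snp4 missing entry imputed with 2 * mean(c(0,0,2))/2 = 2/3
  expected <- 0.3 * G[, 1] + 0.2 * (2 - G[, 2]) + 0.1 * G[, 3] +
    0.25 * c(0, 0, 2 / 3, 2)
  expect_equal(unname(build_wgrs(panel, ins)), unname(expected))
  # absent instrument is a hard error naming the SNP
  expect_error(build_wgrs(panel, data.frame(snp_id = "nope", beta = 1)),
               "nope")
})

test_that("wGRS is exactly invariant to allele-coding flips", {
  set.seed(16)
  G <- matrix(stats::rbinom(50 * 6, 2, 0.3), 50, 6)
  colnames(G) <- paste0("s", 1:6)
  G[sample(300, 10)] <- NA
  panel <- make_panel(G)
  betas <- stats::rnorm(6, 0, 0.2)
  ins <- data.frame(snp_id = colnames(G), beta = betas)
  s1 <- build_wgrs(panel, ins)
  # flip coded allele of SNPs 2 and 5: dosage -> 2 - dosage, beta -> -beta
  G2 <- G; G2[, c(2, 5)] <- 2L - G2[, c(2, 5)]
  panel2 <- make_panel(G2)
  ins2 <- ins; ins2$beta[c(2, 5)] <- -ins2$beta[c(2, 5)]
  s2 <- build_wgrs(panel2, ins2)
  expect_equal(unname(s1), unname(s2), tolerance = 1e-12)
})

test_that("wGRS with true weights is a calibrated predictor (slope 1)", {
  cfg <- sim_config(n_subjects = 1500, n_snps_fbs = 40, n_snps_sbp = 10,
                    n_shared = 0, beta_scale_x = 0.1,
                    causal_fbs_to_sbp = 0, causal_sbp_to_fbs = 0,
                    confounder_sd = 0, missing_rate = 0, seed = 21)
  panel <- generate_cohort(cfg)
  ins <- instruments_from_truth(panel, "fbs")
  w <- build_wgrs(panel, ins)
  fit <- stats::lm(panel$baseline$fbs ~ w)
  sl <- summary(fit)$coefficients[2, ]
  expect_lt(abs(sl[1] - 1), 3 * sl[2])
})

test_that("Bonferroni threshold is alpha/m with guarded inputs", {
  expect_equal(round(bonferroni_threshold(0.05, 91), 4), 0.0005)
  expect_equal(round(bonferroni_threshold(0.05, 68), 4), 0.0007)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})
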