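# Mendelian randomization estimators.
#
# Individual-level: two-stage least squares with the weighted genetic risk
# score as the single instrument, with first-stage partial F and the
# Wu-Hausman endogeneity test. Summary-level: IVW, simple and weighted
# median, and MR-Egger on per-variant association coefficients.

new_mr_estimate <- function(method, effect, se, p, n_instruments,
                            intercept = NULL, intercept_se = NULL,
                            intercept_p = NULL) {
  structure(list(method = method, effect = effect, se = se, p = p,
                 n_instruments = n_instruments, intercept = intercept,
                 intercept_se = intercept_se, intercept_p = intercept_p),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: effect %.4f (SE %.4f), p = %.3g, %d instrument(s)\n",
              x$method, x$effect, x$se, x$p, x$n_instruments))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept %.4f (SE %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' Per-variant summary input for two-sample MR
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome equal-length
#'   per-variant association coefficients and standard errors.
#' @param snp_id variant identifiers.
#' @param direction free-text direction tag (e.g. `"FBS->SBP"`).
#' @return a `two_sample_input`.
#' @export
two_sample_input <- function(beta_exposure, se_exposure, beta_outcome,
                             se_outcome, snp_id = NULL, direction = "") {
  m <- length(beta_exposure)
  if (m < 1 || length(se_exposure) != m || length(beta_outcome) != m ||
      length(se_outcome) != m)
    stop("per-variant arrays must have equal length >= 1", call. = FALSE)
  if (any(se_exposure <= 0) || any(se_outcome <= 0))
    stop("all standard errors must be positive", call. = FALSE)
  structure(list(beta_exposure = beta_exposure, se_exposure = se_exposure,
                 beta_outcome = beta_outcome, se_outcome = se_outcome,
                 snp_id = snp_id %||% paste0("v", seq_len(m)),
                 direction = direction),
            class = "two_sample_input")
}

subset_tsi <- function(dat, keep) {
  two_sample_input(dat$beta_exposure[keep], dat$se_exposure[keep],
                   dat$beta_outcome[keep], dat$se_outcome[keep],
                   dat$snp_id[keep], dat$direction)
}

#' Two-stage least squares with instrument diagnostics
#'
#' Stage 1 regresses the exposure on the instrument and covariates; stage 2
#' regresses the outcome on the fitted exposure and covariates. Standard
#' errors use the structural residual (outcome minus the structural fit
#' evaluated at the *observed* exposure), not the naive stage-2 OLS
#' residual. Diagnostics: the first-stage partial F for the instrument, and
#' the Wu-Hausman endogeneity test from the augmented regression (stage-1
#' residuals added to the structural OLS; t-test on their coefficient).
#'
#' @param exposure,outcome numeric vectors.
#' @param instrument the instrument (e.g. a wGRS vector).
#' @param covariates optional data frame or matrix of covariates.
#' @return list with `estimate` (an `mr_estimate`) and `diagnostics`
#'   (`first_stage_F`, `weak_flag`, `wu_hausman_stat`, `wu_hausman_p`).
#' @export
fit_2sls <- function(exposure, outcome, instrument, covariates = NULL) {
  n <- length(exposure)
  C <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    mm <- stats::model.matrix(~ ., data = cv)
    C <- mm  # includes intercept
  }
  if (n < ncol(C) + 3) stop("too few observations for 2SLS", call. = FALSE)
  if (stats::var(instrument) == 0)
    stop("weak/collinear instrument, F undefined: instrument has zero variance",
         call. = FALSE)
  Z1 <- cbind(instrument, C)
  if (qr(Z1)$rank < ncol(Z1))
    stop("weak/collinear instrument, F undefined: instrument is collinear with covariates",
         call. = FALSE)
  s1 <- stats::lm.fit(Z1, exposure)
  xhat <- exposure - s1$residuals
  # first-stage partial F for the single instrument = t^2
  df1 <- n - ncol(Z1)
  sigma1 <- sum(s1$residuals^2) / df1
  z1inv <- chol2inv(chol(crossprod(Z1)))
  F_stat <- s1$coefficients[1]^2 / (sigma1 * z1inv[1, 1])

  W <- cbind(xhat, C)
  s2 <- stats::lm.fit(W, outcome)
  coefs <- s2$coefficients
  # structural residual uses observed exposure
  e <- outcome - cbind(exposure, C) %*% coefs
  df2 <- n - ncol(W)
  sigma2 <- sum(e^2) / df2
  winv <- chol2inv(chol(crossprod(W)))
  se <- sqrt(sigma2 * winv[1, 1])
  tstat <- coefs[1] / se
  p <- 2 * stats::pt(-abs(tstat), df2)

  # Wu-Hausman: augmented structural regression with stage-1 residuals
  A <- cbind(exposure, C, s1$residuals)
  fa <- stats::lm.fit(A, outcome)
  dfa <- n - ncol(A)
  sa2 <- sum(fa$residuals^2) / dfa
  ainv <- chol2inv(chol(crossprod(A)))
  wh_t <- fa$coefficients[ncol(A)] / sqrt(sa2 * ainv[ncol(A), ncol(A)])
  wh_stat <- wh_t^2
  wh_p <- 2 * stats::pt(-abs(wh_t), dfa)

  list(estimate = new_mr_estimate("2SLS", unname(coefs[1]), se, unname(p), 1L),
       diagnostics = list(first_stage_F = unname(F_stat),
                          weak_flag = unname(F_stat) < 10,
                          wu_hausman_stat = unname(wh_stat),
                          wu_hausman_p = unname(wh_p)))
}

#' Inverse-variance-weighted estimator
#'
#' Fixed-effect meta-analysis of per-variant Wald ratios with weights
#' `beta_exposure^2 / se_outcome^2`; equivalently the no-intercept weighted
#' regression of outcome on exposure coefficients. Variants with a zero
#' exposure coefficient are excluded with a warning. Two-sided normal p.
#'
#' @param dat a [two_sample_input()].
#' @return an `mr_estimate`.
#' @export
mr_ivw <- function(dat) {
  stopifnot(inherits(dat, "two_sample_input"))
  zero <- dat$beta_exposure == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " variant(s) with zero exposure coefficient")
    dat <- subset_tsi(dat, !zero)
  }
  w <- dat$beta_exposure^2 / dat$se_outcome^2
  ratio <- dat$beta_outcome / dat$beta_exposure
  effect <- sum(w * ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- effect / se
  new_mr_estimate("IVW", effect, se, 2 * stats::pnorm(-abs(z)),
                  length(dat$beta_exposure))
}

weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]; w <- w[o]
  cw <- (cumsum(w) - w / 2) / sum(w)
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] <= 0.5) return(r[length(r)])
  i <- max(which(cw < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - cw[i]) / (cw[i + 1] - cw[i])
}

#' Median-based MR estimators
#'
#' Simple: median of per-variant Wald ratios. Weighted: weighted median with
#' weights `beta_exposure^2 / se_outcome^2` via cumulative-weight
#' interpolation (consistent when valid instruments carry at least half the
#' weight). Standard errors by seeded parametric bootstrap, resampling each
#' variant's coefficients from normals with their reported SEs.
#'
#' @param dat a [two_sample_input()] with at least 3 variants.
#' @param weighted logical; weighted or simple median.
#' @param n_boot bootstrap replicates for the SE (warning below 100).
#' @param seed bootstrap seed.
#' @return an `mr_estimate`.
#' @export
mr_median <- function(dat, weighted = FALSE, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(dat, "two_sample_input"))
  m <- length(dat$beta_exposure)
  if (m < 3) stop("median estimators need at least 3 variants", call. = FALSE)
  if (n_boot < 100) warning("unstable SE: n_boot < 100")
  point <- function(bx, by) {
    ratio <- by / bx
    w <- if (weighted) bx^2 / dat$se_outcome^2 else rep(1, m)
    weighted_median_point(ratio, w)
  }
  effect <- point(dat$beta_exposure, dat$beta_outcome)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(m, dat$beta_exposure, dat$se_exposure)
    by <- stats::rnorm(m, dat$beta_outcome, dat$se_outcome)
    point(bx, by)
  }, 0)
  se <- stats::sd(boots)
  z <- effect / se
  new_mr_estimate(if (weighted) "weighted_median" else "simple_median",
                  effect, se, 2 * stats::pnorm(-abs(z)), m)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' MR-Egger regression
#'
#' Variants are first oriented so every exposure coefficient is nonnegative
#' (sign-flipping both coefficients), then outcome coefficients are
#' regressed on exposure coefficients with an intercept, weighted by
#' `1 / se_outcome^2`. The slope estimates the causal effect; the intercept
#' estimates average directional pleiotropy. Standard errors use the
#' weighted residual dispersion with a floor of 1 (multiplicative
#' random-effects convention); p-values from the t distribution with
#' `m - 2` degrees of freedom.
#'
#' @param dat a [two_sample_input()] with at least 3 variants.
#' @return an `mr_estimate` with intercept fields.
#' @export
mr_egger <- function(dat) {
  stopifnot(inherits(dat, "two_sample_input"))
  m <- length(dat$beta_exposure)
  if (m < 3) stop("MR-Egger needs at least 3 variants", call. = FALSE)
  s <- ifelse(dat$beta_exposure < 0, -1, 1)
  bx <- dat$beta_exposure * s
  by <- dat$beta_outcome * s
  if (stats::var(bx) == 0)
    stop("slope/intercept unidentifiable: all exposure coefficients equal after orientation",
         call. = FALSE)
  w <- 1 / dat$se_outcome^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * by)
  coefs <- solve(XtWX, XtWy)
  resid <- by - X %*% coefs
  sigma2 <- sum(w * resid^2) / (m - 2)
  sigma2 <- max(sigma2, 1)   # random-effects floor
  V <- sigma2 * solve(XtWX)
  se_slope <- sqrt(V[2, 2]); se_int <- sqrt(V[1, 1])
  t_slope <- coefs[2] / se_slope
  t_int <- coefs[1] / se_int
  new_mr_estimate("MR_Egger", coefs[2], se_slope,
                  2 * stats::pt(-abs(t_slope), m - 2), m,
                  intercept = coefs[1], intercept_se = se_int,
                  intercept_p = 2 * stats::pt(-abs(t_int), m - 2))
}

#' Leave-one-out sensitivity analysis
#'
#' Refits an estimator excluding each variant in turn. For MR-Egger, flags
#' variants whose exclusion moves the intercept p-value across the 0.05
#' boundary (the signature of a single variant driving apparent directional
#' pleiotropy).
#'
#' @param dat a [two_sample_input()] with at least 4 variants.
#' @param method `"ivw"`, `"egger"`, `"simple_median"` or
#'   `"weighted_median"`.
#' @param ... passed to the underlying estimator.
#' @return data frame with one row per excluded variant (effect, se, p,
#'   intercept columns for Egger, and a `flagged` column).
#' @export
leave_one_out <- function(dat, method = c("ivw", "egger", "simple_median",
                                          "weighted_median"), ...) {
  method <- match.arg(method)
  m <- length(dat$beta_exposure)
  if (m < 4) stop("leave-one-out needs at least 4 variants", call. = FALSE)
  fit1 <- function(d) switch(method,
    ivw = mr_ivw(d),
    egger = mr_egger(d),
    simple_median = mr_median(d, weighted = FALSE, ...),
    weighted_median = mr_median(d, weighted = TRUE, ...))
  full <- fit1(dat)
  rows <- lapply(seq_len(m), function(i) {
    est <- fit1(subset_tsi(dat, seq_len(m) != i))
    data.frame(excluded = dat$snp_id[i], effect = est$effect, se = est$se,
               p = est$p,
               intercept = est$intercept %||% NA_real_,
               intercept_p = est$intercept_p %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (method == "egger") {
    out$flagged <- (full$intercept_p < 0.05) != (out$intercept_p < 0.05)
  } else {
    out$flagged <- FALSE
  }
  out
}
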