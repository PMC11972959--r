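# Person-time accounting, incidence rates with exact Poisson intervals,
# and Cox proportional-hazards regression (Efron ties, Newton-Raphson,
# left truncation supported).

#' Build survival records for one outcome
#'
#' Excludes subjects with a baseline history of T2D, hypertension, or
#' stroke (the healthy-cohort rule), then computes entry and exit times.
#' With `entry_at_second_visit = TRUE` follow-up starts at the second visit
#' (left truncation); subjects whose event or censoring time falls at or
#' before entry are rejected with a reason. Exit is the event time or the
#' administrative censoring horizon.
#'
#' @param panel a `cohort_panel`.
#' @param outcome `"t2d"` or `"htn"`.
#' @param exclusions baseline history flags to exclude on (columns of
#'   `panel$events`).
#' @param entry_at_second_visit logical left-truncation switch.
#' @return data frame of records (subject_id, entry, exit, event, baseline
#'   covariates), with an `"exclusion_report"` attribute giving per-rule
#'   counts, the union excluded, and rejected-record reasons.
#' @export
build_records <- function(panel, outcome = c("t2d", "htn"),
                          exclusions = c("prev_t2d", "prev_htn", "prev_stroke"),
                          entry_at_second_visit = FALSE) {
  outcome <- match.arg(outcome)
  ev <- panel$events
  if (is.null(ev[[paste0(outcome, "_time")]]))
    stop("event times not present for outcome ", outcome, call. = FALSE)
  excl_counts <- vapply(exclusions, function(f) sum(ev[[f]] == 1), 0L)
  excluded <- rep(FALSE, nrow(ev))
  for (f in exclusions) excluded <- excluded | ev[[f]] == 1

  entry <- if (entry_at_second_visit) panel$config$visit_spacing_years else 0
  time <- ev[[paste0(outcome, "_time")]]
  status <- ev[[paste0(outcome, "_event")]]
  rec <- data.frame(subject_id = ev$subject_id, entry = entry, exit = time,
                    event = status, stringsAsFactors = FALSE)
  rec <- cbind(rec, panel$baseline[, setdiff(names(panel$baseline),
                                             c("subject_id")), drop = FALSE])
  rec <- rec[!excluded, , drop = FALSE]
  bad <- rec$exit <= rec$entry
  rejected <- data.frame(subject_id = rec$subject_id[bad],
                         reason = rep("non_positive_follow_up", sum(bad)),
                         stringsAsFactors = FALSE)
  rec <- rec[!bad, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "exclusion_report") <- list(
    per_rule = excl_counts, n_excluded = sum(excluded),
    n_input = nrow(ev), n_analyzed = nrow(rec), rejected = rejected)
  rec
}

#' Incidence rate with an exact Poisson confidence interval
#'
#' `rate = 1000 * events / person-years`; the interval treats the event
#' count as Poisson and uses the exact chi-square relationship
#' (`qchisq(a/2, 2x)/2` to `qchisq(1-a/2, 2x+2)/2`), divided by
#' person-years. With zero events the lower bound is 0.
#'
#' @param records a record data frame from [build_records()], or use
#'   [incidence_from_counts()] with raw counts.
#' @param conf_level confidence level (default 0.95).
#' @return an `incidence_summary`: n_persons, n_events, person_years,
#'   rate_per_1000, rate_ci_low, rate_ci_high, mean_follow_up.
#' @export
incidence <- function(records, conf_level = 0.95) {
  if (nrow(records) < 1) stop("no records", call. = FALSE)
  py <- sum(records$exit - records$entry)
  incidence_from_counts(sum(records$event), py, nrow(records), conf_level)
}

#' @rdname incidence
#' @param n_events,person_years,n_persons raw counts.
#' @export
incidence_from_counts <- function(n_events, person_years, n_persons = NA,
                                  conf_level = 0.95) {
  if (person_years <= 0) stop("person-years must be positive", call. = FALSE)
  a <- 1 - conf_level
  lo <- if (n_events == 0) 0 else stats::qchisq(a / 2, 2 * n_events) / 2
  hi <- stats::qchisq(1 - a / 2, 2 * (n_events + 1)) / 2
  structure(list(n_persons = n_persons, n_events = n_events,
                 person_years = person_years,
                 rate_per_1000 = 1000 * n_events / person_years,
                 rate_ci_low = 1000 * lo / person_years,
                 rate_ci_high = 1000 * hi / person_years,
                 mean_follow_up = if (is.na(n_persons)) NA_real_
                                  else person_years / n_persons,
                 conf_level = conf_level),
            class = "incidence_summary")
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat(sprintf("%d events / %.2f person-years: %.2f per 1,000 (%.2f-%.2f)\n",
              x$n_events, x$person_years, x$rate_per_1000, x$rate_ci_low,
              x$rate_ci_high))
  invisible(x)
}

# model matrix for the Cox fit: numeric columns as-is, character/factor as
# treatment dummies; constant columns dropped with a message
cox_model_matrix <- function(records, covariates) {
  X <- NULL; nms <- character(0)
  for (cv in covariates) {
    v <- records[[cv]]
    if (is.null(v)) stop("covariate not present: ", cv, call. = FALSE)
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      lev <- levels(v)
      if (length(lev) < 2) { message("covariate '", cv, "' is constant; excluded"); next }
      mm <- outer(v, lev[-1], "==") * 1
      X <- cbind(X, mm); nms <- c(nms, paste0(cv, lev[-1]))
    } else {
      if (stats::var(v) == 0) { message("covariate '", cv, "' is constant; excluded"); next }
      X <- cbind(X, v); nms <- c(nms, cv)
    }
  }
  if (is.null(X)) stop("no usable covariates", call. = FALSE)
  colnames(X) <- nms
  if (qr(X)$rank < ncol(X))
    stop("covariates are collinear", call. = FALSE)
  X
}

# Efron partial likelihood, score and information at beta, with left
# truncation; risk sums via reverse cumulative sums over exit and entry
# orderings (entry >= t implies exit >= t, so the risk-set sum is the
# difference of the two marginals)
cox_loglik <- function(beta, X, entry, exit, status) {
  n <- nrow(X); p <- ncol(X)
  lp <- as.numeric(X %*% beta)
  lp <- lp - mean(lp)              # stabilizes exp() without changing beta
  w <- exp(lp)
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  XX <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]

  rev_cum <- function(ordv, M) {
    # reverse cumulative sums in the order of ascending ordv
    out <- apply(M[order(ordv), , drop = FALSE], 2,
                 function(col) rev(cumsum(rev(col))))
    matrix(out, nrow = n)
  }
  Mall <- cbind(w, X * w, XX * w)
  exit_sorted <- sort(exit)
  entry_sorted <- sort(entry)
  cum_exit <- rev_cum(exit, Mall)
  cum_entry <- rev_cum(entry, Mall)

  ev_rle <- rle(sort(exit[status == 1]))
  ev_times <- ev_rle$values
  d_all <- ev_rle$lengths
  m_ev <- length(ev_times)
  npack <- ncol(XX)
  ii <- cbind(pairs[, 1], pairs[, 2])
  unpack <- function(v) {
    s2m <- matrix(0, p, p)
    s2m[ii] <- v
    s2m[ii[, c(2, 1), drop = FALSE]] <- v
    s2m
  }
  # risk-set sums at every event time, in one indexed lookup
  i_exit <- findInterval(ev_times, exit_sorted, left.open = TRUE) + 1L
  j_entry <- findInterval(ev_times, entry_sorted, left.open = TRUE) + 1L
  S_all <- matrix(0, m_ev, ncol(Mall))
  okx <- i_exit <= n
  S_all[okx, ] <- cum_exit[i_exit[okx], , drop = FALSE]
  oke <- j_entry <= n
  S_all[oke, ] <- S_all[oke, , drop = FALSE] -
    cum_entry[j_entry[oke], , drop = FALSE]

  ll <- sum(lp[status == 1])
  U <- colSums(X[status == 1, , drop = FALSE])
  I <- matrix(0, p, p)

  single <- d_all == 1L
  if (any(single)) {   # untied event times, fully vectorized
    s0 <- S_all[single, 1]
    S1 <- S_all[single, 2:(p + 1), drop = FALSE]
    S2 <- S_all[single, -(1:(p + 1)), drop = FALSE]
    mu <- S1 / s0
    ll <- ll - sum(log(s0))
    U <- U - colSums(mu)
    I <- I + unpack(colSums(S2 / s0)) - crossprod(mu)
  }
  for (k in which(!single)) {   # Efron correction at tied event times
    t <- ev_times[k]; d <- d_all[k]
    D <- which(exit == t & status == 1)
    s0 <- S_all[k, 1]; s1 <- S_all[k, 2:(p + 1)]; s2v <- S_all[k, -(1:(p + 1))]
    sd0 <- sum(w[D])
    sd1 <- colSums(X[D, , drop = FALSE] * w[D])
    sd2v <- colSums(XX[D, , drop = FALSE] * w[D])
    for (l in seq_len(d) - 1) {
      f <- l / d
      den <- s0 - f * sd0
      mu <- (s1 - f * sd1) / den
      ll <- ll - log(den)
      U <- U - mu
      I <- I + unpack((s2v - f * sd2v) / den) - tcrossprod(mu)
    }
  }
  list(loglik = ll, score = U, info = I)
}

#' Cox proportional-hazards regression (Efron ties)
#'
#' Maximizes the Efron partial likelihood by Newton-Raphson, stopping when
#' the score norm drops below `tol`. Left truncation is honored: a subject
#' enters the risk set strictly after `entry` and leaves at `exit`.
#' Monotone likelihood (a coefficient diverging, the perfect-separation
#' analog) and non-convergence raise errors naming the covariate or the
#' last gradient norm.
#'
#' @param records data frame with `entry`, `exit`, `event` and covariate
#'   columns (see [build_records()]).
#' @param covariates covariate column names.
#' @param ties only `"efron"` is implemented.
#' @param tol convergence tolerance on the score norm (default 1e-9).
#' @param max_iter Newton-Raphson cap (default 50).
#' @return a `cox_fit`: per-covariate table (log_hr, se, hr, ci_low,
#'   ci_high, p), partial log-likelihood, `-2 logL`, events, iterations.
#' @export
fit_cox <- function(records, covariates, ties = "efron", tol = 1e-9,
                    max_iter = 50) {
  ties <- match.arg(ties, "efron")
  if (sum(records$event) < 1) stop("no events", call. = FALSE)
  X <- cox_model_matrix(records, covariates)
  p <- ncol(X)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    der <- cox_loglik(beta, X, records$entry, records$exit, records$event)
    gnorm <- sqrt(sum(der$score^2))
    if (gnorm < tol) break
    step <- tryCatch(solve(der$info, der$score), error = function(e)
      stop("information matrix singular at iteration ", it, call. = FALSE))
    beta <- beta + step
    if (any(abs(beta) > 20))
      stop("monotone likelihood: coefficient for '",
           colnames(X)[which.max(abs(beta))], "' diverges", call. = FALSE)
  }
  der <- cox_loglik(beta, X, records$entry, records$exit, records$event)
  if (sqrt(sum(der$score^2)) >= max(tol, 1e-6))
    stop(sprintf("no convergence in %d iterations (score norm %.3g)",
                 max_iter, sqrt(sum(der$score^2))), call. = FALSE)
  V <- solve(der$info)
  se <- sqrt(diag(V))
  z <- beta / se
  tab <- data.frame(term = colnames(X), log_hr = beta, se = se,
                    hr = exp(beta), ci_low = exp(beta - 1.96 * se),
                    ci_high = exp(beta + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  structure(list(coefficients = tab, partial_log_likelihood = der$loglik,
                 minus2_log_likelihood = -2 * der$loglik,
                 n = nrow(records), n_events = sum(records$event),
                 iterations = it, score_norm = sqrt(sum(der$score^2))),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: %d subjects, %d events, -2logL = %.3f\n",
              x$n, x$n_events, x$minus2_log_likelihood))
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Trajectory-to-incidence report (Table-2 layout)
#'
#' For each trajectory grouping (FBS groups against incident hypertension,
#' SBP groups against incident T2D) this emits per-group persons, events,
#' person-years and exact-interval incidence rates, plus hazard ratios for
#' the uncontrolled-vs-controlled contrast under three covariate sets:
#' model 1 (age, sex), model 2 (adding BMI, smoking, alcohol, exercise and
#' medication flags), and model 2c (adding baseline risk-score quartiles,
#' computed on the analysis cohort after exclusions).
#'
#' @param panel a `cohort_panel`.
#' @param assignments_fbs,assignments_sbp trajectory labels per subject
#'   (named character vectors or data frames with subject_id and label).
#' @param wgrs_fbs,wgrs_sbp risk-score vectors for the quartile covariate.
#' @param entry_at_second_visit passed to [build_records()].
#' @return a `table2_report`: list with one element per grouping holding
#'   the per-group incidence block, the three `cox_fit`s, and the group
#'   hazard-ratio rows.
#' @export
table2_report <- function(panel, assignments_fbs, assignments_sbp,
                          wgrs_fbs, wgrs_sbp,
                          entry_at_second_visit = FALSE) {
  as_label_vec <- function(a) {
    if (is.data.frame(a)) stats::setNames(a$label, a$subject_id)
    else a
  }
  groupings <- list(
    fbs_groups = list(labels = as_label_vec(assignments_fbs), outcome = "htn",
                      wgrs = wgrs_fbs),
    sbp_groups = list(labels = as_label_vec(assignments_sbp), outcome = "t2d",
                      wgrs = wgrs_sbp)
  )
  out <- list()
  for (gnm in names(groupings)) {
    g <- groupings[[gnm]]
    rec <- build_records(panel, g$outcome,
                         entry_at_second_visit = entry_at_second_visit)
    rec$traj_group <- unname(g$labels[rec$subject_id])
    if (anyNA(rec$traj_group))
      stop("trajectory assignments do not cover all at-risk subjects",
           call. = FALSE)
    rec$traj_group <- factor(rec$traj_group, c("controlled", "uncontrolled"))
    wg <- g$wgrs[rec$subject_id]
    qs <- stats::quantile(wg, c(0.25, 0.5, 0.75))
    rec$wgrs_quartile <- paste0("Q", findInterval(wg, qs) + 1L)

    inc <- lapply(split(rec, rec$traj_group), incidence)
    m1 <- fit_cox(rec, c("traj_group", "age", "sex"))
    m2 <- fit_cox(rec, c("traj_group", "age", "sex", "bmi", "smoking",
                         "alcohol", "exercise", "med_antidiabetic",
                         "med_antihypertensive"))
    m2c <- fit_cox(rec, c("traj_group", "age", "sex", "bmi", "smoking",
                          "alcohol", "exercise", "med_antidiabetic",
                          "med_antihypertensive", "wgrs_quartile"))
    grp_row <- function(fit, tag) {
      r <- fit$coefficients[fit$coefficients$term == "traj_groupuncontrolled", ]
      data.frame(model = tag, hr = r$hr, ci_low = r$ci_low,
                 ci_high = r$ci_high, p = r$p,
                 minus2logl = fit$minus2_log_likelihood,
                 stringsAsFactors = FALSE)
    }
    out[[gnm]] <- list(outcome = g$outcome, incidence = inc,
                       models = list(model1 = m1, model2 = m2, model2c = m2c),
                       hr_rows = rbind(grp_row(m1, "model1"),
                                       grp_row(m2, "model2"),
                                       grp_row(m2c, "model2c")),
                       exclusion_report = attr(rec, "exclusion_report"),
                       n_by_group = table(rec$traj_group))
  }
  structure(out, class = "table2_report")
}

#' Write the Table-2-shaped report as TSV
#'
#' @param report a `table2_report`.
#' @param file output path.
#' @return the file, invisibly.
#' @export
write_table2 <- function(report, file) {
  rows <- list()
  for (gnm in names(report)) {
    blk <- report[[gnm]]
    for (lab in names(blk$incidence)) {
      s <- blk$incidence[[lab]]
      base <- data.frame(grouping = gnm, outcome = blk$outcome, group = lab,
                         n_persons = s$n_persons, n_events = s$n_events,
                         person_years = s$person_years,
                         rate_per_1000 = s$rate_per_1000,
                         rate_ci_low = s$rate_ci_low,
                         rate_ci_high = s$rate_ci_high,
                         stringsAsFactors = FALSE)
      if (lab == "uncontrolled") {
        for (i in seq_len(nrow(blk$hr_rows))) {
          r <- blk$hr_rows[i, ]
          base[[paste0(r$model, "_hr")]] <- r$hr
          base[[paste0(r$model, "_ci_low")]] <- r$ci_low
          base[[paste0(r$model, "_ci_high")]] <- r$ci_high
          base[[paste0(r$model, "_minus2logl")]] <- r$minus2logl
        }
      }
      rows[[paste(gnm, lab)]] <- base
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(all_cols, names(r))] <- NA; r[all_cols] })
  write_tsv(do.call(rbind, rows), file)
  invisible(file)
}
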