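# Genetically predicted phenotype series and group-based trajectory
# modeling (GBTM): a finite mixture of polynomial-in-time mean curves with
# shared residual SD, fitted by EM with multi-start, model choice by BIC
# with a minimum-group-share rule.

#' Genetically predicted per-visit phenotype series
#'
#' For each visit the observed phenotype is regressed on the weighted
#' genetic risk score across subjects; a subject's predicted value at that
#' visit is the fitted value of that regression. Because prediction needs
#' only the wGRS, subjects missing a visit still get a predicted value.
#'
#' @param panel a `cohort_panel` with at least 2 visits.
#' @param wgrs per-subject score vector aligned with `panel$subject_ids`.
#' @param phenotype `"fbs"` or `"sbp"`.
#' @return long data frame (subject_id, visit, time_years, predicted,
#'   source), with per-visit intercepts/slopes as attribute `"fits"`.
#' @export
predict_series <- function(panel, wgrs, phenotype = c("fbs", "sbp")) {
  phenotype <- match.arg(phenotype)
  if (stats::var(wgrs) == 0)
    stop("wGRS has zero variance; per-visit regressions undefined", call. = FALSE)
  vis <- panel$visits
  visit_ids <- sort(unique(vis$visit))
  if (length(visit_ids) < 2) stop("need at least 2 visits", call. = FALSE)
  n <- length(panel$subject_ids)
  fits <- data.frame(visit = visit_ids, time_years = NA_real_,
                     intercept = NA_real_, slope = NA_real_)
  rows <- vector("list", length(visit_ids))
  for (i in seq_along(visit_ids)) {
    v <- vis[vis$visit == visit_ids[i], ]
    y <- v[[phenotype]][match(panel$subject_ids, v$subject_id)]
    ok <- !is.na(y)
    cf <- stats::lm.fit(cbind(1, wgrs[ok]), y[ok])$coefficients
    fits$time_years[i] <- v$time_years[1]
    fits$intercept[i] <- cf[1]; fits$slope[i] <- cf[2]
    rows[[i]] <- data.frame(subject_id = panel$subject_ids,
                            visit = visit_ids[i],
                            time_years = v$time_years[1],
                            predicted = cf[1] + cf[2] * wgrs,
                            source = "wgrs_predicted",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$visit), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

# long (subject_id, time_years, value-col) -> list(Y wide matrix, times)
series_to_wide <- function(series, value_col = NULL) {
  if (is.matrix(series)) {
    return(list(Y = series,
                times = attr(series, "times") %||% seq_len(ncol(series)) - 1))
  }
  value_col <- value_col %||%
    intersect(c("predicted", "value", "fbs", "sbp"), names(series))[1]
  if (is.na(value_col)) stop("no value column found in series", call. = FALSE)
  subj <- unique(series$subject_id)
  times <- sort(unique(series$time_years))
  Y <- matrix(NA_real_, length(subj), length(times),
              dimnames = list(subj, NULL))
  Y[cbind(match(series$subject_id, subj),
          match(series$time_years, times))] <- series[[value_col]]
  list(Y = Y, times = times)
}

poly_basis <- function(times, order) {
  vapply(0:order, function(k) times^k, numeric(length(times)))
}

#' Fit a group-based trajectory model by EM
#'
#' Maximizes the normal-mixture likelihood
#' `prod_i sum_k pi_k prod_t Normal(y_it; poly_k(t), sigma)` with a shared
#' residual SD: the E-step computes posterior responsibilities, the M-step
#' solves a weighted polynomial least-squares problem per group and updates
#' the mixing proportions. Multi-start keeps the best converged likelihood;
#' a start whose responsibilities empty a group is restarted. Groups are
#' canonically ordered by intercept (ascending) so fits are comparable
#' across runs; the group whose fitted curve spans the largest range over
#' the observation window is labeled `"uncontrolled"`, the others
#' `"controlled"`.
#'
#' @param series long data frame (subject_id, time_years, value) or a wide
#'   subjects-by-times matrix with a `"times"` attribute.
#' @param K number of latent groups.
#' @param orders polynomial order per group (scalar recycled; at most 3).
#' @param max_iter,tol EM iteration cap and log-likelihood gain tolerance.
#' @param n_starts number of random starts.
#' @param seed seed for the starts.
#' @param sigma_floor lower bound on the residual SD (guards zero-noise
#'   degeneracy).
#' @param value_col value column name when `series` is long.
#' @return a `gbtm_fit`: mixing proportions, per-group coefficients,
#'   residual SD, log-likelihood, BIC, posterior matrix, assignments,
#'   per-group average posterior, minimum assigned share, labels, and the
#'   log-likelihood trace of the winning start.
#' @export
fit_gbtm <- function(series, K, orders = 2, max_iter = 500, tol = 1e-6,
                     n_starts = 10, seed = NULL, sigma_floor = 1e-6,
                     value_col = NULL) {
  wd <- series_to_wide(series, value_col)
  Y <- wd$Y; times <- wd$times
  n <- nrow(Y)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  orders <- rep_len(orders, K)
  if (any(orders > 3)) stop("polynomial order is capped at 3", call. = FALSE)
  O <- !is.na(Y)
  if (any(rowSums(O) < 2))
    stop("every subject needs at least 2 observations", call. = FALSE)
  Y0 <- ifelse(O, Y, 0)
  n_obs <- sum(O)
  if (!is.null(seed)) set.seed(seed)

  bases <- lapply(orders, function(o) poly_basis(times, o))
  m_step <- function(resp) {
    coefs <- vector("list", K)
    mu <- matrix(0, length(times), K)
    for (k in seq_len(K)) {
      B <- bases[[k]]
      cwt <- colSums(resp[, k] * O)          # per-time total weight
      cwy <- colSums(resp[, k] * Y0)
      A <- crossprod(B, cwt * B)
      cf <- solve(A, crossprod(B, cwy))
      coefs[[k]] <- as.numeric(cf)
      mu[, k] <- B %*% cf
    }
    ss <- 0
    for (k in seq_len(K)) {
      R2 <- (Y0 - matrix(mu[, k], n, length(times), byrow = TRUE))^2 * O
      ss <- ss + sum(resp[, k] * rowSums(R2))
    }
    sigma <- max(sqrt(ss / n_obs), sigma_floor)
    list(pi = pmax(colMeans(resp), 1e-12), coefs = coefs, mu = mu,
         sigma = sigma)
  }
  e_step <- function(par) {
    ll_ik <- matrix(0, n, K)
    for (k in seq_len(K)) {
      R2 <- (Y0 - matrix(par$mu[, k], n, length(times), byrow = TRUE))^2 * O
      ll_ik[, k] <- -0.5 * rowSums(R2) / par$sigma^2 -
        rowSums(O) * (log(par$sigma) + 0.5 * log(2 * pi))
    }
    lw <- sweep(ll_ik, 2, log(par$pi), "+")
    mx <- apply(lw, 1, max)
    w <- exp(lw - mx)
    tot <- rowSums(w)
    list(resp = w / tot, loglik = sum(mx + log(tot)))
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    # start 1: split subjects by overall level; others: random responsibilities
    resp <- if (K == 1) {
      matrix(1, n, 1)
    } else if (s == 1) {
      lev <- rowSums(Y0) / rowSums(O)
      grp <- cut(rank(lev, ties.method = "first"), K, labels = FALSE)
      0.9 * outer(grp, seq_len(K), "==") + 0.1 / K
    } else {
      r <- matrix(stats::rexp(n * K), n, K)
      r / rowSums(r)
    }
    ll_prev <- -Inf
    trace <- numeric(0)
    degenerate <- FALSE
    for (it in seq_len(max_iter)) {
      par <- tryCatch(m_step(resp), error = function(e) NULL)
      if (is.null(par) || any(par$pi < 1e-8)) { degenerate <- TRUE; break }
      es <- e_step(par)
      resp <- es$resp
      trace <- c(trace, es$loglik)
      if (es$loglik - ll_prev < tol && it > 1) break
      ll_prev <- es$loglik
    }
    if (degenerate) next
    if (is.null(best) || trace[length(trace)] > best$loglik) {
      best <- list(par = par, resp = resp, loglik = trace[length(trace)],
                   trace = trace)
    }
  }
  if (is.null(best))
    stop("all EM starts degenerated (empty group); reduce K", call. = FALSE)

  # canonical order: ascending intercept
  ord <- order(vapply(best$par$coefs, `[`, 0, 1))
  pi_k <- best$par$pi[ord]
  coefs <- best$par$coefs[ord]
  mu <- best$par$mu[, ord, drop = FALSE]
  resp <- best$resp[, ord, drop = FALSE]
  orders <- orders[ord]

  assignment <- max.col(resp, ties.method = "first")
  shares <- tabulate(assignment, K) / n
  avg_post <- vapply(seq_len(K), function(k) {
    if (any(assignment == k)) mean(resp[assignment == k, k]) else NA_real_
  }, 0)
  span <- apply(mu, 2, function(v) diff(range(v)))
  labels <- rep("controlled", K)
  if (K >= 2) labels[which.max(span)] <- "uncontrolled"
  n_par <- sum(orders + 1) + (K - 1) + 1
  bic <- -2 * best$loglik + n_par * log(n)

  structure(list(n_groups = K, orders = orders, coefficients = coefs,
                 residual_sd = best$par$sigma, mixing_proportions = pi_k,
                 log_likelihood = best$loglik, bic = bic, n_params = n_par,
                 posterior = resp, assignment = assignment,
                 group_shares = shares, avg_posterior = avg_post,
                 min_group_share = min(shares), labels = labels,
                 times = times, subject_ids = rownames(Y),
                 loglik_trace = best$trace),
            class = "gbtm_fit")
}

#' @export
print.gbtm_fit <- function(x, ...) {
  cat(sprintf("gbtm_fit: K = %d, logL = %.2f, BIC = %.2f, sigma = %.4f\n",
              x$n_groups, x$log_likelihood, x$bic, x$residual_sd))
  for (k in seq_len(x$n_groups))
    cat(sprintf("  group %d (%s): share %.3f, avg posterior %.3f, coef [%s]\n",
                k, x$labels[k], x$group_shares[k], x$avg_posterior[k],
                paste(signif(x$coefficients[[k]], 4), collapse = ", ")))
  invisible(x)
}

#' Select the number of trajectory groups by BIC
#'
#' Fits every combination of `K_range` and `orders`, computes
#' `BIC = -2 logL + p log(n_subjects)`, and marks models whose smallest
#' assigned-group share is below `min_share` as assumption-violating; the
#' best BIC among surviving models is selected. If every model violates the
#' share rule the best-BIC violator is returned with a warning (the
#' pragmatic choice when the smallest class of interest is itself rare).
#'
#' @param series as in [fit_gbtm()].
#' @param K_range candidate group counts (default 1:4).
#' @param orders candidate polynomial orders (applied to all groups).
#' @param min_share minimum assigned share (default 0.05).
#' @param ... passed to [fit_gbtm()].
#' @return list with `best` (a `gbtm_fit`) and `table` (one row per
#'   candidate: K, order, logL, BIC, min share, flag, selected).
#' @export
select_model <- function(series, K_range = 1:4, orders = 2:3,
                         min_share = 0.05, ...) {
  if (!length(K_range)) stop("K_range must be nonempty", call. = FALSE)
  fits <- list(); rows <- list()
  for (K in K_range) for (o in orders) {
    fit <- tryCatch(fit_gbtm(series, K, orders = o, ...),
                    error = function(e) NULL)
    key <- sprintf("K%d_o%d", K, o)
    if (is.null(fit)) {
      rows[[key]] <- data.frame(K = K, order = o, n_params = NA, logL = NA,
                                bic = NA, min_group_share = NA,
                                flag = "fit_failed", stringsAsFactors = FALSE)
      next
    }
    fits[[key]] <- fit
    rows[[key]] <- data.frame(
      K = K, order = o, n_params = fit$n_params, logL = fit$log_likelihood,
      bic = fit$bic, min_group_share = fit$min_group_share,
      flag = if (fit$min_group_share < min_share) "min_share_violation" else "",
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- !is.na(tab$bic) & tab$flag == ""
  if (any(ok)) {
    pick <- which(ok)[which.min(tab$bic[ok])]
  } else {
    any_fit <- !is.na(tab$bic)
    if (!any(any_fit)) stop("no candidate model could be fitted", call. = FALSE)
    pick <- which(any_fit)[which.min(tab$bic[any_fit])]
    warning("all candidate models violate the minimum-group-share rule; ",
            "returning the best BIC among violators")
  }
  tab$selected <- seq_len(nrow(tab)) == pick
  list(best = fits[[sprintf("K%d_o%d", tab$K[pick], tab$order[pick])]],
       table = tab)
}

#' Write trajectory artifacts
#'
#' @param fit a `gbtm_fit`.
#' @param selection optional selection table from [select_model()].
#' @param directory output directory; writes `trajectory_fit.json`
#'   (coefficients, shares, BIC table) and `assignments.tsv`
#'   (subject_id, group, posterior, label).
#' @return the directory, invisibly.
#' @export
write_trajectory <- function(fit, directory, selection = NULL) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  post <- fit$posterior[cbind(seq_along(fit$assignment), fit$assignment)]
  assignments <- data.frame(
    subject_id = fit$subject_ids %||% seq_along(fit$assignment),
    group = fit$assignment, posterior = post,
    label = fit$labels[fit$assignment], stringsAsFactors = FALSE)
  write_tsv(assignments, file.path(directory, "assignments.tsv"))
  payload <- list(n_groups = fit$n_groups, orders = fit$orders,
                  coefficients = fit$coefficients,
                  residual_sd = fit$residual_sd,
                  mixing_proportions = fit$mixing_proportions,
                  group_shares = fit$group_shares,
                  avg_posterior = fit$avg_posterior,
                  log_likelihood = fit$log_likelihood, bic = fit$bic,
                  labels = fit$labels, times = fit$times)
  if (!is.null(selection)) payload$selection_table <- selection
  jsonlite::write_json(payload, file.path(directory, "trajectory_fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}
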