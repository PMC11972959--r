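#!/usr/bin/env Rscript
# Stage 4: genetically predicted per-visit series and group-based
# trajectory models, with BIC selection over K = 1..3 and the 5%
# minimum-share rule.

library(bidirmr)

panel <- qc_filter(read_cohort("results/cohort"))$panel
wg <- bidirmr:::read_tsv_checked("results/wgrs.tsv",
                                 numeric_cols = c("wgrs_fbs", "wgrs_sbp"))
wg <- wg[match(panel$subject_ids, wg$subject_id), ]

for (ph in c("fbs", "sbp")) {
  series <- predict_series(panel, wg[[paste0("wgrs_", ph)]], ph)
  sel <- select_model(series, K_range = 1:3, orders = 2:3,
                      n_starts = 4, seed = 20260104)
  write_trajectory(sel$best, sprintf("results/trajectory_%s", ph),
                   selection = sel$table)
  fit <- sel$best
  message(sprintf("%s: selected K = %d (order %d), BIC %.1f, shares %s, labels %s",
                  toupper(ph), fit$n_groups, fit$orders[1], fit$bic,
                  paste(sprintf("%.2f", fit$group_shares), collapse = "/"),
                  paste(fit$labels, collapse = "/")))
  message(sprintf("  average posterior by group: %s",
                  paste(sprintf("%.2f", fit$avg_posterior), collapse = "/")))
}
message("trajectory fits and assignments written to results/trajectory_*/")
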