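#!/usr/bin/env Rscript

# Stage 4: prognostic evaluation of the refit Feature-score.
# Univariate/multivariate Cox models, per-feature Spearman correlations
# with OS, nomogram point scales with calibration, ROC with the
# training-cohort Youden cutoff applied to the validation cohort, and
# Kaplan-Meier risk stratification.

library(collascore)

pf <- read.csv("results/patient_scores.csv", stringsAsFactors = TRUE)
pf$feature_score <- pf$score_refit
tr <- pf[pf$cohort == "training", ]
va <- pf[pf$cohort == "validation", ]

covs <- c("age_group", "sex", "tnm", "differentiation", "pni", "lvi",
          "location", "feature_score")
uni <- cox_fit(pf, covs, mode = "univariate")
multi <- cox_fit(pf, covs, mode = "multivariate")
cox_tab <- rbind(uni$table, multi$table)
write.csv(cox_tab, "results/cox_models.csv", row.names = FALSE)
fs <- uni$table[uni$table$covariate == "feature_score", ]
message(sprintf("Univariate Feature-score: HR %.3f [%.3f-%.3f], p = %.4g",
                fs$hr, fs$ci_low, fs$ci_high, fs$p))

fc <- feature_os_correlation(pf, method = "spearman")
write.csv(fc, "results/feature_os_spearman.csv", row.names = FALSE)
message("Feature-OS Spearman correlations:")
print(fc, digits = 3)

nomo <- build_nomogram(multi, pf)
write.csv(nomo$point_tables, "results/nomogram_points.csv",
          row.names = FALSE)
pred12 <- predict_survival(nomo, pf, 12)
cal <- calibration_curve(pred12, pf, 12, n_bins = 4)
write.csv(cal, "results/calibration_12mo.csv", row.names = FALSE)
message(sprintf("12-month calibration: mean |pred - obs| = %.3f",
                mean(abs(cal$predicted - cal$observed))))

roc_tr <- roc_youden(tr$feature_score, tr$event)
message(sprintf("Training ROC: AUC %.3f [%.3f-%.3f], Youden cutoff %.3f",
                roc_tr$auc, roc_tr$auc_ci[1], roc_tr$auc_ci[2],
                roc_tr$cutoff))
for (nm in c("training", "validation")) {
  dd <- if (nm == "training") tr else va
  grp <- assign_risk_group(dd$feature_score, roc_tr$cutoff)
  km <- km_logrank(dd, grp)
  message(sprintf("  %s KM: high-vs-low HR %.2f, log-rank p = %.4g",
                  nm, km$hr, km$logrank_p))
  write.csv(km$curves, sprintf("results/km_%s.csv", nm), row.names = FALSE)
}
message("Wrote results/cox_models.csv, nomogram_points.csv, ",
        "calibration_12mo.csv, km_*.csv")
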