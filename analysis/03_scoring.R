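#!/usr/bin/env Rscript

# Stage 3: Feature-score. Split the cohort into training and validation
# (stratified by event status, 107:42 proportions), refit the eight
# coefficients by cross-validated ridge Cox regression on the training
# set, and score every patient with both the refit and the published
# coefficient sets.

library(collascore)

pf <- read.csv("results/patient_features.csv")
sp <- split_cohort(pf, prop = 107 / 149, seed = 42L)
message(sprintf("Training %d / validation %d patients (event rates %.2f / %.2f)",
                nrow(sp$training), nrow(sp$validation),
                mean(sp$training$event), mean(sp$validation$event)))

refit <- fit_ridge_cv(sp$training, k_folds = 5, seed = 42L)
message("Refit ridge-Cox coefficients (z-scored features), lambda = ",
        signif(refit$penalty, 3), ":")
print(round(refit$weights, 4))

pf$cohort <- ifelse(pf$patient_id %in% sp$training$patient_id,
                    "training", "validation")
pf$score_refit <- compute_feature_score(pf, refit)
pf$score_published <- compute_feature_score(
  pf, published_score_coefficients()
)
write.csv(pf, "results/patient_scores.csv", row.names = FALSE)

cors <- cor(pf[, c("score_refit", "score_published")],
            pf$os_months, method = "spearman")
message(sprintf("Spearman with OS: refit %.3f, published %.3f",
                cors[1], cors[2]))
message("Wrote results/patient_scores.csv")
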