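#!/usr/bin/env Rscript
# Stage 3: split, pre-select and fit the imaging-biomarker score.
#
# Splits 99/55 as in the study design, applies the three-rule cascade on
# the training cohort (univariable Cox p < 0.25; |r| >= 0.8 pruning
# keeping the smaller screening p; LASSO-Cox with 10-fold CV at the
# minimum-deviance lambda), reports VIFs of the retained set, and writes
# the fitted self-contained formula plus per-patient scores.

suppressPackageStartupMessages(library(ibmscore))
dir.create("results", showWarnings = FALSE)

feats <- read.csv("results/features.csv", check.names = FALSE)
tab <- read.csv("scratch/cohort/cohort.csv")
data <- merge(tab, feats, by = "patient_id", sort = FALSE)

sp <- random_split(data$patient_id, 99 / 154, seed = 7L)
train <- data[data$patient_id %in% sp$training, ]
valid <- data[data$patient_id %in% sp$validation, ]
message(sprintf("split: %d training / %d validation",
                nrow(train), nrow(valid)))

balance <- cohort_balance(train, valid,
                          c(continuous = "truth_major_semi_axis",
                            continuous = "truth_smoothing_sigma",
                            continuous = "truth_mean_intensity",
                            categorical = "truth_slice_thickness"))
write.csv(balance, "results/balance.csv", row.names = FALSE)
message("cohort balance (all p should be unremarkable):")
print(balance)

reg <- feature_registry()
screen <- univariable_cox_screen(train, reg$name)
message(sprintf("univariable screen: %d / 96 kept at p < 0.25",
                sum(screen$kept)))
pruned <- correlation_prune(train, screen)
message(sprintf("correlation pruning removed %d, retained %d",
                length(pruned$removed), length(pruned$retained)))
if (nrow(train) > length(pruned$retained) + 1) {
  v <- vif(train, pruned$retained)
  message(sprintf("VIF range of retained set: %.2f - %.2f",
                  min(v), max(v[is.finite(v)])))
}

fit <- fit_lasso_cox(train, pruned$retained, seed = 11L)
message(sprintf("lambda_min = %.4f (log = %.3f), %d nonzero terms",
                fit$lambda_min, log(fit$lambda_min), length(fit$beta)))
formula <- build_score(fit, train, endpoint = "OS")
message(sprintf("score constant: %+.1f (smallest 0.1 multiple giving",
                formula$constant), " positive training scores)")
write_formula(formula, "results/formula.json")

scores <- rbind(
  data.frame(patient_id = train$patient_id, cohort = "training",
             score = ibm_score(train, formula)),
  data.frame(patient_id = valid$patient_id, cohort = "validation",
             score = ibm_score(valid, formula)))
write.csv(scores, "results/scores.csv", row.names = FALSE)
message("wrote results/formula.json and results/scores.csv")
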