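#!/usr/bin/env Rscript
# Post-hoc analyses on the logistic-model predictions: subgroup AUCs,
# per-marker comparison on shared folds, dichotomized-risk survival (Cox +
# Kaplan-Meier), binary metrics. Writes results/posthoc/.

library(eegprog)

cohort <- read_tsv(file.path("results", "cohort", "cohort.tsv"))
tensor <- read_tsv(file.path("results", "markers", "marker_tensor.tsv"))
pred <- read_tsv(file.path("results", "evaluation", "predictions_glm_logistic_l1l2.tsv"))
out_dir <- file.path("results", "posthoc")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# subgroup AUCs with the existing fold assignment
sub <- do.call(rbind, lapply(
  c("age_group", "sex", "focal_lesion", "ied_status", "slowing", "asm_count",
    "epilepsy_type"),
  function(v) subgroup_auc(pred, cohort, v)))
write_tsv(sub, file.path(out_dir, "subgroup_auc.tsv"))
cat("subgroup AUCs (not-estimable strata are small-sample):\n")
print(sub[, c("variable", "stratum", "n", "auc", "estimable")])

# per-marker comparison on identical folds
fm <- build_feature_matrix(tensor, cohort)
sp <- model_spec("glm_logistic_l1l2", grid = expand.grid(alpha = 1, C = 1),
                 select_c = 0.1)
marker_tab <- suppressWarnings(compare_markers(fm, sp, seed = 20260924))
write_tsv(marker_tab, file.path(out_dir, "marker_comparison.tsv"))
cat("\nper-marker AUC (identical CV splits):\n")
print(marker_tab)

# dichotomized-risk survival
mm <- match(pred$eeg_id, cohort$eeg_id)
risk <- dichotomize_risk(pred$score)
cox <- fit_cox(cohort$time_to_event_weeks[mm], cohort$event_observed[mm],
               data.frame(risk_group = risk, age = cohort$age[mm],
                          sex = cohort$sex[mm], asm_count = cohort$asm_count[mm]))
write_tsv(cox$hr, file.path(out_dir, "cox_hazard_ratios.tsv"))
cat("\nCox hazard ratios (risk group adjusted for age, sex, ASM count):\n")
print(cox$hr)

km <- kaplan_meier(cohort$time_to_event_weeks[mm], cohort$event_observed[mm], risk)
write_tsv(km$curves, file.path(out_dir, "km_curves.tsv"))
cat("\none-year seizure-free survival by predicted risk:\n")
print(round(km$surv_52w, 3))
cat("logrank p:", format(km$logrank$p, digits = 3), "\n")

bm <- binary_metrics(pred$score, pred$label, threshold = 0.5)
write_tsv(bm, file.path(out_dir, "binary_metrics.tsv"))
cat("\nbinary metrics at 0.5:\n")
print(bm)
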