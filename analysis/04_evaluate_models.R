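#!/usr/bin/env Rscript
# Evaluate the four classifiers for one-year seizure recurrence under
# patient-grouped nested CV (10 inner / 5 outer folds, median aggregation),
# plus the age-interaction and two-step variants for the logistic model.
# Reads results/cohort + results/markers, writes results/evaluation/.

library(eegprog)

cohort <- read_tsv(file.path("results", "cohort", "cohort.tsv"))
tensor <- read_tsv(file.path("results", "markers", "marker_tensor.tsv"))
out_dir <- file.path("results", "evaluation")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

fm <- build_feature_matrix(tensor, cohort)
seed <- 20260924

specs <- list(
  glm_logistic_l1l2 = model_spec("glm_logistic_l1l2",
                                 grid = expand.grid(alpha = c(1, 0), C = 1),
                                 select_c = 0.1),
  svm_rbf = model_spec("svm_rbf", grid = expand.grid(cost = c(1, 10), gamma = NA),
                       select_c = 0.1),
  random_forest = model_spec("random_forest",
                             grid = expand.grid(num_trees = 500, max_depth = 0,
                                                min_node = c(1, 5)),
                             select_c = 0.1),
  gradient_boosted_trees = model_spec("gradient_boosted_trees",
                                      grid = expand.grid(nrounds = 200, eta = 0.1,
                                                         max_leaves = c(15, 31)),
                                      select_c = 0.1))

rows <- list()
cvs <- list()
for (alg in names(specs)) {
  cv <- suppressWarnings(nested_cv_evaluate(fm, specs[[alg]], seed = seed))
  cvs[[alg]] <- cv
  write_tsv(cv$predictions, file.path(out_dir, sprintf("predictions_%s.tsv", alg)))
  rows[[alg]] <- data.frame(model = alg, variant = "plain", auc = cv$result$auc,
                            ci_low = cv$result$ci_low, ci_high = cv$result$ci_high,
                            p_vs_chance = cv$result$p_vs_chance)
  cat(sprintf("%-24s AUC %.3f (%.3f-%.3f) p=%.3g\n", alg, cv$result$auc,
              cv$result$ci_low, cv$result$ci_high, cv$result$p_vs_chance))
}

# age-interaction variant (logistic)
age <- cohort$age[match(fm$eeg_id, cohort$eeg_id)]
fm_age <- add_age_interactions(fm, age)
cv_age <- suppressWarnings(nested_cv_evaluate(fm_age, specs$glm_logistic_l1l2, seed = seed))
rows$age <- data.frame(model = "glm_logistic_l1l2", variant = "age-interaction",
                       auc = cv_age$result$auc, ci_low = cv_age$result$ci_low,
                       ci_high = cv_age$result$ci_high,
                       p_vs_chance = cv_age$result$p_vs_chance)
cat(sprintf("%-24s AUC %.3f (%.3f-%.3f)\n", "glm + age interactions",
            cv_age$result$auc, cv_age$result$ci_low, cv_age$result$ci_high))

# two-step IED variant on the plain logistic predictions
pred <- cvs$glm_logistic_l1l2$predictions
flag <- cohort$ied_status[match(pred$eeg_id, cohort$eeg_id)] == "present"
pred$score <- two_step_classify(flag, pred$score)
res2 <- auc_ci_ledell(pred$score, pred$label, pred$fold)
rows$two_step <- data.frame(model = "glm_logistic_l1l2", variant = "two-step-ied",
                            auc = res2$auc, ci_low = res2$ci_low,
                            ci_high = res2$ci_high, p_vs_chance = res2$p_vs_chance)
cat(sprintf("%-24s AUC %.3f (%.3f-%.3f)\n", "glm two-step (IED)",
            res2$auc, res2$ci_low, res2$ci_high))

write_tsv(do.call(rbind, rows), file.path(out_dir, "evaluation_summary.tsv"))
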