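# Subgroup AUCs, marker comparison, survival analyses, binary metrics

make_predictions <- function(n = 60, seed = 1, auc_effect = 1.5) {
  set.seed(seed)
  y <- runif(n) < 0.4
  data.frame(eeg_id = sprintf("E%03d", 1:n), fold = rep_len(1:5, n),
             label = y, score = plogis(auc_effect * y + rnorm(n)),
             stringsAsFactors = FALSE)
}

test_that("subgroup AUC over one stratum equals the overall result", {
  pr <- make_predictions()
  cohort <- data.frame(eeg_id = pr$eeg_id, sex = "F", age = 50, asm_count = 0,
                       focal_lesion = FALSE, ied_status = "absent",
                       slowing = FALSE, epilepsy_type = "focal",
                       stringsAsFactors = FALSE)
  res <- subgroup_auc(pr, cohort, "sex")
  overall <- auc_ci_ledell(pr$score, pr$label, pr$fold)
  expect_equal(res$auc, overall$auc)
  expect_equal(res$ci_low, overall$ci_low)

  # a one-class stratum is flagged, not an error
  cohort$sex <- ifelse(pr$label, "F", "M")
  cohort$sex[which(pr$label)[1:3]] <- "M"
  res2 <- subgroup_auc(pr, cohort, "sex")
  expect_false(res2$estimable[res2$stratum == "F"])
  expect_error(subgroup_auc(pr, cohort, "shoe_size"), "unknown")
})

test_that("injected subgroup heterogeneity is recovered", {
  deltas <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 120
    y <- runif(n) < 0.4
    lesion <- runif(n) < 0.5
    strength <- ifelse(lesion, 0, 2.5)  # effect only in lesion-negative patients
    pr <- data.frame(eeg_id = sprintf("E%03d", 1:n), fold = rep_len(1:5, n),
                     label = y, score = plogis(strength * y + rnorm(n)))
    cohort <- data.frame(eeg_id = pr$eeg_id, focal_lesion = lesion)
    res <- subgroup_auc(pr, cohort, "focal_lesion")
    res$auc[res$stratum == "no_lesion"] - res$auc[res$stratum == "lesion"]
  }, numeric(1))
  expect_gt(mean(deltas), 0.1)
  expect_gte(sum(deltas > 0), 9)
})

test_that("marker comparison ranks the informative family first on shared folds", {
  fm <- make_sim_fm(n_pat = 40, n_ep = 2, p = 60, d = 0, seed = 7)
  bp_cols <- which(fm$marker == "BP")
  set.seed(8)
  fm$x[, bp_cols] <- fm$x[, bp_cols] + fm$y * 1.5
  sp <- model_spec("glm_logistic_l1l2", grid = data.frame(alpha = 1, C = 1),
                   select_c = 0.1)
  tab <- compare_markers(fm, sp, seed = 9)
  expect_identical(tab$marker[tab$marker != "all"][1], "BP")
  expect_gte(tab$auc[tab$marker == "all"], max(tab$auc[tab$marker == "BP"]) - 0.05)
  expect_length(attr(tab, "folds"), nrow(fm$x))
})

test_that("risk dichotomization follows the strict-mean rule", {
  expect_equal(as.character(dichotomize_risk(c(0.2, 0.8))), c("low", "high"))
  expect_true(all(dichotomize_risk(rep(0.4, 5)) == "low"))
  expect_equal(as.character(dichotomize_risk(c(0, 0.4, 0.45), center = "median")),
               c("low", "low", "high"))
  expect_error(dichotomize_risk(0.5), ">= 2")
})

test_that("Cox fit recovers a known hazard ratio with covariate adjustment", {
  set.seed(10)
  n <- 500
  grp <- rep(c(0, 1), each = n / 2)
  o <- simulate_outcomes(grp, list(baseline_hazard_week = 0.006,
                                   log_hr_risk = log(2),
                                   followup_min_weeks = 26, followup_max_weeks = 156),
                         seed = 11)
  cov <- data.frame(risk_group = factor(ifelse(grp > 0, "high", "low"),
                                        levels = c("low", "high")),
                    age = round(runif(n, 18, 80)), sex = sample(c("F", "M"), n, TRUE),
                    asm_count = rpois(n, 1))
  fit <- fit_cox(o$time_to_event_weeks, o$event_observed, cov)
  hr_row <- fit$hr[grep("risk_group", fit$hr$term), ]
  expect_lt(abs(log(hr_row$hr) - log(2)), 0.35)
  expect_true(hr_row$ci_low <= hr_row$hr && hr_row$hr <= hr_row$ci_high)
  expect_error(fit_cox(o$time_to_event_weeks, rep(FALSE, n), cov), "at least one")
  expect_error(fit_cox(c(-1, o$time_to_event_weeks[-1]), o$event_observed, cov),
               "negative")
})

test_that("Kaplan-Meier matches closed forms and runs the logrank test", {
  km <- kaplan_meier(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$curves$surv, c(2 / 3, 1 / 3, 0))
  km_c <- kaplan_meier(c(5, 6, 7), c(FALSE, FALSE, FALSE))
  expect_true(all(km_c$curves$surv == 1))
  set.seed(12)
  g <- rep(c("a", "b"), each = 100)
  o <- simulate_outcomes(rep(c(0, 1.5), each = 100),
                         list(baseline_hazard_week = 0.005, log_hr_risk = 1,
                              followup_min_weeks = 60, followup_max_weeks = 200),
                         seed = 13)
  km2 <- kaplan_meier(o$time_to_event_weeks, o$event_observed, g)
  expect_lt(km2$surv_52w[["b"]], km2$surv_52w[["a"]])
  expect_lt(km2$logrank$p, 0.05)
})

test_that("logrank p-values are uniform under the null", {
  ps <- vapply(1:200, function(s) {
    o <- simulate_outcomes(rep(0, 80),
                           list(baseline_hazard_week = 0.008, log_hr_risk = 0,
                                followup_min_weeks = 26, followup_max_weeks = 156),
                           seed = 1000 + s)
    g <- rep(c("a", "b"), 40)
    kaplan_meier(o$time_to_event_weeks, o$event_observed, g)$logrank$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("binary metrics reproduce the confusion-table arithmetic", {
  scores <- c(rep(0.9, 10), rep(0.1, 5), rep(0.9, 3), rep(0.1, 12))
  labels <- c(rep(TRUE, 15), rep(FALSE, 15))
  m <- binary_metrics(scores, labels)
  est <- stats::setNames(m$estimate, m$metric)
  expect_equal(unname(est["sensitivity"]), 10 / 15)
  expect_equal(unname(est["specificity"]), 12 / 15)
  expect_equal(unname(est["ppv"]), 10 / 13)
  expect_equal(unname(est["npv"]), 12 / 17)
  # PPV identity from the same table
  prev <- mean(labels)
  ppv_id <- est["sensitivity"] * prev /
    (est["sensitivity"] * prev + (1 - est["specificity"]) * (1 - prev))
  expect_equal(unname(est["ppv"]), unname(ppv_id))
  perfect <- binary_metrics(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(perfect$estimate == 1))
})
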