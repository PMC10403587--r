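# Post-hoc analyses: subgroup AUCs, per-marker comparison, survival

#' Subgroup strata for a clinical variable
#'
#' Supported variables: `age_group` (18-40, 40-60, >60), `sex`,
#' `focal_lesion`, `ied_status`, `slowing`, `asm_count` (0, 1, >=2),
#' `epilepsy_type`.
#'
#' @param cohort Cohort table.
#' @param variable Variable name.
#' @return Factor of stratum labels, one per cohort row.
#' @export
subgroup_strata <- function(cohort, variable) {
  switch(variable,
    age_group = cut(cohort$age, c(-Inf, 40, 60, Inf),
                    labels = c("18-40", "40-60", ">60")),
    sex = factor(cohort$sex),
    focal_lesion = factor(ifelse(cohort$focal_lesion, "lesion", "no_lesion")),
    ied_status = factor(cohort$ied_status),
    slowing = factor(ifelse(cohort$slowing, "slowing", "no_slowing")),
    asm_count = cut(cohort$asm_count, c(-Inf, 0, 1, Inf), labels = c("0", "1", ">=2")),
    epilepsy_type = factor(cohort$epilepsy_type),
    stop(sprintf("unknown subgroup variable: %s", variable))
  )
}

#' Subgroup AUC analysis
#'
#' Recomputes the cross-validated AUC and LeDell CI within each stratum, using
#' the existing fold assignments. Strata with fewer than `min_per_class` EEGs
#' in either class are reported as not estimable (`NA`), mirroring small
#' subgroups where estimation is unreliable or impossible.
#'
#' @param predictions Per-EEG prediction data.frame from
#'   [nested_cv_evaluate()] (columns `eeg_id`, `fold`, `label`, `score`).
#' @param cohort Cohort table.
#' @param variable Subgroup variable (see [subgroup_strata()]).
#' @param min_per_class Minimum EEGs per class per stratum (default 5).
#' @return Data frame: one row per stratum with `n`, `auc`, `ci_low`,
#'   `ci_high`, `estimable`.
#' @export
subgroup_auc <- function(predictions, cohort, variable, min_per_class = 5L) {
  strata <- subgroup_strata(cohort, variable)
  st <- strata[match(predictions$eeg_id, cohort$eeg_id)]
  out <- lapply(levels(droplevels(st)), function(lv) {
    sel <- which(st == lv)
    n1 <- sum(predictions$label[sel]); n0 <- sum(!predictions$label[sel])
    if (n1 < min_per_class || n0 < min_per_class) {
      return(data.frame(stratum = lv, n = length(sel), auc = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        estimable = FALSE, stringsAsFactors = FALSE))
    }
    r <- suppressWarnings(auc_ci_ledell(predictions$score[sel],
                                        predictions$label[sel],
                                        predictions$fold[sel]))
    data.frame(stratum = lv, n = length(sel), auc = r$auc, ci_low = r$ci_low,
               ci_high = r$ci_high, estimable = TRUE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$variable <- variable
  res
}

#' Per-marker predictive comparison on identical CV splits
#'
#' Runs [nested_cv_evaluate()] once per marker family (restricting the feature
#' columns to that family) and once for the union of all markers, injecting
#' the same outer-fold assignment into every run. Markers whose features are
#' all missing are skipped with a warning.
#'
#' @param fm Full `feature_matrix`.
#' @param spec A [model_spec()].
#' @param markers Marker families to compare (default: all present in `fm`).
#' @param inner_k,outer_k,q,seed As in [nested_cv_evaluate()].
#' @return Data frame sorted by AUC (one row per marker plus `"all"`), with
#'   the shared fold assignment as attribute `"folds"`.
#' @export
compare_markers <- function(fm, spec, markers = NULL, inner_k = 10L,
                            outer_k = 5L, q = 0.5, seed = 1L) {
  if (is.null(markers)) markers <- unique(fm$marker)
  folds <- grouped_folds(fm$patient_id, outer_k, seed)
  run <- function(cols) {
    nested_cv_evaluate(.subset_fm(fm, cols = cols), spec, inner_k = inner_k,
                       outer_k = outer_k, q = q, seed = seed, folds = folds)
  }
  rows <- list()
  for (mk in markers) {
    cols <- which(fm$marker == mk)
    if (!length(cols) || all(is.na(fm$x[, cols]))) {
      warning(sprintf("marker %s has no observed features; skipped", mk))
      next
    }
    r <- run(cols)$result
    rows[[mk]] <- data.frame(marker = mk, auc = r$auc, ci_low = r$ci_low,
                             ci_high = r$ci_high, stringsAsFactors = FALSE)
  }
  r <- run(seq_len(ncol(fm$x)))$result
  rows[["all"]] <- data.frame(marker = "all", auc = r$auc, ci_low = r$ci_low,
                              ci_high = r$ci_high, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc), ]
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  out
}

#' Dichotomize predicted risk at the cohort mean
#'
#' High risk means a score strictly above the mean score of the analysis
#' cohort (all equal scores therefore fall in the low-risk group). A `median`
#' switch is provided.
#'
#' @param scores Per-EEG predicted scores.
#' @param center `"mean"` (default) or `"median"`.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize_risk <- function(scores, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(scores) < 2L) stop("need >= 2 EEGs to dichotomize")
  c0 <- if (center == "mean") mean(scores) else stats::median(scores)
  factor(ifelse(scores > c0, "high", "low"), levels = c("low", "high"))
}

#' Cox proportional-hazards model for seizure recurrence
#'
#' Efron-tie partial-likelihood fit of the dichotomized risk group controlled
#' for standardized age, sex, and ASM count (ASM entered as a continuous
#' covariate). Proportionality is checked with the scaled-residual trend test;
#' violations are reported as messages. Near-separation triggers a penalized
#' (ridge) refit with a warning.
#'
#' @param time_weeks Follow-up or event time in weeks.
#' @param event Logical event indicator.
#' @param covariates Data frame with columns `risk_group` (factor low/high),
#'   `age` (years), `sex`, `asm_count`. Extra columns are included as-is.
#' @return List of class `survival_result`: `hr` table (HR, CI, p per
#'   covariate), the `fit`, and `proportionality` (cox.zph table).
#' @export
fit_cox <- function(time_weeks, event, covariates) {
  if (any(time_weeks < 0)) stop("negative follow-up times")
  if (sum(event) < 1L) stop("Cox model needs at least one observed event")
  df <- as.data.frame(covariates)
  if ("age" %in% names(df)) df$age <- as.numeric(scale(df$age))
  df$.time <- time_weeks; df$.event <- as.integer(event)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(setdiff(names(df), c(".time", ".event")),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) > 15)) {
    warning("possible separation; refitting with ridge penalty 1e-3")
    vars <- setdiff(names(df), c(".time", ".event"))
    xm <- stats::model.matrix(stats::reformulate(vars), df)[, -1, drop = FALSE]
    df2 <- data.frame(.time = df$.time, .event = df$.event)
    fit <- survival::coxph(survival::Surv(.time, .event) ~
                             survival::ridge(xm, theta = 1e-3),
                           data = df2, ties = "efron")
  }
  sm <- summary(fit)
  hr <- data.frame(term = rownames(sm$coefficients),
                   hr = exp(sm$coefficients[, "coef"]),
                   ci_low = sm$conf.int[, "lower .95"],
                   ci_high = sm$conf.int[, "upper .95"],
                   p = sm$coefficients[, ncol(sm$coefficients)],
                   stringsAsFactors = FALSE)
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  if (!is.null(zph) && any(zph$table[, "p"] < 0.05, na.rm = TRUE)) {
    message("fit_cox: proportional-hazards test flags covariate(s): ",
            paste(rownames(zph$table)[zph$table[, "p"] < 0.05], collapse = ", "))
  }
  structure(list(hr = hr, fit = fit, proportionality = if (!is.null(zph)) zph$table),
            class = "survival_result")
}

#' Kaplan-Meier curves with log-rank test
#'
#' Product-limit estimate per group with Greenwood 95% CI bands, the log-rank
#' test across groups, and the one-year (52-week) survival per group.
#'
#' @param time_weeks Event/censoring times in weeks.
#' @param event Logical event indicator.
#' @param group Grouping factor (empty groups dropped with a warning).
#' @return List: `curves` (data.frame time/surv/ci per group), `logrank`
#'   (chi-square statistic, df, p), `surv_52w` (named vector).
#' @export
kaplan_meier <- function(time_weeks, event, group = NULL) {
  if (is.null(group)) group <- factor(rep("all", length(time_weeks)))
  group <- droplevels(factor(group))
  empty <- setdiff(levels(group), unique(as.character(group)))
  if (length(empty)) warning("empty group(s) excluded: ", paste(empty, collapse = ", "))
  df <- data.frame(t = time_weeks, e = as.integer(event), g = group)
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = df, conf.type = "log")
  strata_names <- if (is.null(fit$strata)) levels(group) else sub("^g=", "", names(fit$strata))
  idx <- if (is.null(fit$strata)) rep(1L, length(fit$time)) else rep(seq_along(fit$strata), fit$strata)
  curves <- data.frame(group = strata_names[idx], time = fit$time,
                       surv = fit$surv, ci_low = fit$lower, ci_high = fit$upper,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       stringsAsFactors = FALSE)
  s52 <- vapply(strata_names, function(g) {
    cv <- curves[curves$group == g & curves$time <= 52, , drop = FALSE]
    if (!nrow(cv)) 1 else cv$surv[nrow(cv)]
  }, numeric(1))
  logrank <- NULL
  if (nlevels(group) > 1L) {
    sd <- survival::survdiff(survival::Surv(t, e) ~ g, data = df)
    logrank <- list(chisq = sd$chisq, df = length(sd$n) - 1,
                    p = stats::pchisq(sd$chisq, length(sd$n) - 1, lower.tail = FALSE))
  }
  list(curves = curves, logrank = logrank, surv_52w = s52, fit = fit)
}

#' Binary classification metrics at a threshold
#'
#' Sensitivity, specificity, PPV and NPV from the confusion table at
#' `threshold`, each with an exact (Clopper-Pearson) binomial 95% CI.
#'
#' @param scores Per-EEG scores.
#' @param labels Per-EEG labels.
#' @param threshold Decision threshold (default 0.5; score > threshold =
#'   positive call).
#' @return Data frame with one row per metric: `estimate`, `ci_low`,
#'   `ci_high`, `num`, `den`.
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  pos <- scores > threshold
  tp <- sum(pos & labels); fn <- sum(!pos & labels)
  fp <- sum(pos & !labels); tn <- sum(!pos & !labels)
  mk <- function(name, num, den) {
    if (den == 0) {
      return(data.frame(metric = name, estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, num = num, den = den,
                        stringsAsFactors = FALSE))
    }
    ci <- stats::binom.test(num, den)$conf.int
    data.frame(metric = name, estimate = num / den, ci_low = ci[1],
               ci_high = ci[2], num = num, den = den, stringsAsFactors = FALSE)
  }
  rbind(mk("sensitivity", tp, tp + fn), mk("specificity", tn, tn + fp),
        mk("ppv", tp, tp + fp), mk("npv", tn, tn + fn))
}
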