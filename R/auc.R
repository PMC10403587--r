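# ROC AUC and confidence intervals (DeLong, LeDell cross-validated)

#' Mann-Whitney ROC AUC
#'
#' Rank-based AUC with ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels Logical or 0/1 labels (TRUE/1 = case).
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval for the ROC AUC
#'
#' Mann-Whitney AUC with the DeLong structural-component variance and a
#' normal-approximation 95% CI truncated to \[0, 1\].
#'
#' @inheritParams auc_mw
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `eeg_eval_result`: `auc`, `ci_low`, `ci_high`,
#'   `ci_method = "delong"`, `se`, `n_eegs`, `p_vs_chance`.
#' @export
auc_ci_delong <- function(scores, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  cases <- scores[labels]; controls <- scores[!labels]
  m <- length(cases); n <- length(controls)
  if (m == 0L || n == 0L) stop("both classes must be present")
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(cases, function(x) mean(psi(x, controls)), numeric(1))
  v01 <- vapply(controls, function(y) mean(psi(cases, y)), numeric(1))
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else as.numeric(auc == 0.5)
  structure(list(auc = auc, ci_low = max(0, auc - z * se),
                 ci_high = min(1, auc + z * se), ci_method = "delong",
                 se = se, n_eegs = m + n, per_fold_aucs = NULL,
                 p_vs_chance = p),
            class = "eeg_eval_result")
}

#' LeDell influence-function CI for the cross-validated AUC
#'
#' The point estimate is the average of the per-fold AUCs; the variance comes
#' from the influence function of the CV-AUC estimator evaluated within each
#' fold (cases: projection onto the control-score distribution, controls:
#' onto the case-score distribution), combined across folds. 95% normal CI
#' truncated to \[0, 1\]. Folds containing a single class are excluded with a
#' warning.
#'
#' @param scores Per-EEG aggregated scores.
#' @param labels Per-EEG labels.
#' @param fold_ids Outer-fold assignment per EEG.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `eeg_eval_result` with `ci_method = "ledell_cv"` and
#'   `per_fold_aucs`.
#' @export
auc_ci_ledell <- function(scores, labels, fold_ids, conf_level = 0.95) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  folds <- sort(unique(fold_ids))
  fold_auc <- c(); fold_var <- c()
  for (f in folds) {
    sel <- fold_ids == f
    y <- labels[sel]; s <- scores[sel]
    if (length(unique(y)) < 2L) {
      warning(sprintf("fold %s has a single class; excluded from the CV-AUC average", f))
      next
    }
    cases <- s[y]; controls <- s[!y]
    m <- length(cases); n0 <- length(controls); nk <- m + n0
    psi <- function(x, yv) (x > yv) + 0.5 * (x == yv)
    g1 <- vapply(cases, function(x) mean(psi(x, controls)), numeric(1))
    g0 <- vapply(controls, function(yv) mean(psi(cases, yv)), numeric(1))
    a <- mean(g1)
    p1 <- m / nk
    ic <- c((g1 - a) / p1, (g0 - a) / (1 - p1))
    fold_auc <- c(fold_auc, a)
    fold_var <- c(fold_var, mean(ic^2) / nk)
  }
  if (!length(fold_auc)) stop("no fold with both classes present")
  auc <- mean(fold_auc)
  se <- sqrt(sum(fold_var) / length(fold_auc)^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else as.numeric(auc == 0.5)
  structure(list(auc = auc, ci_low = max(0, auc - z * se),
                 ci_high = min(1, auc + z * se), ci_method = "ledell_cv",
                 se = se, n_eegs = length(scores), per_fold_aucs = fold_auc,
                 p_vs_chance = p),
            class = "eeg_eval_result")
}

#' @export
print.eeg_eval_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f, %s; n = %d EEGs; p vs chance = %.3g)\n",
              x$auc, x$ci_low, x$ci_high, x$ci_method, x$n_eegs, x$p_vs_chance))
  invisible(x)
}
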