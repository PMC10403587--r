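# Patient-grouped nested cross-validation and model evaluation

#' Patient-grouped fold assignment
#'
#' All epochs of a patient land in the same fold; folds are balanced by
#' patient count.
#'
#' @param patient_ids Character/factor vector, one entry per row (epoch).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per row.
#' @export
grouped_folds <- function(patient_ids, k, seed = 1L) {
  pts <- unique(patient_ids)
  if (length(pts) < k) stop(sprintf("need >= %d distinct patients, got %d", k, length(pts)))
  shuffled <- .with_seed(seed, sample(pts))
  fold_of <- stats::setNames(rep_len(seq_len(k), length(pts)), shuffled)
  unname(fold_of[as.character(patient_ids)])
}

# Standardization fitted on the training rows only.
.fit_scaler <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
.apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$mu), 2, scaler$sd, "/")
}

# L1-penalized linear SVM (squared hinge) by FISTA proximal gradient.
# Objective: C * sum_i max(0, 1 - y_i (x_i b + b0))^2 + ||b||_1 (b0 unpenalized).
.l1svm_fit <- function(x, y, C, max_iter = 150L, tol = 1e-5) {
  yy <- ifelse(y, 1, -1)
  n <- nrow(x); p <- ncol(x)
  # Lipschitz bound for the smooth part: 2C * lambda_max(X'X) (X incl. intercept)
  v <- rep(1 / sqrt(p + 1), p + 1)
  Xa <- cbind(x, 1)
  for (i in 1:15) {
    v <- crossprod(Xa, Xa %*% v)
    v <- as.numeric(v) / sqrt(sum(v^2))
  }
  L <- 2 * C * sqrt(sum((crossprod(Xa, Xa %*% v))^2)) + 1e-8
  b <- numeric(p); b0 <- 0
  zb <- b; zb0 <- b0; tk <- 1
  soft <- function(u, lam) sign(u) * pmax(abs(u) - lam, 0)
  for (it in seq_len(max_iter)) {
    marg <- 1 - yy * (as.numeric(x %*% zb) + zb0)
    act <- marg > 0
    gb <- -2 * C * as.numeric(crossprod(x[act, , drop = FALSE], yy[act] * marg[act]))
    gb0 <- -2 * C * sum(yy[act] * marg[act])
    b_new <- soft(zb - gb / L, 1 / L)
    b0_new <- zb0 - gb0 / L
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zb <- b_new + (tk - 1) / t_new * (b_new - b)
    zb0 <- b0_new + (tk - 1) / t_new * (b0_new - b0)
    moved <- max(abs(b_new - b), abs(b0_new - b0))
    b <- b_new; b0 <- b0_new; tk <- t_new
    if (moved < tol) break
  }
  list(beta = b, beta0 = b0)
}

#' Feature selection with an L1-regularized linear SVM
#'
#' Fits a squared-hinge, L1-penalized linear SVM on standardized training
#' features and retains the columns with nonzero coefficients. When nothing
#' survives the penalty, all columns are retained with a warning.
#'
#' @param x Standardized, imputed feature matrix (training rows only).
#' @param y Logical labels.
#' @param C Inverse penalty strength (larger keeps more features).
#' @return Integer vector of retained column indices.
#' @export
feature_select_l1svm <- function(x, y, C = 0.1) {
  if (length(unique(y)) < 2L) stop("feature selection needs both classes")
  fit <- .l1svm_fit(x, as.logical(y), C)
  keep <- which(abs(fit$beta) > 1e-8)
  if (!length(keep)) {
    warning("L1-SVM selected no features; retaining all columns")
    keep <- seq_len(ncol(x))
  }
  keep
}

#' Model specification
#'
#' @param algorithm One of `"glm_logistic_l1l2"`, `"svm_rbf"`,
#'   `"random_forest"`, `"gradient_boosted_trees"`.
#' @param grid Data frame of hyperparameter combinations (one row per
#'   candidate); `NULL` for the default grid.
#' @param select_c Numeric grid of L1-SVM feature-selection strengths tried in
#'   the inner loop.
#' @param class_weights Use inverse-prevalence class weights (default TRUE).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("glm_logistic_l1l2", "svm_rbf",
                                     "random_forest", "gradient_boosted_trees"),
                       grid = NULL, select_c = c(0.01, 0.1),
                       class_weights = TRUE) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) {
    grid <- switch(algorithm,
      glm_logistic_l1l2 = expand.grid(alpha = c(1, 0), C = 10^c(-1, 0, 1)),
      svm_rbf = expand.grid(cost = 10^c(-1, 1), gamma = c(NA, 0.01)),  # NA = 1/p
      random_forest = expand.grid(num_trees = 500, max_depth = c(0, 8), min_node = c(1, 5)),
      gradient_boosted_trees = expand.grid(nrounds = 200, eta = c(0.05, 0.1),
                                           max_leaves = c(15, 31)))
  }
  if (!nrow(grid)) stop("hyperparameter grid must be non-empty")
  structure(list(algorithm = algorithm, grid = grid, select_c = select_c,
                 class_weights = class_weights),
            class = "model_spec")
}

# Fit one configuration and return a scoring closure (epoch scores in [0,1]).
.fit_model <- function(algorithm, hp, x, y, class_weights = TRUE, seed = 1L) {
  y <- as.logical(y)
  w <- rep(1, length(y))
  if (class_weights) {
    w[y] <- 0.5 / mean(y)
    w[!y] <- 0.5 / mean(!y)
  }
  if (algorithm == "glm_logistic_l1l2") {
    lam <- 1 / (hp$C * length(y))
    pad <- ncol(x) < 2L  # glmnet requires >= 2 columns
    if (pad) x <- cbind(x, .pad = 0)
    # decreasing path ending at the target lambda (glmnet converges poorly on
    # a single lambda)
    fit <- glmnet::glmnet(x, factor(y), family = "binomial", alpha = hp$alpha,
                          lambda = lam * c(16, 8, 4, 2, 1), weights = w,
                          standardize = FALSE)
    function(newx) {
      if (pad) newx <- cbind(newx, .pad = 0)
      as.numeric(stats::predict(fit, newx, type = "response", s = lam))
    }
  } else if (algorithm == "svm_rbf") {
    gam <- if (is.na(hp$gamma)) 1 / ncol(x) else hp$gamma
    cw <- if (class_weights) c("FALSE" = 0.5 / mean(!y), "TRUE" = 0.5 / mean(y)) else NULL
    fit <- e1071::svm(x, factor(y), kernel = "radial", cost = hp$cost,
                      gamma = gam, class.weights = cw, scale = FALSE)
    function(newx) {
      d <- attr(stats::predict(fit, newx, decision.values = TRUE), "decision.values")[, 1]
      # orient decision values toward the positive class
      if (colnames(attr(stats::predict(fit, newx[1, , drop = FALSE],
                                       decision.values = TRUE),
                        "decision.values"))[1] == "FALSE/TRUE") d <- -d
      stats::plogis(d)
    }
  } else if (algorithm == "random_forest") {
    df <- data.frame(y = factor(y), x, check.names = FALSE)
    fit <- ranger::ranger(y ~ ., data = df, probability = TRUE,
                          num.trees = hp$num_trees,
                          max.depth = if (hp$max_depth == 0) NULL else hp$max_depth,
                          min.node.size = hp$min_node, case.weights = w,
                          seed = seed, num.threads = 1)
    function(newx) {
      pr <- stats::predict(fit, data.frame(newx, check.names = FALSE),
                           num.threads = 1)$predictions
      pr[, "TRUE"]
    }
  } else {
    spw <- if (class_weights) sum(!y) / max(sum(y), 1) else 1
    fit <- xgboost::xgboost(
      data = x, label = as.numeric(y), nrounds = hp$nrounds,
      params = list(objective = "binary:logistic", eta = hp$eta,
                    tree_method = "hist", grow_policy = "lossguide",
                    max_leaves = hp$max_leaves, max_depth = 0,
                    scale_pos_weight = spw, nthread = 1, seed = seed),
      verbose = 0)
    function(newx) as.numeric(stats::predict(fit, newx))
  }
}

#' Aggregate epoch-level predictions per EEG
#'
#' Empirical `q`-quantile (linear interpolation, default the median) of each
#' EEG's epoch scores.
#'
#' @param scores Numeric epoch scores.
#' @param eeg_id EEG identifier per score.
#' @param q Aggregation quantile in \[0.1, 0.9\].
#' @return Named numeric vector of per-EEG scores.
#' @export
aggregate_epoch_predictions <- function(scores, eeg_id, q = 0.5) {
  if (q < 0.1 - 1e-9 || q > 0.9 + 1e-9) stop("q must lie in [0.1, 0.9]")
  keep <- !is.na(scores)
  if (!all(keep)) {
    warning("EEG(s) with missing epoch scores excluded from aggregation")
    scores <- scores[keep]; eeg_id <- eeg_id[keep]
  }
  vapply(split(scores, eeg_id), stats::quantile, numeric(1), probs = q, names = FALSE)
}

# Impute + standardize + select + fit on a training matrix; returns a closure
# scoring raw (unimputed, unstandardized) epoch rows of held-out data.
.fit_config <- function(x_train, y_train, algorithm, hp, select_c,
                        class_weights, seed) {
  imp <- impute_missing(x_train)
  scaler <- .fit_scaler(imp$data)
  xs <- .apply_scaler(scaler, imp$data)
  keep <- feature_select_l1svm(xs, y_train, C = select_c)
  score_fn <- .fit_model(algorithm, hp, xs[, keep, drop = FALSE],
                         y_train, class_weights, seed)
  function(newx) {
    xn <- .apply_scaler(scaler, impute_apply(imp, newx))[, keep, drop = FALSE]
    score_fn(xn)
  }
}

# Inner grouped CV: pick (select_c, hyperparameters) maximizing the pooled
# per-EEG aggregated AUC.
.inner_select <- function(fm, rows, spec, inner_k, q, seed) {
  configs <- merge(data.frame(select_c = spec$select_c), spec$grid, by = NULL)
  if (nrow(configs) == 1L) return(configs[1, , drop = FALSE])
  k <- min(inner_k, length(unique(fm$patient_id[rows])))
  folds <- grouped_folds(fm$patient_id[rows], k, seed)
  best <- NULL; best_auc <- -Inf
  for (ci in seq_len(nrow(configs))) {
    hp <- configs[ci, , drop = FALSE]
    sc <- rep(NA_real_, length(rows))
    ok <- TRUE
    for (f in seq_len(k)) {
      tr <- rows[folds != f]; va <- rows[folds == f]
      if (length(unique(fm$y[tr])) < 2L) { ok <- FALSE; break }
      fitted <- tryCatch(
        .fit_config(fm$x[tr, , drop = FALSE], fm$y[tr], spec$algorithm, hp,
                    hp$select_c, spec$class_weights, seed),
        error = function(e) NULL)
      if (is.null(fitted)) { ok <- FALSE; break }
      sc[match(va, rows)] <- fitted(fm$x[va, , drop = FALSE])
    }
    if (!ok || anyNA(sc)) next
    agg <- aggregate_epoch_predictions(sc, fm$eeg_id[rows], q)
    ylab <- vapply(split(fm$y[rows], fm$eeg_id[rows]), `[`, logical(1), 1)
    a <- tryCatch(auc_mw(agg, ylab[names(agg)]), error = function(e) NA_real_)
    if (is.finite(a) && a > best_auc) { best_auc <- a; best <- hp }
  }
  if (is.null(best)) configs[1, , drop = FALSE] else best
}

#' Nested cross-validated evaluation of a classifier
#'
#' Outer folds are patient-grouped; within each outer-training set an inner
#' grouped CV selects the L1-SVM feature-selection strength and the model
#' hyperparameters by pooled per-EEG aggregated AUC. The selected
#' configuration is refit on the outer-training set, outer-test epochs are
#' scored, aggregated per EEG at quantile `q`, and the per-fold AUCs are
#' combined with the LeDell influence-function CI.
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()].
#' @param spec A [model_spec()].
#' @param inner_k,outer_k Inner/outer fold counts (defaults 10 and 5).
#' @param q Aggregation quantile (default 0.5, the median).
#' @param seed Integer seed.
#' @param folds Optional externally supplied outer-fold assignment per row
#'   (used to keep CV splits identical across runs).
#' @return List of class `eeg_cv_result`: `result` (an `eeg_eval_result`),
#'   `predictions` (per-EEG data.frame with fold, label, aggregated score),
#'   `epoch_scores`, `fold_manifest` (patient -> fold).
#' @export
nested_cv_evaluate <- function(fm, spec, inner_k = 10L, outer_k = 5L, q = 0.5,
                               seed = 1L, folds = NULL) {
  n <- nrow(fm$x)
  if (is.null(folds)) {
    for (attempt in 0:9) {
      folds <- grouped_folds(fm$patient_id, outer_k, .child_seed(seed, attempt))
      one_class <- vapply(seq_len(outer_k), function(f) {
        length(unique(fm$y[folds == f])) < 2L
      }, logical(1))
      if (!any(one_class)) break
      if (attempt == 9L) stop("could not build outer folds with both classes in every fold")
    }
  }
  epoch_scores <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    tr <- which(folds != f); te <- which(folds == f)
    hp <- .inner_select(fm, tr, spec, inner_k, q, .child_seed(seed, 100 + f))
    fitted <- .fit_config(fm$x[tr, , drop = FALSE], fm$y[tr], spec$algorithm,
                          hp, hp$select_c, spec$class_weights,
                          .child_seed(seed, 200 + f))
    epoch_scores[te] <- fitted(fm$x[te, , drop = FALSE])
  }
  eeg_fold <- vapply(split(folds, fm$eeg_id), `[`, numeric(1), 1)
  eeg_y <- vapply(split(fm$y, fm$eeg_id), `[`, logical(1), 1)
  agg <- aggregate_epoch_predictions(epoch_scores, fm$eeg_id, q)
  ids <- names(agg)
  res <- auc_ci_ledell(agg, eeg_y[ids], eeg_fold[ids])
  manifest <- unique(data.frame(patient_id = fm$patient_id, fold = folds,
                                stringsAsFactors = FALSE))
  structure(list(result = res,
                 predictions = data.frame(eeg_id = ids, fold = eeg_fold[ids],
                                          label = eeg_y[ids], score = unname(agg),
                                          stringsAsFactors = FALSE),
                 epoch_scores = epoch_scores, folds = folds,
                 fold_manifest = manifest, q = q, spec = spec),
            class = "eeg_cv_result")
}

#' Two-step clinical-flag classifier
#'
#' EEGs with a positive clinical flag (e.g. IEDs present) receive score 1.0;
#' the remaining EEGs keep the model score.
#'
#' @param flag Logical per EEG.
#' @param model_scores Numeric per EEG.
#' @return Combined per-EEG scores.
#' @export
two_step_classify <- function(flag, model_scores) {
  if (length(flag) != length(model_scores)) stop("flags and scores must be aligned")
  ifelse(as.logical(flag), 1.0, model_scores)
}

#' Train/holdout evaluation with inner CV model selection
#'
#' Requires disjoint patient sets. An inner grouped CV (default 10-fold) on
#' the training split selects the feature-selection strength and
#' hyperparameters; the final model is fit on all training rows, test epochs
#' are scored and aggregated per EEG, and the AUC is reported with the DeLong
#' CI plus binary metrics at threshold 0.5.
#'
#' @param fm_train,fm_test `feature_matrix` objects with disjoint patients.
#' @param spec A [model_spec()].
#' @param q Aggregation quantile.
#' @param inner_k Inner fold count (default 10).
#' @param seed Integer seed.
#' @return List: `result` (DeLong `eeg_eval_result`), `metrics` (from
#'   [binary_metrics()]), `predictions` (per-EEG), `config` (chosen
#'   hyperparameters).
#' @export
holdout_evaluate <- function(fm_train, fm_test, spec, q = 0.5, inner_k = 10L,
                             seed = 1L) {
  overlap <- intersect(unique(fm_train$patient_id), unique(fm_test$patient_id))
  if (length(overlap)) {
    stop("patient(s) present in both splits: ", paste(overlap, collapse = ", "))
  }
  hp <- .inner_select(fm_train, seq_len(nrow(fm_train$x)), spec, inner_k, q,
                      .child_seed(seed, 1))
  fitted <- .fit_config(fm_train$x, fm_train$y, spec$algorithm,
                        hp, hp$select_c, spec$class_weights, .child_seed(seed, 2))
  sc_test <- fitted(fm_test$x)
  agg <- aggregate_epoch_predictions(sc_test, fm_test$eeg_id, q)
  y <- vapply(split(fm_test$y, fm_test$eeg_id), `[`, logical(1), 1)[names(agg)]
  res <- auc_ci_delong(agg, y)
  metrics <- binary_metrics(agg, y)
  list(result = res, metrics = metrics,
       predictions = data.frame(eeg_id = names(agg), label = y, score = unname(agg),
                                stringsAsFactors = FALSE),
       config = hp)
}
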