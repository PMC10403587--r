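# End-to-end pipeline orchestration, configuration, logging, tabular I/O

#' Write/read a tab-separated table
#'
#' Plain TSV with a header row; the on-disk interchange format for cohort
#' tables, marker tensors and predictions.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `path` / the data frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing input file: %s", path))
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.log_stage <- function(log, stage, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(...))
  message(line)
  if (!is.null(log)) cat(line, "\n", file = log, append = TRUE)
  invisible(line)
}

#' Pipeline run configuration
#'
#' Bundles the simulation, preprocessing, marker and evaluation parameters
#' with their defaults; every stochastic step of [run_pipeline()] is seeded
#' from `seed`.
#'
#' @param sim A [sim_config()].
#' @param out_dir Output directory for stage artifacts.
#' @param hp_cutoff_hz,notch_hz,epoch_len_s,reject_k_folds Preprocessing
#'   parameters.
#' @param wspec,scheme,params Marker parameters ([wavelet_spec()],
#'   [band_scheme()], [entropy_params()]).
#' @param markers Marker subset to extract (default all).
#' @param models Character vector of [model_spec()] algorithms to evaluate.
#' @param inner_k,outer_k,q Evaluation parameters.
#' @param variant `"plain"`, `"age-interaction"`, `"two-step-ied"` or
#'   `"two-step-lesion"`.
#' @param subgroups Subgroup variables for the post-hoc stage.
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), out_dir = tempfile("eegprog_run_"),
                       hp_cutoff_hz = 0.75, notch_hz = 60, epoch_len_s = 10,
                       reject_k_folds = 5L,
                       wspec = wavelet_spec(), scheme = band_scheme(),
                       params = entropy_params(), markers = marker_names(),
                       models = "glm_logistic_l1l2",
                       inner_k = 10L, outer_k = 5L, q = 0.5,
                       variant = "plain",
                       subgroups = c("age_group", "sex", "focal_lesion", "ied_status"),
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Stages, in order: simulate (cohort table + EDF recordings), preprocess
#' (filter, average reference, epoch, fit rejection thresholds, repair),
#' extract (marker tensor), evaluate (patient-grouped nested CV per model,
#' optionally with the age-interaction or two-step variants), posthoc
#' (subgroup AUCs, dichotomized-risk survival). Artifacts are written under
#' `config$out_dir`; each stage logs counts in/out, and any failure aborts
#' with the stage name.
#'
#' @param config A [run_config()].
#' @return List with `cohort`, `tensor`, `evaluation` (per model), `posthoc`,
#'   and `paths`; also written to disk as TSV/JSON.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(config$out_dir, "pipeline.log")
  stage <- "simulate"
  result <- tryCatch({
    sim <- simulate_cohort(config$sim)
    cohort <- sim$cohort
    edf_dir <- file.path(config$out_dir, "edf")
    dir.create(edf_dir, showWarnings = FALSE)
    for (id in names(sim$recordings)) {
      write_edf(sim$recordings[[id]], file.path(edf_dir, paste0(id, ".edf")))
    }
    write_tsv(cohort, file.path(config$out_dir, "cohort.tsv"))
    .log_stage(log, stage, "n_patients=%d n_recordings=%d seed=%d",
               nrow(cohort), length(sim$recordings), config$sim$seed)

    stage <- "preprocess"
    epochs <- list()
    for (id in cohort$eeg_id) {
      rec <- read_edf(file.path(edf_dir, paste0(id, ".edf")),
                      eeg_id = id,
                      patient_id = cohort$patient_id[cohort$eeg_id == id])
      rec <- to_average_reference(
        filter_recording(rec, config$hp_cutoff_hz, config$notch_hz))
      eps <- extract_epochs(rec, config$epoch_len_s)
      if (length(eps) >= config$reject_k_folds) {
        thr <- fit_rejection_thresholds(eps, config$reject_k_folds,
                                        seed = .child_seed(config$seed, 11))
        eps <- repair_epochs(eps, thr)
      }
      epochs <- c(epochs, eps)
    }
    .log_stage(log, stage, "n_epochs=%d", length(epochs))

    stage <- "extract"
    tensor <- extract_marker_tensor(epochs, config$sim$sampling_rate,
                                    config$wspec, config$scheme, config$params,
                                    markers = config$markers)
    write_tsv(tensor, file.path(config$out_dir, "marker_tensor.tsv"))
    .log_stage(log, stage, "n_values=%d n_missing=%d", nrow(tensor), sum(tensor$missing))

    stage <- "evaluate"
    fm <- build_feature_matrix(tensor, cohort)
    if (config$variant == "age-interaction") {
      age <- cohort$age[match(fm$eeg_id, cohort$eeg_id)]
      fm <- add_age_interactions(fm, age)
    }
    models <- config$models
    if (is.character(models)) {
      models <- stats::setNames(lapply(models, model_spec), models)
    }
    evaluation <- list()
    for (alg in names(models)) {
      cv <- nested_cv_evaluate(fm, models[[alg]], inner_k = config$inner_k,
                               outer_k = config$outer_k, q = config$q,
                               seed = .child_seed(config$seed, 21))
      if (startsWith(config$variant, "two-step")) {
        flag_col <- if (config$variant == "two-step-ied") {
          cohort$ied_status[match(cv$predictions$eeg_id, cohort$eeg_id)] == "present"
        } else {
          cohort$focal_lesion[match(cv$predictions$eeg_id, cohort$eeg_id)]
        }
        cv$predictions$score <- two_step_classify(flag_col, cv$predictions$score)
        cv$result <- auc_ci_ledell(cv$predictions$score, cv$predictions$label,
                                   cv$predictions$fold)
      }
      evaluation[[alg]] <- cv
      write_tsv(cv$predictions,
                file.path(config$out_dir, sprintf("predictions_%s.tsv", alg)))
      .log_stage(log, stage, "model=%s auc=%.3f ci=[%.3f, %.3f]",
                 alg, cv$result$auc, cv$result$ci_low, cv$result$ci_high)
    }

    stage <- "posthoc"
    best <- evaluation[[1]]
    sub <- do.call(rbind, lapply(config$subgroups, function(v) {
      subgroup_auc(best$predictions, cohort, v)
    }))
    mm <- match(best$predictions$eeg_id, cohort$eeg_id)
    risk_group <- dichotomize_risk(best$predictions$score)
    cox <- tryCatch(
      fit_cox(cohort$time_to_event_weeks[mm], cohort$event_observed[mm],
              data.frame(risk_group = risk_group, age = cohort$age[mm],
                         sex = cohort$sex[mm], asm_count = cohort$asm_count[mm])),
      error = function(e) { .log_stage(log, stage, "cox skipped: %s", conditionMessage(e)); NULL })
    km <- kaplan_meier(cohort$time_to_event_weeks[mm], cohort$event_observed[mm],
                       risk_group)
    posthoc <- list(subgroups = sub, cox = cox, km = km)
    write_tsv(sub, file.path(config$out_dir, "subgroup_auc.tsv"))
    write_tsv(km$curves, file.path(config$out_dir, "km_curves.tsv"))
    .log_stage(log, stage, "subgroup_rows=%d km_groups=%d",
               nrow(sub), length(km$surv_52w))

    summary <- list(
      seed = config$seed,
      auc = lapply(evaluation, function(cv) {
        list(auc = cv$result$auc, ci_low = cv$result$ci_low,
             ci_high = cv$result$ci_high, p_vs_chance = cv$result$p_vs_chance)
      }),
      surv_52w = as.list(km$surv_52w))
    jsonlite::write_json(summary, file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
    list(cohort = cohort, tensor = tensor, evaluation = evaluation,
         posthoc = posthoc,
         paths = list(out_dir = config$out_dir,
                      results = file.path(config$out_dir, "results.json")))
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  result
}
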