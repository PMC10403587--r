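# Epoch-level feature matrices

#' Build the epoch-level feature matrix from a marker tensor
#'
#' Rows are epochs, columns the flattened (channel x marker x band-or-level)
#' features; per-row keys (`eeg_id`, `patient_id`) and the outcome label are
#' carried alongside. Missing marker values stay `NA` (impute downstream,
#' inside each training split).
#'
#' @param tensor Long-format tensor from [extract_marker_tensor()].
#' @param cohort Cohort table (needs `eeg_id`, `patient_id`, and the outcome
#'   column).
#' @param outcome Name of the outcome column (default
#'   `"outcome_recurrence_1y"`).
#' @param markers Optional subset of [marker_names()] to keep.
#' @return List of class `feature_matrix`: `x` (epochs x features), `eeg_id`,
#'   `patient_id`, `y` (logical), `marker` (marker family per column).
#' @export
build_feature_matrix <- function(tensor, cohort, outcome = "outcome_recurrence_1y",
                                 markers = NULL) {
  if (!is.null(markers)) tensor <- tensor[tensor$marker %in% markers, , drop = FALSE]
  feat <- paste(tensor$channel, tensor$marker, tensor$sub_index, sep = ".")
  key <- paste(tensor$eeg_id, tensor$epoch_index, sep = "#")
  rows <- unique(key); cols <- unique(feat)
  x <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  x[cbind(match(key, rows), match(feat, cols))] <- tensor$value
  eeg_id <- sub("#.*$", "", rows)
  m <- match(eeg_id, cohort$eeg_id)
  if (anyNA(m)) stop("tensor contains eeg_ids absent from the cohort table")
  structure(list(x = x, eeg_id = eeg_id, patient_id = cohort$patient_id[m],
                 y = as.logical(cohort[[outcome]][m]),
                 marker = sub("^[^.]+\\.([^.]+)\\..*$", "\\1", cols)),
            class = "feature_matrix")
}

.subset_fm <- function(fm, rows = NULL, cols = NULL) {
  if (!is.null(rows)) {
    fm$x <- fm$x[rows, , drop = FALSE]
    fm$eeg_id <- fm$eeg_id[rows]; fm$patient_id <- fm$patient_id[rows]
    fm$y <- fm$y[rows]
  }
  if (!is.null(cols)) {
    fm$x <- fm$x[, cols, drop = FALSE]
    fm$marker <- fm$marker[cols]
  }
  fm
}

#' Add age and age-by-feature interaction columns
#'
#' Age is standardized with the training mean/SD (pass `train_stats` when
#' transforming held-out rows); output columns are the original features, the
#' standardized age, and age-by-feature products, i.e. `2p + 1` columns.
#'
#' @param fm A `feature_matrix`.
#' @param age_years Numeric age per row of `fm$x`.
#' @param train_stats Optional `c(mean, sd)` from the training split.
#' @return The augmented `feature_matrix`, with attribute `"age_stats"`.
#' @export
add_age_interactions <- function(fm, age_years, train_stats = NULL) {
  if (length(age_years) != nrow(fm$x)) stop("age must be given for every row")
  if (anyNA(age_years)) {
    stop("missing age for eeg_id(s): ",
         paste(unique(fm$eeg_id[is.na(age_years)]), collapse = ", "))
  }
  if (is.null(train_stats)) train_stats <- c(mean(age_years), stats::sd(age_years))
  a <- (age_years - train_stats[1]) / train_stats[2]
  inter <- fm$x * a
  colnames(inter) <- paste0("ageX.", colnames(fm$x))
  fm$x <- cbind(fm$x, age_scaled = a, inter)
  fm$marker <- c(fm$marker, "age", paste0("ageX", fm$marker))
  attr(fm, "age_stats") <- train_stats
  fm
}
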