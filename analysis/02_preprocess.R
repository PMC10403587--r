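#!/usr/bin/env Rscript
# Preprocess the simulated cohort: filter, average-reference, cut 10-s epochs
# at annotated time points, fit per-channel rejection thresholds, repair.
# Reads results/cohort/, writes results/epochs/.

library(eegprog)

cohort <- read_tsv(file.path("results", "cohort", "cohort.tsv"))
edf_dir <- file.path("results", "cohort", "edf")
out_dir <- file.path("results", "epochs")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

n_in <- 0L; n_out <- 0L; n_interp <- 0L
all_epochs <- list()
for (id in cohort$eeg_id) {
  rec <- read_edf(file.path(edf_dir, paste0(id, ".edf")), eeg_id = id,
                  patient_id = cohort$patient_id[cohort$eeg_id == id])
  rec <- to_average_reference(filter_recording(rec, hp_cutoff_hz = 0.75, notch_hz = 60))
  eps <- extract_epochs(rec, epoch_len_s = 10)
  n_in <- n_in + length(eps)
  thr <- fit_rejection_thresholds(eps, k_folds = 5)
  eps <- repair_epochs(eps, thr, max_bad_fraction = 0.3)
  n_out <- n_out + length(eps)
  n_interp <- n_interp + sum(vapply(eps, function(e) length(e$interpolated_channels), 1L))
  all_epochs <- c(all_epochs, eps)
}

saveRDS(all_epochs, file.path(out_dir, "epochs.rds"))  # local intermediate
cat(sprintf("epochs in: %d, kept after repair: %d, channel interpolations: %d\n",
            n_in, n_out, n_interp))
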