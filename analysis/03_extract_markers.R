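#!/usr/bin/env Rscript
# Extract the ten computational markers per epoch/channel/band-or-level.
# Reads results/epochs/, writes results/markers/marker_tensor.tsv.

library(eegprog)

epochs <- readRDS(file.path("results", "epochs", "epochs.rds"))
out_dir <- file.path("results", "markers")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

tensor <- extract_marker_tensor(epochs, fs = 200,
                                wspec = wavelet_spec(),
                                scheme = band_scheme(),
                                params = entropy_params())
write_tsv(tensor, file.path(out_dir, "marker_tensor.tsv"))

cat(sprintf("marker tensor: %d values (%d epochs x %d channels), %.1f%% missing\n",
            nrow(tensor), length(epochs), length(unique(tensor$channel)),
            100 * mean(tensor$missing)))
by_marker <- tapply(tensor$missing, tensor$marker, mean)
cat("missingness by marker (%):\n")
print(round(100 * by_marker, 1))
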