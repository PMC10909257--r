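#!/usr/bin/env Rscript
# Stage 4 -- linear feed-forward network (Levenberg-Marquardt).
#
# Trains the 81 -> 5 -> 4 purelin-purelin network on a seeded 70/15/15
# train/validation/test split of the calibration mixtures, with validation
# early stopping, then predicts the hold-out and assay samples.

suppressPackageStartupMessages(library(quatspec))

design <- read_design_csv("results/run/design.csv")
spectra <- read_spectra_csv("results/run/spectra.csv")
assay_design <- read_design_csv("results/run/assay_design.csv")
assay_spectra <- read_spectra_csv("results/run/assay_spectra.csv")

win <- select_window(spectra, 220, 300)
is_cal <- design$role == "calibration"
cal <- design_subset(design, "calibration")
val <- design_subset(design, "validation")
cal_spec <- quatspec:::new_spectra_set(win$wavelengths_nm,
  win$absorbance[is_cal, ], design$sample_ids[is_cal])
val_spec <- quatspec:::new_spectra_set(win$wavelengths_nm,
  win$absorbance[!is_cal, ], design$sample_ids[!is_cal])
assay_spec <- select_window(assay_spectra, 220, 300)

m <- train_ann(cal_spec, cal$nominal, ann_config(n_hidden = 5, seed = 3))
cat(sprintf("Trained %d epochs; best validation MSE %.3g at epoch %d\n",
            nrow(m$history), min(m$history[, "validation"]), m$best_epoch))
print(training_diagnostics(m), digits = 4)

hist_df <- data.frame(epoch = seq_len(nrow(m$history)), m$history)
write.csv(hist_df, "results/run/ann_history.csv", row.names = FALSE)

for (set in c("validation", "assay")) {
  sp <- if (set == "validation") val_spec else assay_spec
  nom <- if (set == "validation") val$nominal else assay_design$nominal
  pred <- predict(m, sp)
  rec <- recovery_stats(pred, nom)
  cat(sprintf("ANN %-10s mean recovery %%: %s | SD: %s\n", set,
              paste(sprintf("%6.2f", rec$mean), collapse = " "),
              paste(sprintf("%4.2f", rec$sd), collapse = " ")))
  write.csv(data.frame(sample_id = rownames(pred), pred, check.names = FALSE),
            sprintf("results/run/pred_ann_%s.csv", set), row.names = FALSE)
}
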