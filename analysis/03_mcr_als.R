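#!/usr/bin/env Rscript
# Stage 3 -- multivariate curve resolution (MCR-ALS).
#
# Fits the bilinear model D ~ C S' on the windowed calibration block under
# non-negativity (both profiles) and the correlation constraint (anchoring
# concentrations to the reference values), reports %LOF / R2, compares the
# resolved spectra with the true generating bands, and predicts validation
# and assay samples by one-by-one matrix augmentation.

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

m <- fit_mcr_als(cal_spec, cal$nominal)
cat(sprintf("Converged in %d iterations: %%LOF = %.4f, R2 = %.4f%%\n",
            m$n_iter, m$lof, m$r2))

# resolved vs generating spectra (component matching by max correlation)
pure <- default_pure_spectra()
S_true <- t(pure$unit_absorptivity[, colnames(cal_spec$absorbance)])
perm <- match_components(m$S, S_true)
cors <- diag(cor(S_true, m$S[, perm]))
cat("Correlation of resolved spectra with the generating bands:",
    paste(sprintf("%s %.4f", analytes(), cors), collapse = ", "), "\n")

write.csv(data.frame(wavelength_nm = win$wavelengths_nm,
                     m$S[, perm] |> `colnames<-`(analytes())),
          "results/run/mcr_resolved_spectra.csv", row.names = FALSE)
write.csv(data.frame(iteration = seq_along(m$lof_trace),
                     lof_percent = m$lof_trace),
          "results/run/mcr_lof_trace.csv", row.names = FALSE)

for (set in c("validation", "assay")) {
  sp <- if (set == "validation") val_spec else assay_spec
  nom <- if (set == "validation") val$nominal else assay_design$nominal
  pred <- predict_mcr(m, sp, cal_spec, cal$nominal)
  rec <- recovery_stats(pred, nom)
  cat(sprintf("MCR %-10s mean recovery %%: %s | SD: %s\n", set,
              paste(sprintf("%6.2f", rec$mean), collapse = " "),
              paste(sprintf("%4.2f", rec$sd), collapse = " ")))
  write.csv(data.frame(sample_id = rownames(pred), pred, check.names = FALSE),
            sprintf("results/run/pred_mcr_%s.csv", set), row.names = FALSE)
}
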