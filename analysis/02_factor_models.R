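#!/usr/bin/env Rscript
# Stage 2 -- PCR and PLS calibration.
#
# Windows the simulated spectra to 220-300 nm (81 points), selects the
# latent-variable count by leave-one-out cross-validation, fits both factor
# models on the 25 calibration mixtures and predicts the 5-sample validation
# hold-out and the capsule assay.

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

cv <- list(pcr = loo_cross_validate(cal_spec, cal$nominal, 8, "pcr"),
           pls = loo_cross_validate(cal_spec, cal$nominal, 8, "pls"))
cat("Leave-one-out RMSECV selects", cv$pcr$selected_lv, "LVs (PCR) and",
    cv$pls$selected_lv, "LVs (PLS)\n")
write.csv(data.frame(lv = cv$pcr$lv_counts,
                     pcr_mean_rmsecv = cv$pcr$mean_rmsecv,
                     pls_mean_rmsecv = cv$pls$mean_rmsecv),
          "results/run/cv_curve.csv", row.names = FALSE)

for (eng in c("pcr", "pls")) {
  fit_fun <- if (eng == "pcr") fit_pcr else fit_pls
  m <- fit_fun(cal_spec, cal$nominal, cv[[eng]]$selected_lv)
  write_factor_model(m, sprintf("results/run/model_%s.json", eng))
  for (set in c("validation", "assay")) {
    sp <- if (set == "validation") val_spec else assay_spec
    nom <- if (set == "validation") val$nominal else assay_design$nominal
    pred <- predict(m, sp)
    rec <- recovery_stats(pred, nom)
    cat(sprintf("%s %-10s mean recovery %%: %s | SD: %s\n", toupper(eng), set,
                paste(sprintf("%6.2f", rec$mean), collapse = " "),
                paste(sprintf("%4.2f", rec$sd), collapse = " ")))
    write.csv(data.frame(sample_id = rownames(pred), pred,
                         check.names = FALSE),
              sprintf("results/run/pred_%s_%s.csv", eng, set),
              row.names = FALSE)
  }
}
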