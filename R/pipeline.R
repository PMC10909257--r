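# End-to-end workflow: simulate -> window -> calibrate (4 engines) ->
# predict -> diagnose -> greenness, as one reproducible run.

#' Run the full chemometric workflow
#'
#' Simulates the calibration/validation spectra from the packaged design and
#' band table, windows them, fits all requested engines, predicts the
#' validation set and the simulated capsule assay, and computes diagnostics
#' and greenness reports. With `out_dir` set, every table is written (CSV /
#' JSON) together with a manifest of seeds and configuration; runs are
#' deterministic for fixed seeds.
#'
#' @param noise_sd absorbance noise sd in AU (default 0.002).
#' @param seed master integer seed; stage seeds derive from it.
#' @param window wavelength window in nm (default `c(220, 300)`).
#' @param engines subset of `"pcr"`, `"pls"`, `"mcr"`, `"ann"`.
#' @param n_lv latent variables for PCR/PLS, or `"auto"` for leave-one-out
#'   selection (default 4, the known rank of this system).
#' @param design_source `"table1"` (default) or `"generated"`.
#' @param out_dir optional run directory.
#' @return Invisible list with the design, spectra, fitted models, validation
#'   predictions, recovery/diagnostic tables and greenness reports.
#' @export
run_pipeline <- function(noise_sd = 0.002, seed = 1, window = c(220, 300),
                         engines = c("pcr", "pls", "mcr", "ann"),
                         n_lv = 4, design_source = "table1",
                         out_dir = NULL) {
  engines <- match.arg(engines, several.ok = TRUE)
  seed <- as.integer(seed)
  design <- generate_design(source = design_source)
  pure <- default_pure_spectra()
  spectra <- simulate_spectra(design, pure, noise_sd = noise_sd, seed = seed)
  assay <- simulate_dosage_form(pure, noise_sd = noise_sd, seed = seed + 1L)

  win <- select_window(spectra, window[1], window[2])
  cal <- design_subset(design, "calibration")
  val <- design_subset(design, "validation")
  is_cal <- design$role == "calibration"
  cal_spec <- new_spectra_set(win$wavelengths_nm,
                              win$absorbance[is_cal, , drop = FALSE],
                              design$sample_ids[is_cal])
  val_spec <- new_spectra_set(win$wavelengths_nm,
                              win$absorbance[!is_cal, , drop = FALSE],
                              design$sample_ids[!is_cal])
  assay_spec <- select_window(assay$spectra, window[1], window[2])

  if (identical(n_lv, "auto")) {
    cv <- loo_cross_validate(cal_spec, cal$nominal, max_lv = 8, method = "pcr")
    n_lv <- cv$selected_lv
  }

  models <- list(); val_pred <- list(); assay_pred <- list()
  for (eng in engines) {
    if (eng == "pcr") {
      m <- fit_pcr(cal_spec, cal$nominal, n_lv)
      val_pred[[eng]] <- predict(m, val_spec)
      assay_pred[[eng]] <- predict(m, assay_spec)
    } else if (eng == "pls") {
      m <- fit_pls(cal_spec, cal$nominal, n_lv)
      val_pred[[eng]] <- predict(m, val_spec)
      assay_pred[[eng]] <- predict(m, assay_spec)
    } else if (eng == "mcr") {
      m <- fit_mcr_als(cal_spec, cal$nominal)
      val_pred[[eng]] <- predict_mcr(m, val_spec, cal_spec, cal$nominal)
      assay_pred[[eng]] <- predict_mcr(m, assay_spec, cal_spec, cal$nominal)
    } else {
      m <- train_ann(cal_spec, cal$nominal, ann_config(seed = seed + 2L))
      val_pred[[eng]] <- predict(m, val_spec)
      assay_pred[[eng]] <- predict(m, assay_spec)
    }
    models[[eng]] <- m
  }

  recovery <- lapply(val_pred, recovery_stats, nominal = val$nominal)
  assay_recovery <- lapply(assay_pred, recovery_stats,
                           nominal = assay$design$nominal)
  fom <- lapply(val_pred, function(P) {
    do.call(rbind, lapply(colnames(P), function(a) {
      cbind(analyte = a,
            regression_fom(P[, a], val$nominal[, a], seed = seed))
    }))
  })
  greenness <- list(eco_proposed = eco_scale(eco_items_proposed()),
                    eco_reported = eco_scale(eco_items_reported()),
                    agree = agree_score(agree_scores_synthetic()))

  result <- list(design = design, pure = pure, spectra = spectra,
                 window = window, n_lv = n_lv, models = models,
                 val_nominal = val$nominal, val_pred = val_pred,
                 assay = assay, assay_pred = assay_pred,
                 recovery = recovery, assay_recovery = assay_recovery,
                 fom = fom, greenness = greenness,
                 seed = seed, noise_sd = noise_sd)

  if (!is.null(out_dir)) write_run_dir(result, out_dir)
  invisible(result)
}

write_run_dir <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_design_csv(result$design, file.path(out_dir, "design.csv"))
  write_spectra_csv(result$spectra, file.path(out_dir, "spectra.csv"))
  for (eng in names(result$val_pred)) {
    utils::write.csv(data.frame(sample_id = rownames(result$val_pred[[eng]]),
                                result$val_pred[[eng]], check.names = FALSE),
                     file.path(out_dir, paste0("predictions_", eng, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  diag <- list(
    recovery = lapply(result$recovery, function(r)
      list(mean = as.list(r$mean), sd = as.list(r$sd))),
    assay_recovery = lapply(result$assay_recovery, function(r)
      list(mean = as.list(r$mean), sd = as.list(r$sd))),
    fom = lapply(result$fom, function(f) f),
    greenness = list(eco_proposed = result$greenness$eco_proposed$score,
                     eco_reported = result$greenness$eco_reported$score,
                     agree = result$greenness$agree$overall))
  jsonlite::write_json(diag, file.path(out_dir, "diagnostics.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  manifest <- list(package = "quatspec",
                   version = as.character(utils::packageVersion("quatspec")),
                   seed = result$seed, noise_sd = result$noise_sd,
                   window = result$window, n_lv = result$n_lv,
                   engines = names(result$models))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}

#' Cross-engine comparison report
#'
#' Tabulates mean recovery, recovery SD, RMSEP, Durbin-Watson and EJCR
#' membership per engine and analyte, plus pooled-t / variance-ratio F of
#' each engine's validation recoveries against a designated reference engine.
#'
#' @param result a [run_pipeline()] result.
#' @param reference engine name used as the comparison reference (default the
#'   first fitted engine).
#' @return Data frame, one row per engine x analyte.
#' @export
compare_report <- function(result, reference = names(result$val_pred)[1]) {
  qs_check(reference %in% names(result$val_pred),
           "reference engine not present in the run")
  rows <- list()
  for (eng in names(result$val_pred)) {
    P <- result$val_pred[[eng]]
    for (a in colnames(P)) {
      rec <- result$recovery[[eng]]
      ref_rec <- result$recovery[[reference]]$recovery[, a]
      cmp <- compare_methods(rec$recovery[, a], ref_rec)
      ej <- ejcr(P[, a], result$val_nominal[, a])
      fom_row <- result$fom[[eng]][result$fom[[eng]]$analyte == a, ]
      rows[[length(rows) + 1]] <- data.frame(
        engine = eng, analyte = a,
        mean_recovery = unname(rec$mean[a]), sd_recovery = unname(rec$sd[a]),
        rmsep = fom_row$rmse, dw = fom_row$dw,
        ejcr_contains_ideal = ej$contains_ideal,
        t_vs_ref = cmp$t, F_vs_ref = cmp$F)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
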