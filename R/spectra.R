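# Synthetic UV-Vis spectra: Beer-Lambert mixing of Gaussian band shapes.

new_spectra_set <- function(wavelengths_nm, absorbance, sample_ids) {
  steps <- diff(wavelengths_nm)
  if (length(steps) > 0) {
    qs_check(all(steps > 0), "wavelength grid must be ascending")
    qs_check(max(steps) - min(steps) < 1e-9, "wavelength grid must be uniform")
  }
  qs_check(all(is.finite(absorbance)), "absorbance must be finite")
  dimnames(absorbance) <- list(sample_ids, format_nm(wavelengths_nm))
  structure(list(wavelengths_nm = wavelengths_nm, absorbance = absorbance,
                 sample_ids = sample_ids),
            class = "spectra_set")
}

format_nm <- function(x) sprintf("%.1f", x)

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " samples x ",
      length(x$wavelengths_nm), " wavelengths (",
      format_nm(min(x$wavelengths_nm)), "-", format_nm(max(x$wavelengths_nm)),
      " nm)\n", sep = "")
  invisible(x)
}

#' Default pure-component spectra
#'
#' Unit-concentration absorptivity spectra (AU per ug/mL at 1 cm path) for the
#' four analytes, built as sums of Gaussian bands over 200-400 nm. The band
#' table ships as a plain-text data file and is deliberately synthetic: it
#' reproduces the qualitative situation of the real mixture -- four strongly
#' overlapped absorbers in the 220-300 nm window -- not any measured
#' absorptivities.
#'
#' @param grid_step_nm wavelength step; must divide the 200 nm span (default 1).
#' @param bands data frame with columns `analyte`, `center_nm`, `width_nm`,
#'   `height`; defaults to the packaged band table.
#' @return A `pure_spectra` object: `wavelengths_nm` and a 4 x n_wavelengths
#'   `unit_absorptivity` matrix in canonical analyte order.
#' @export
default_pure_spectra <- function(grid_step_nm = 1, bands = NULL) {
  span <- 400 - 200
  qs_check(grid_step_nm > 0 && abs(span / grid_step_nm -
             round(span / grid_step_nm)) < 1e-9,
           "grid_step_nm must divide the 200-400 nm span")
  if (is.null(bands))
    bands <- utils::read.csv(qs_extdata("pure_bands.csv"),
                             stringsAsFactors = FALSE)
  qs_check(all(bands$width_nm > 0) && all(bands$height > 0),
           "band widths and heights must be positive")
  qs_check(all(bands$center_nm >= 200 & bands$center_nm <= 400),
           "band centers must lie within 200-400 nm")
  wl <- seq(200, 400, by = grid_step_nm)
  A <- matrix(0, 4, length(wl), dimnames = list(analytes(), format_nm(wl)))
  for (i in seq_len(nrow(bands))) {
    a <- bands$analyte[i]
    qs_check(a %in% analytes(), paste("unknown analyte in band table:", a))
    A[a, ] <- A[a, ] + bands$height[i] *
      exp(-0.5 * ((wl - bands$center_nm[i]) / bands$width_nm[i])^2)
  }
  structure(list(wavelengths_nm = wl, unit_absorptivity = A),
            class = "pure_spectra")
}

#' @export
print.pure_spectra <- function(x, ...) {
  cat("<pure_spectra> 4 analytes x ", length(x$wavelengths_nm),
      " wavelengths\n", sep = "")
  invisible(x)
}

#' Simulate mixture spectra by Beer-Lambert additivity
#'
#' Absorbance = concentrations x unit absorptivity, plus i.i.d. homoscedastic
#' Gaussian photometric noise. Noiseless output is exactly bilinear (rank at
#' most 4).
#'
#' @param design a `design_matrix` (its nominal block gives concentrations).
#' @param pure a `pure_spectra` object.
#' @param noise_sd absorbance noise standard deviation in AU (default 0.002).
#' @param seed integer seed for the noise draw.
#' @return A `spectra_set` row-aligned with `design`.
#' @export
simulate_spectra <- function(design, pure, noise_sd = 0.002, seed = 1) {
  qs_check(noise_sd >= 0, "noise_sd must be non-negative")
  C <- design$nominal
  qs_check(identical(colnames(C), rownames(pure$unit_absorptivity)),
           "design and pure spectra analyte order mismatch")
  A <- C %*% pure$unit_absorptivity
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    A <- A + matrix(stats::rnorm(length(A), 0, noise_sd), nrow(A))
  }
  new_spectra_set(pure$wavelengths_nm, A, design$sample_ids)
}

#' Simulate the capsule dosage-form assay samples
#'
#' The dosage form carries the four analytes at the challenging 80:1:10:60
#' PARA:CPM:CAF:ASC ratio; at the working dilution this is nominally
#' (20.00, 15.00, 2.50, 0.25) ug/mL of PARA, ASC, CAF, CPM. The minor CPM
#' component is lifted into the calibrated range by standard addition
#' (`spike_cpm`, default 0.75 ug/mL, giving a total of 1.00). Three replicate
#' solutions are generated; post-spike nominals are the recovery reference.
#'
#' @param pure a `pure_spectra` object.
#' @param spike_cpm CPM standard addition (ug/mL, >= 0).
#' @param noise_sd absorbance noise sd (AU).
#' @param seed integer seed.
#' @param n_replicates number of replicate determinations (default 3).
#' @return List with `spectra` (a `spectra_set`) and `design` (a
#'   `design_matrix` with role `"assay"` holding the post-spike nominals).
#' @export
simulate_dosage_form <- function(pure, spike_cpm = 0.75, noise_sd = 0.002,
                                 seed = 1, n_replicates = 3) {
  qs_check(spike_cpm >= 0, "spike_cpm must be non-negative")
  nominal1 <- c(PARA = 20, ASC = 15, CAF = 2.5, CPM = 0.25 + spike_cpm)
  nominal <- matrix(rep(nominal1, each = n_replicates), n_replicates, 4,
                    dimnames = list(NULL, analytes()))
  ids <- sprintf("capsule_rep%d", seq_len(n_replicates))
  design <- new_design_matrix(ids, nominal,
                              coded_from_nominal(nominal),
                              rep("assay", n_replicates),
                              default_level_grids())
  list(spectra = simulate_spectra(design, pure, noise_sd, seed),
       design = design)
}

#' Write / read spectra as CSV
#'
#' First column `sample_id`; remaining columns named by wavelength with one
#' decimal ("220.0"); values in AU.
#'
#' @param spectra a `spectra_set`.
#' @param path file path.
#' @return `read_spectra_csv` returns a `spectra_set`.
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- data.frame(sample_id = spectra$sample_ids, spectra$absorbance,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wl <- as.numeric(colnames(df)[-1])
  new_spectra_set(wl, as.matrix(df[, -1, drop = FALSE]), df$sample_id)
}
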