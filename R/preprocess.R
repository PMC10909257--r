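# Spectral window selection and mean-centering.

#' Select an inclusive wavelength window
#'
#' The working window for this mixture is 220.0-300.0 nm (81 points at 1 nm):
#' below 220 nm the signal is noise-dominated, above 300 nm uninformative.
#'
#' @param spectra a `spectra_set`.
#' @param low_nm,high_nm window bounds; must lie on the wavelength grid.
#' @return A `spectra_set` restricted to the window.
#' @export
select_window <- function(spectra, low_nm = 220, high_nm = 300) {
  qs_check(low_nm <= high_nm, "low_nm must not exceed high_nm")
  wl <- spectra$wavelengths_nm
  i_lo <- match(TRUE, abs(wl - low_nm) < 1e-9)
  i_hi <- match(TRUE, abs(wl - high_nm) < 1e-9)
  qs_check(!is.na(i_lo) && !is.na(i_hi),
           "window bounds must lie on the wavelength grid")
  keep <- i_lo:i_hi
  new_spectra_set(wl[keep], spectra$absorbance[, keep, drop = FALSE],
                  spectra$sample_ids)
}

#' Mean-center a spectral block
#'
#' Subtracts per-wavelength column means. In calibration mode the means are
#' computed from the data; in prediction mode supply `reference_means` (the
#' calibration means) so new samples are centered consistently.
#'
#' @param spectra a `spectra_set` (already windowed).
#' @param reference_means optional numeric vector of column means to use.
#' @return A `centered_block`: `X_centered`, `x_means`, `wavelengths_nm`.
#' @export
mean_center <- function(spectra, reference_means = NULL) {
  X <- spectra$absorbance
  if (is.null(reference_means)) {
    qs_check(nrow(X) >= 2,
             "need at least 2 samples to compute centering means")
    reference_means <- colMeans(X)
  }
  qs_check(length(reference_means) == ncol(X),
           "reference_means length must match wavelength count")
  structure(list(X_centered = sweep(X, 2, reference_means),
                 x_means = as.numeric(reference_means),
                 wavelengths_nm = spectra$wavelengths_nm,
                 sample_ids = spectra$sample_ids),
            class = "centered_block")
}
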