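# quatspec

Chemometric resolution of a severely overlapped quaternary UV-Vis mixture —
paracetamol (PARA), ascorbic acid (ASC), caffeine (CAF) and chlorpheniramine
maleate (CPM), the composition of combination cold-medicine capsules — by
four multivariate calibration engines, with full validation diagnostics and
analytical greenness scoring.

The package is aimed at analytical chemists and chemometricians who want a
tested, reproducible reference implementation of this workflow. Because the
original measured spectra are not publicly deposited, the package carries a
synthetic-data generator (five-level four-factor calibration design,
sum-of-Gaussian pure spectra, Beer-Lambert mixing with homoscedastic
photometric noise, dosage-form simulation at the 80:1:10:60 ratio with CPM
spiking) and exercises everything end-to-end on data it generates.

## The models

All engines start from the multi-wavelength Beer-Lambert model
`D = C Sᵀ + E` on the 220–300 nm window (81 points at 1 nm):

- **PCR** — principal components of the mean-centered spectra by SVD,
  least-squares regression of concentrations on the first *k* scores.
- **PLS** — NIPALS PLS2 (all four analytes jointly) with block deflation,
  `B = W(PᵀW)⁻¹Qᵀ`; latent variables for both factor models selected by
  leave-one-out cross-validation (RMSECV minimum).
- **MCR-ALS** — alternating least squares on `D ≈ C Sᵀ` under
  non-negativity (active-set NNLS on both profiles) and a correlation
  constraint that regresses each resolved concentration column on its
  reference column, anchoring components and units; convergence at < 0.1 %
  relative change in `LOF = 100·√(Σe²/Σd²)`, with `R² = 100 − LOF²/100`.
  Test samples are predicted one-by-one by matrix augmentation.
- **ANN** — feed-forward 81 → 5 → 4 network with identity (purelin)
  transfers, trained by Levenberg-Marquardt with seeded 70/15/15
  train/validation/test splits and validation early stopping. A
  purelin-purelin network is exactly an affine map, which gives the trainer
  a sharp least-squares oracle.

Diagnostics: recovery mean/SD/RSD, RMSEC/RMSEP, predicted-vs-nominal
regression, Durbin-Watson with a seeded permutation p-value, elliptical
joint confidence region (EJCR) of (intercept, slope), pooled-t and
variance-ratio F between methods. Greenness: Eco-scale penalty points
(score = 100 − ΣPP) and an AGREE-style 12-principle weighted mean.

## Worked example

```r
library(quatspec)

design <- generate_design()          # 25 calibration + 5 validation mixtures
pure   <- default_pure_spectra()     # synthetic band table, 200-400 nm
cal    <- design_subset(design, "calibration")
val    <- design_subset(design, "validation")

cal_spec <- select_window(simulate_spectra(cal, pure, noise_sd = 0.002, seed = 1))
val_spec <- select_window(simulate_spectra(val, pure, noise_sd = 0.002, seed = 101))

m <- fit_mcr_als(cal_spec, cal$nominal)
m
#> <mcr_model> 4 components, 22 iterations; %LOF = 0.155263, R2 = 99.9998%

pred <- predict_mcr(m, val_spec, cal_spec, cal$nominal)
recovery_stats(pred, val$nominal)
#> <recovery_table> 5 samples
#>        PARA   ASC    CAF   CPM
#> mean 101.00 99.21 100.80 99.02
#> sd     1.39  0.70   1.29  1.31
```

The lack of fit (0.16 %) says the constrained bilinear model reconstructs
99.9998 % of the spectral variance; mean recoveries within ±1 % of 100 with
SDs near 1 % are the expected scale at 0.002 AU photometric noise. The
numbered scripts under `analysis/` run the complete study — simulation,
factor models with cross-validation, curve resolution, network training,
cross-engine diagnostics, greenness — writing tables under `results/run/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

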