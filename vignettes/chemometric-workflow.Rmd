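---
title: "Resolving a quaternary cold-medicine mixture: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving a quaternary cold-medicine mixture: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`quatspec` implements a complete multivariate-calibration workflow for a
severely overlapped quaternary UV-Vis mixture: paracetamol (PARA), ascorbic
acid (ASC), caffeine (CAF) and chlorpheniramine maleate (CPM), the
composition of combination cold-medicine capsules. Because a quantitative
mixture analysis cannot be demonstrated without spectra, the package carries
its own synthetic-data generator; every engine, diagnostic and test runs
end-to-end on data it produces.

## The measurement model

All engines start from the multi-wavelength Beer-Lambert law. For `n`
mixtures measured at `w` wavelengths,

$$D = C\,S^\top + E,$$

where `D` (`n x w`) holds absorbances, `C` (`n x 4`) the analyte
concentrations in µg/mL, `S` (`w x 4`) the unit-concentration absorptivity
spectra at 1 cm path, and `E` instrumental noise. The generator draws `E` as
i.i.d. Gaussian absorbance noise, 0.002 AU by default — the scale of
photometric noise of a routine dispersive UV-Vis instrument. The default
`S` is a sum-of-Gaussian band table (a plain-text data file) whose four
spectra overlap strongly across the 220–300 nm working window (all pairwise
correlations above 0.3); it is synthetic, standing in qualitatively for the
real absorptivities, which are not published. Consequences of this
idealization are discussed at the end.

### Calibration design

The calibration set is a five-level, four-factor design: 25 mixtures over
the grids PARA 4–20, ASC 3–15, CAF 2.5–12.5 and CPM 1–9 µg/mL, plus a
five-mixture validation hold-out. The published concentration table ships
verbatim as the default (`generate_design()`), including its duplicated
all-center row (mixtures 1 and 25) — preserved deliberately, as printed. A
self-consistent cyclic generator (`source = "generated"`) is provided for
fresh designs: one 24-long cyclic level sequence, phase-shifted by six runs
per factor, which reproduces the structural properties of the published
block (all-center first run, wrapped replicate at run 25, full level
coverage per factor) without claiming to reproduce its exact row order.
The printed table does not follow any single-shift cyclic rule we could
identify, so it is treated as data, not as the output of an algorithm.

The capsule assay simulator places the four analytes at the dosage-form
ratio 80:1:10:60 (PARA:CPM:CAF:ASC), i.e. nominally (20, 15, 2.5, 0.25)
µg/mL at the working dilution, and lifts CPM into the calibrated range by a
0.75 µg/mL standard addition; three replicate solutions are generated.

### Preprocessing

The working window is 220.0–300.0 nm at 1 nm — 81 spectral points; below
220 nm the simulated signal is noise-dominated and above 300 nm carries no
information. PCR and PLS mean-center both blocks internally (prediction
re-uses the stored calibration means). MCR-ALS and the network consume raw
in-window absorbances: non-negativity constraints are meaningless on
centered data, so the blanket "mean-centering" of classical practice is
interpreted as applying to the regression models only. This asymmetry is a
deliberate design decision, documented here because the two conventions are
often conflated.

## The four engines

**PCR** computes principal components of the centered spectra by SVD
(numerically safer than NIPALS PCA, identical subspace) and regresses the
centered concentrations on the first *k* scores. **PLS** is NIPALS PLS2 —
all four analytes modelled jointly, as multicomponent toolbox practice has
it — with deflation of both blocks and coefficients assembled as
$B = W(P^\top W)^{-1}Q^\top$; a PLS1 mode exists for single-analyte work.
Latent-variable counts come from leave-one-out cross-validation with
per-fold recentring; the selected count minimizes the analyte-averaged
RMSECV, ties resolved toward fewer components. On noiseless synthetic data
this recovers the true rank 4; with noise the global minimum can drift
higher for PCR, which the cross-validation table makes visible rather than
hiding (no parsimony heuristic is applied — the rule is the plain minimum).
RMSEC/RMSECV use an `n` denominator, so absolute values are comparable only
qualitatively with conventions that subtract degrees of freedom.

**MCR-ALS** alternates least-squares estimates of `C` and `S` under three
constraints: non-negativity of both profiles (active-set NNLS per
row/column; a fast clipping mode exists behind a flag) and the correlation
constraint, which each iteration regresses every resolved concentration
column on its reference column over the calibration rows and replaces those
entries by the fitted values. The correlation constraint does three jobs at
once: it fixes the rotational ambiguity of the bilinear factorization,
pins the component order to the analytes, and anchors concentrations in
real units. It applies to `C` only — a correlation constraint needs
reference values, which exist only for concentrations; the published phrase
"applied to both profiles" is read as non-negativity on both, correlation
on `C`. Initialization is purest-sample spectra chosen by a greedy
determinant (volume) criterion; known spectra can be injected for tests.
Convergence follows the toolbox convention: relative change in %LOF below
0.1% between iterations, with
$\mathrm{LOF} = 100\sqrt{\sum e^2 / \sum d^2}$ and
$R^2 = 100 - \mathrm{LOF}^2/100$ (an exact identity, tested to machine
precision). Divergence — LOF rising beyond tolerance for three consecutive
iterations — aborts with an error. Test samples are predicted one at a
time by appending the spectrum to the calibration matrix and re-running ALS
from the fitted spectra, with the correlation constraint restricted to the
calibration rows.

**The network** is a feed-forward 81 → 5 → 4 architecture with identity
("purelin") transfers in both layers, trained by Levenberg-Marquardt on the
full weight vector. With linear transfers the network is exactly an affine
map — `ann_as_affine()` collapses it, and tests assert the collapse — so
the trainer has a sharp oracle: on full-column-rank data the converged
network must match the ordinary least-squares affine fit. Five hidden
neurons are the default (four is the supported alternative; sources for
this architecture disagree between four and five, and neither is asserted
as canonical). Damping starts at 0.1 — the stated "learning rate 0.1" is
meaningless for pure LM and is read as the initial damping — rising 10x on
rejected steps, falling 10x on accepted ones; training MSE therefore
decreases monotonically. The 25 calibration mixtures are split 70/15/15
(19/3/3) into train/validation/test by a seeded shuffle; the five-mixture
design hold-out never enters training. Early stopping halts after six
consecutive validation-MSE increases, and the returned weights are those of
the best-validation epoch.

Two scaling choices deserve emphasis. Outputs are scaled per analyte to
[-1, 1], so early stopping (whose history is recorded in scaled space)
weighs all four analytes equally — otherwise the minor CPM component is
invisible next to paracetamol. Inputs are centered per wavelength but share
one *global* scale factor rather than per-wavelength normalization.
Absorbances are commensurable quantities in one unit; normalizing each
wavelength to [-1, 1] inflates the noise at weakly absorbing wavelengths,
and the LM solution then converges near the minimum-norm interpolator of
that distorted geometry, degrading the minor analyte several-fold. We
verified this directly by comparing minimum-norm interpolators in both
geometries before fixing the design. Weight initialization is small
fan-in-scaled uniform noise (a linear network needs no symmetry breaking);
it is kept small so the converged map carries negligible random residue
along directions outside the training span, which is what lets the
converged coefficients track the Beer-Lambert pseudo-inverse.

## Diagnostics

Validation quality is summarized per analyte by recovery statistics (mean,
sample SD with `n - 1`, RSD — the SD column is the one comparable with
published recovery tables, whose "RSD" header prints SD-scale values),
RMSEC/RMSEP, and predicted-versus-nominal regression (slope, intercept,
correlation). Residual structure is probed by the Durbin-Watson statistic
on residuals ordered by ascending nominal concentration; its p-value comes
from a seeded permutation test (two-sided departure from 2) rather than the
Imhof/Pan exact distribution — assumption-free, and its null uniformity is
itself property-tested. Accuracy is tested jointly by the elliptical joint
confidence region of (intercept, slope): the method passes when (0, 1)
falls inside $\{b : (\hat b - b)^\top X^\top X (\hat b - b) \le
2 s^2 F_{2,n-2,0.95}\}$. Between-method comparisons use the pooled-variance
two-sample t (df `n1 + n2 - 2`) and the variance ratio F with the larger
variance on top, both accepting raw values or (mean, SD, n) summaries; the
two routes are tested for exact agreement.

## Greenness

The Eco-scale engine scores penalty items against the published rule
tables: reagent points are pictograms x signal word (warning 1, danger 2) x
amount bracket (<10 mL/g: 1, 10–100: 2, >100: 3); instrument energy,
occupational hazard and waste score from their own brackets; the score is
100 minus total penalty points, "excellent" above 75. The methanol-based
procedure's item list (3 pictograms, danger, 10–100 mL; negligible
instrument energy; no hazard; 1–10 mL waste) reproduces the published
score of 85, the water-based comparator 97. The published account does not
itemize how methanol's 12 points decompose nor which waste bracket was
meant; the shipped decomposition is the unique one consistent with the rule
table and the printed totals. The AGREE-style aggregator is a weighted
arithmetic mean of 12 principle scores in [0, 1]; the full per-principle
rubric automation is out of scope, so scores are direct inputs. The shipped
12-score profile is a *synthetic reconstruction* averaging to the published
overall of 0.77 — a regression fixture, labelled as such, not a claim about
the original per-principle assessment.

## Numerical choices and degenerate inputs

- NNLS is Lawson-Hanson active set (tiny systems, K = 4); it is
  cross-checked against an independent solver in the tests.
- ALS guards singular normal equations via a reciprocal-condition check and
  treats `LOF < 1e-8`% as converged (noiseless fixed points would otherwise
  divide 0/0 in the relative-change rule).
- EJCR membership carries a small numerical slack so an exact fit
  (`s² = 0`, estimate at the ideal point to rounding) counts as inside.
- Window bounds must lie on the wavelength grid exactly; a single-column
  window is legal (degenerate slice).
- Coded levels off the five-point grids (e.g. the 8/8/8/8 validation
  mixture) map to `NA` rather than the nearest level.
- All randomness — noise draws, network splits and initialization,
  permutation tests — flows from explicit integer seeds; identical seeds
  give bit-identical matrices.

## Problem sizes

The test suite and the analysis scripts run the study at its native scale:
25 + 5 mixtures, 81 wavelengths, 3 assay replicates; Monte-Carlo style
checks use a handful of seeds (noise properties, recovery scales), 400–1000
replicates for distributional properties of the Durbin-Watson statistic,
and 199–1999 shuffles for permutation p-values. These sizes were chosen as
the smallest at which the asserted properties are stable.

## What passing tests do and do not show

The generator emulates additive Beer-Lambert mixing with homoscedastic
Gaussian noise and band shapes that only qualitatively resemble the real
chromophores. Real spectra add wavelength-correlated noise, baseline drift,
stray-light nonlinearity at high absorbance, solvent and excipient effects
(the dosage-form simulator models no excipient background, matching the
reported absence of interference), and absorptivities that differ from our
Gaussians. Passing tests therefore demonstrate that the algorithms are
implemented correctly and behave as theory predicts on ideal bilinear data
— exact recovery without noise, published-scale recoveries at 0.002 AU
noise — not that any particular figure from the original measured data is
reproduced. Published figures recomputable from printed tables (recovery
means/SDs, t and F statistics, Eco-scale totals, the LOF/R² pair) are
reproduced exactly; figures tied to the unavailable measured spectra
(calibration RMSEC/RMSEP tables, iteration counts) are not claimed.
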