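Package: quatspec
Title: Chemometric Resolution of a Quaternary Cold-Medicine Mixture by
    PCR, PLS, MCR-ALS and a Linear Feed-Forward Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multivariate calibration workflow for a severely overlapped
    quaternary UV-Vis mixture of paracetamol, ascorbic acid, caffeine and
    chlorpheniramine maleate. Provides a five-level four-factor calibration
    design (with the published concentration table as a fixture), a
    Beer-Lambert synthetic-spectra generator with configurable Gaussian band
    tables, spectral window selection and mean-centering, principal component
    regression and NIPALS partial least squares with leave-one-out
    cross-validation, multivariate curve resolution by alternating least
    squares under non-negativity and correlation constraints, a
    Levenberg-Marquardt trained linear (purelin-purelin) feed-forward network,
    validation diagnostics (recovery statistics, RMSEC/RMSEP, Durbin-Watson
    with a permutation p-value, elliptical joint confidence region, pooled t
    and variance-ratio F comparisons), and analytical greenness scoring
    (Eco-scale penalty points and an AGREE-style aggregator).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
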