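Package: isodiel
Title: Dual Stable-Isotope Internal-Standard Metabolomics for Diel Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Credentialing and relative quantification of LC-MS metabolite
    features using a fully 13C-labeled internal-standard extract and separate
    13C/15N-labeled cultures. Pairs each unlabeled feature with its co-eluting
    mass-shifted internal-standard counterpart, infers carbon and nitrogen
    atom counts from labeling-induced mass shifts, quantifies relative
    metabolite inventories as 12C/13C isotopic area ratios, and runs the
    statistics for diurnal sampling designs (one-way ANOVA and fold-change
    screens, coefficient-of-variation gate, PCA with per-group confidence
    ellipses, peaking-time classification) together with a sinusoidal
    light-profile model and instantaneous specific growth-rate estimation
    from OD720 time series. Includes a synthetic-study generator that
    emulates the full design with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
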