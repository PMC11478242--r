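Package: eimsCascade
Title: Hierarchical PLS-DA Classification of EI Mass Spectra for
    Synthetic Cannabinoid Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying novel synthetic cannabinoids and
    annotating their structural subgroups (core, head and tail moieties)
    from low-resolution electron-ionization mass spectra.  Provides a
    NIST MSP reader and unit-mass binning, autoscaling with venetian
    blinds cross-validation, a NIPALS partial least squares discriminant
    analysis (PLS-DA) engine with Gaussian decision thresholds,
    genetic-algorithm variable selection over m/z channels, a
    seven-node hierarchical binary decision cascade with per-node
    figures of merit (accuracy, TPR, TNR, F1, MCC), and a synthetic
    EI-spectrum generator encoding class-diagnostic fragment ions so
    the whole pipeline is testable without external spectral libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
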