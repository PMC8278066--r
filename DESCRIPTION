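Package: qnmrassay
Title: Quantitative 1H-NMR Assay Simulation, Quantification and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for internal-standard quantitative proton NMR (qNMR) assays
    of pharmaceutical mixtures, built around the fluticasone propionate /
    azelastine hydrochloride nasal-spray assay with inositol as internal
    standard. Provides a physically motivated spectrum simulator (Lorentzian
    lineshapes, T1-dependent steady-state amplitudes, scan averaging, baseline
    drift), a processing chain (exponential apodization, Fourier transform,
    automatic phase correction, polynomial baseline correction, axis
    referencing), region integration and internal-standard quantification
    (integral ratios, purity equation, calibration inversion), and the ICH
    Q2(R1) validation statistics: linearity with LOD/LOQ from the calibration
    intercept, accuracy with t/F comparison against a reference method,
    intra/inter-day precision, stability and specificity. Spectra are read and
    written as JCAMP-DX; tables as CSV; run configuration as YAML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
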