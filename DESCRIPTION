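Package: bsfs
Title: Baseline Spectral Fingerprint Sorting for Medication Authenticity Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies medications as authentic or low-quality/counterfeit from
    UV absorbance fingerprints measured at a small set of discrete wavelengths.
    Category boundaries for the authentic band are learned as per-wavelength
    minima and maxima over replicate authentic preparations, and samples are
    sorted against those boundaries with the ELECTRE TRI-B outranking method
    (concordance, discordance and credibility indices with indifference,
    preference and veto thresholds and both the pessimistic and optimistic
    assignment procedures). Includes threshold calibration by misclassification
    minimisation over a (preference, veto) grid, sensitivity sweeps over the
    credibility cut level, a seeded generator of synthetic authentic and
    contaminant spectra, the published Praziquantel reference tables, CSV/JSON
    input and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
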