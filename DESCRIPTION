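Package: glycodia
Title: Statistical Control and Library Tools for DIA Glycoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Peptide-centric analysis of intact glycopeptides from
    data-independent acquisition (DIA) mass spectrometry. Builds consensus
    glycopeptide spectral libraries from DDA identifications, generates
    peptide/glycan/both decoy libraries, estimates error rates with a
    two-dimensional false discovery rate based on a bivariate four-groups
    mixture model, resolves co-isolated glycoforms with a Bayesian
    hierarchical model over in-silico Y-ion identification transitions,
    extends libraries semi-empirically by k-nearest-neighbor fragment
    swapping, and aggregates quantities over the glycopeptide, site-specific
    glycan and protein glycosite hierarchy. Includes a synthetic-data module
    that emulates glycan databases, glycopeptide libraries, four-class
    D-score distributions, transition-level glycoform signals and entrapment
    benchmarks for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    xml2
Suggests: testthat (>= 3.0.0), withr, yaml, jsonlite
Config/testthat/edition: 3
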