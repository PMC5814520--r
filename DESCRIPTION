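Package: linkquant
Title: Label-Free MS1 Quantitation of Cross-Linked Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for label-free quantitative cross-linking mass
    spectrometry (QCLMS). Cross-linked peptide identifications are converted
    into mass-equivalent linear peptide forms so that MS1-filtering tools
    built for linear peptides can quantify them; spectral-library input
    (.ssl) is written for library construction; precursor isotope envelopes
    are extracted from centroided MS1 mzML data and integrated per replicate
    with match-between-runs; and reproducibility is summarised as
    per-residue-pair coefficients of variation, saturation and overlap
    analyses, and CV-versus-intensity profiles. Cross-links are validated
    against a crystal structure via C-alpha distances and decoy counts. A
    synthetic-data generator renders replicate MS1 acquisitions of a
    cross-linked tryptic digest with known ground truth so the entire
    pipeline is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    pracma,
    jsonlite,
    mzR,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
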