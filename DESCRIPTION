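Package: gpersig
Title: Mass-Action Modeling of GPER/EGFR Signaling and Tamoxifen Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, simulating and analyzing mass-action
    ordinary-differential-equation models of the GPR30 (GPER) / EGFR /
    PI3K / MAPK / STAT signaling network in breast cancer cells, with a
    packaged synthetic transcription of the tamoxifen-responsive MCF-7
    network. Includes SBML import/export, stiff ODE integration,
    treated-versus-untreated trajectory comparison, local sensitivity
    analysis, rate-constant fitting, downstream RNA-seq expression
    statistics (Phred quality, read filtering, RPKM, Benjamini-Hochberg
    adjustment, differential-expression calling, hypergeometric gene-set
    enrichment), and seeded synthetic-data generators with known ground
    truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
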