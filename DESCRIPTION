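Package: specfx
Title: Spectrum-Effect Relationship Screening for Herbal Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spectrum-effect relationship analysis of multi-batch
    chromatographic fingerprints of herbal preparations: common-peak matching
    across batches with a retention-time window, relative retention time and
    relative peak area quality-control summaries (RSD), fingerprint similarity
    matrices, DPPH radical-scavenging and total-antioxidant-capacity assay
    computation, grey relational analysis with Deng coefficients, single-response
    orthogonal projections to latent structures (OPLS) with VIP scoring, and a
    joint rule that nominates candidate active components (VIP > 1 with a
    positive regression coefficient in every assay). Ships transcribed reference
    tables from a ten-batch Yiwei Decoction antioxidant study and a synthetic
    multi-batch data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
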