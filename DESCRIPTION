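Package: msnforest
Title: Automated Generation of Multi-Stage Fragmentation (MSn) Spectral
    Libraries from Pooled Flow-Injection Runs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: High-throughput pipeline for building open multi-stage
    fragmentation (MSn) mass-spectral libraries from pooled-compound
    flow-injection acquisitions. Curates compound metadata (structure
    standardization, salt stripping, descriptor computation, unique
    sample-identifier assignment, acquisition-sequence generation), reads
    centroided MSn scan data (mzML and a JSON scan dialect), assembles
    precursor-lineage fragmentation trees, annotates tree roots against the
    compounds known to be in each injected sample using exact adduct masses,
    scores precursor isolation purity, denoises and filters spectra, merges
    spectra per collision energy, across energies and into pseudo-MS2
    composites, and exports libraries in MGF, MSP and JSON formats. Includes
    weighted-cosine library matching, InChIKey-based library-overlap
    analysis, and a synthetic data-dependent MSn acquisition simulator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    jsonlite,
    mzR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
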