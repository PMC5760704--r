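Package: umclone
Title: Clonal Evolution and Neutral Growth Analysis for Uveal Melanoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the life history of uveal melanoma tumors from bulk
    sequencing data. Converts somatic variant allele frequencies to cancer cell
    fractions with adjustment for tumor purity and allele-specific copy number,
    clusters mutations with a truncated Dirichlet-process binomial mixture
    sampled by Gibbs, builds rooted clone trees (normal cell, most recent
    common ancestor, subclones) under the pigeonhole constraint with
    classification of canonical driver aberrations as ancestral or subclonal,
    and tests for neutral tumor evolution via the 1/f power-law fit of the
    cumulative subclonal mutation distribution M(f). Includes a synthetic
    tumor generator with known clonal architecture and a neutral mutation
    tail, so the whole pipeline is testable without controlled-access patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    xml2,
    withr,
    optparse
Config/testthat/edition: 3
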