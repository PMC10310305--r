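Package: germlinekit
Title: Curation, Temporary Nomenclature and Publication of Immune Receptor Germline Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for curating immunoglobulin and T-cell receptor germline
    reference sets. Implements the community germline-set data model
    (allele descriptions, germline sets, per-subject genotypes) with
    validation; a temporary allele nomenclature based on random 20-bit
    identifiers in a restricted base32 alphabet; a two-phase label
    allocation workflow over a CSV naming-domain registry with alias
    traceability and registry merging; canonical JSON and FASTA
    serialisation of germline sets with version bumping and release
    diffing; and construction of personalised germline sets from
    per-subject genotypes. Includes deterministic synthetic-data
    generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
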