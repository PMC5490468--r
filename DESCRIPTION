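Package: matcompare
Title: Pairwise Protein Alignment Across Multiple Substitution Matrices
Version: 1.0.0
Authors@R:
    person("Alex", "Doran", email = "alex.doran@example.org",
           role = c("aut", "cre"))
Description: Batch comparison of substitution matrices for pairwise protein
    alignment. Aligns one pattern/subject pair of protein sequences under any
    number of substitution-matrix and affine gap-penalty configurations
    (bundled NCBI PAM/BLOSUM matrices or user-supplied custom matrices listed
    in a master file), using five scoring modes (global, local, overlap,
    global-local, local-global). For every configuration it reports the
    alignment score, four percent-identity variants, per-column log-odds and
    conservation annotation, amino-acid classification under seven
    physicochemical schemes, and indel/match/subsequence search results, then
    ranks and min-max normalises the configurations and writes JSON, TSV and
    static HTML reports. Includes an exhaustive alignment-enumeration oracle
    for verification and a deterministic synthetic-fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
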