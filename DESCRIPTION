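Package: poresift
Title: Nanopore Adaptive-Sampling Read Accounting and Host-Depletion Analysis
Version: 0.1.0
Authors@R:
    person("poresift", "developers", email = "poresift@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing Oxford Nanopore adaptive-sampling
    ("Read Until") sequencing runs used for host-DNA depletion or
    microbial enrichment in metagenomics. Parses basecalled reads
    (FASTQ) and MinKNOW-style decision logs, splits reads into the
    accepted / rejected / no-decision categories, joins per-read
    taxonomic classifications, and computes run-level yield summaries,
    per-category human and bacterial content, filtered abundance
    tables, control-versus-depletion concordance statistics
    (stratified fold deviations, Bray-Curtis dissimilarity, Spearman
    correlation with pairwise-case exclusion), and mock-community
    representation bias from alignments. Includes a synthetic
    adaptive-sampling run generator with named presets so complete
    analyses run at desk scale without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
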