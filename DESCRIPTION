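Package: epienrich
Title: Cell-Type-Specific Enrichment of SNP Sets in Epigenomic Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests a set of GWAS variants for tissue- and cell-type-specific
    enrichment in epigenomic annotation tracks (DNase I hotspots, histone mark
    broadPeaks, chromatin states). For each biosample the observed overlap
    count of the input SNP set is compared against covariate-matched background
    SNP sets (matched on decile bins of minor allele frequency, distance to the
    nearest transcription start site, and GC content) with an exact one-sided
    binomial test, followed by Benjamini-Hochberg correction across biosamples.
    Includes greedy LD pruning, a single-file rsid-indexed overlap database
    built from BED tracks, batch analysis of GWAS-catalogue association files
    with complete-linkage clustering summaries, a false-positive-rate
    calibration harness, and a synthetic-data generator with controllable
    covariate confounding and spiked enrichments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    IRanges,
    jsonlite,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
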