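Package: mescan
Title: Metastable Epiallele Screening and Read-Level Methylation
    Homogeneity from Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("mescan", "developers", email = "mescan@example.org",
           role = c("aut", "cre"))
Description: Detects metastable epialleles (MEs) -- genomic regions with
    systemic, cross-tissue interindividual variation in CpG methylation --
    from multi-individual, multi-tissue bisulfite sequencing data.
    Implements the three-step ME screen (per-CpG metastability criteria,
    single-linkage clustering, purity filtering) with SNP-proximity
    masking and matched control-region sampling; stage-wise methylation
    summaries across early-embryo developmental series, including
    intermediate-methylation fractions and stratified pre/post-gastrulation
    transition analyses with bootstrap confidence intervals; a read
    homogeneity index (RHI) that contrasts observed adjacent-CpG
    methylation transition counts against a cluster-wide permutation null;
    and genomic enrichment statistics (tile-based Fisher tests, proximity
    profiles, chromatin-state overlap, mQTL enrichment). A synthetic-data
    module generates cohorts, stage series, read-level call sets and
    feature tracks with planted truth so the whole pipeline is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    methods,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
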