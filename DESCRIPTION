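Package: segwise
Title: Segment-Wise Enrichment Scans for Case-Control Genome-Wide
    Association Data
Version: 0.1.0
Authors@R: person("Segwise", "Developers", email = "segwise@example.org",
    role = c("aut", "cre"))
Description: Tests whether large overlapping chromosomal segments (megabase
    scale) contain more nominally significant SNP-phenotype associations
    than expected under a case-control label-permutation null.  Provides
    per-SNP Armitage trend tests with optional principal-component
    (EIGENSTRAT-style) stratification adjustment, a 50 percent overlap
    segment lattice with permutation "metasignificance" p-values,
    multi-cohort combination via a compound-significance replication rule
    and Fisher's combined probability test, a set-based gene test with
    greedy LD pruning, readers and writers for PLINK 1 binary cohorts, and
    a reproducible synthetic-cohort generator with haplotype-block linkage
    disequilibrium, population stratification and planted enriched
    segments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
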