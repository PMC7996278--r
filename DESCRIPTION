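Package: tagsel
Title: Tagging SNP Selection for Candidate-Gene Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Selects tagging SNPs in candidate gene regions for association
    studies of ischemic-stroke outcomes. Starting from a rat-to-human
    orthologue table, the pipeline extracts biallelic SNPs from population
    VCF data over gene regions with flanks, filters on minor allele
    frequency, computes pairwise linkage-disequilibrium r-squared (haplotype
    counting on phased data, two-locus EM or composite correlation on
    unphased genotypes), selects tagSNPs by greedy set-cover and by
    complete-linkage minimax clustering, compares the two by tagging
    effectiveness, and prioritizes the chosen tags by intersection with
    significant single-tissue eQTL records filtered to brain, artery, nerve,
    blood and heart tissues. A founder-resampling haplotype simulator with
    controllable block LD structure makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
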