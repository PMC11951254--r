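Package: regionassoc
Title: Region-Level Genome-Wide Association Testing with LD-Bin Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-level genome-wide association testing for quantitative and
    binary traits. Reads genotypes from VCF by genomic region, filters and
    recodes variants to minor-allele dosage, prunes near-duplicate variants on
    within-region linkage disequilibrium (LD), assigns variants to LD bins by
    clique-based clustering of the squared-correlation graph, and computes
    eight region-level tests per region: the multiple-linear-combination (MLC)
    contrast test on LD bins, the 1-df linear-combination (LC) burden test, the
    full-df multiple-regression Wald test, a principal-component test (PC80),
    the SKAT variance-component score test and its SKAT-O omnibus, and the
    simpleM and GATES minP corrections, plus single-variant tests, bin-level
    tests, a Cauchy (ACAT) combination across tests, Firth (Jeffreys-prior)
    penalized logistic regression for unbalanced binary traits, structured
    tab-separated outputs, and Miami/QQ/locus/bin visualization utilities.
    Includes a synthetic-fixture generator producing block-LD genotypes as VCF
    with matching region and phenotype tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    parallel,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
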