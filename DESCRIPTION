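Package: creolecore
Title: Diversity Analysis and Core Reference Set Selection for Landrace
    Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing crop landrace collections genotyped with
    sparse biallelic SNP panels (e.g. genotyping-by-sequencing) and for
    assembling core reference sets from mixed genotypic and phenotypic data.
    Provides allele-frequency and diversity statistics (Nei and Shannon
    indices, G_ST and gene flow, Weir-Cockerham F_ST), simple-matching
    distances with complete-linkage classification, equally-spaced marker
    subsetting, rare-allele characterization per group (including unique and
    geographically fixed alleles), and a core-selection engine combining
    principal-component reduction, two-block multiple factor analysis with a
    block-contribution constraint, Ward-initialized Gaussian-mixture
    clustering, diversity-proportional allocation, and Gower-distance
    maximized stratified sampling. A calibrated population simulator
    generates genotype, phenotype and geography fixtures for testing every
    stage without access to the original collection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    cluster,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
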