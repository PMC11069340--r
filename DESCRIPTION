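Package: rhizoscreen
Title: Genotype-Phenotype-Expression Screening for Catabolic Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated screen for bacterial catabolic gene clusters that
    combines three criteria over a panel of isolates: induction of gene
    expression under a candidate substrate (two-condition RNA-seq fold
    change), conservation of the encoded proteins among strains that show the
    degradation phenotype, and loss or divergence in strains that do not.
    Candidate genes are intersected and contiguous chromosomal hotspots are
    detected; cluster presence is tested for enrichment in strain traits such
    as isolation source by Fisher's exact test. Companion quantifications
    cover growth-curve inhibition indices (trapezoidal AUC normalised to the
    zero-dose control, Welch t-tests with Benjamini-Hochberg adjustment) and
    exact-mass annotation of catabolic intermediates (monoisotopic [M-H]-
    m/z with ppm matching and deuterium label shifts). A synthetic-data
    module plants ground-truth clusters, induction signals, dose-dependent
    growth inhibition and mass peaks so the whole analysis runs and is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
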