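Package: editome
Title: A-to-I RNA Editome Discovery, Quantification, and Target Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery of high-confidence adenosine-to-inosine (A-to-I) RNA
    editing sites from per-sample RNA variant calls via a filter cascade
    (read-support and quality thresholds, subtraction of known DNA variants,
    restriction to a curated editing catalog, and an informative-sample
    rule); quantification of editing levels at site, gene, and sample
    resolution; classification of group-specific editing by a specificity
    score with an inclusive 0.75 threshold; and a three-criterion target
    prioritization funnel (knockdown downregulation, editing reduction, and
    adverse high-expression survival) with correlation-based candidate
    ranking. Includes a seeded beta-binomial cohort simulator that generates
    pileups, variant calls, catalogs, annotations, knockdown and survival
    tables with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    survival,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
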