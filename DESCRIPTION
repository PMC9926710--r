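Package: PTXmap
Title: Pseudo-Testcross Linkage Mapping and XY Sex-Chromosome Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering an XY sex-determination system from a
    single outbred F1 family genotyped by whole-genome resequencing. Implements
    the full inference chain: two-stage variant filtering (read-support rules
    plus hard site filters), extraction of maternal and paternal pseudo-testcross
    datasets with unexpected-homozygote error screening, sex-specific linkage-map
    construction (two-point recombination fractions and LOD scores, Bonferroni
    LOD thresholds, marker binning and ordering, Kosambi distances), a binary
    sex-trait QTL scan with permutation thresholds, depth-of-coverage sex
    assignment and sex-linked contig flagging, a per-gene coverage-breadth
    screen for Y-linked genes, and tissue-restricted expression classification.
    A synthetic-data generator produces pseudo-testcross families with full
    ground truth (parental haplotypes, crossovers, sex genotypes, chimeric
    contigs) so that every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    igraph,
    mclust
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, LinkageDisequilibrium, QualityControl, Coverage
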