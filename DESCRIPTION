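Package: orthoscaf
Title: Protein-Guided Scaffolding of Fragmented Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Orders and orients genome-assembly contigs into scaffolds using
    orthologous guide proteins, while simultaneously producing homology-based
    gene models. Contigs carrying exons of the same gene are linked through a
    score-optimization framework: translated protein-to-contig alignments are
    filtered, condensed into putative exonic regions (PExRs) and contig gene
    models, clustered along each guide protein, and combined by exhaustive
    path enumeration with alpha/beta ratio filters into maximal scaffoldable
    sets ranked by scaffolding power. Protein scaffolds sharing contigs are
    merged into super-scaffolds via directed precedence graphs. Includes a
    synthetic genome/proteome simulator with known truth and accuracy metrics
    (N50, local link correctness, scaffold correctness).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    igraph,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
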