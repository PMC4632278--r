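Package: hgtpipe
Title: Detection, Phylogenetic Distribution and Gain/Loss Rates of
    Horizontally Transferred Genes in Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying horizontally transferred (foreign) genes
    in animal transcriptomes from partitioned BLAST bitscores using the HGT
    index h_U, screening putative contaminants, grouping transcripts into
    cross-species ortholog sets by reciprocal best hits or Markov
    clustering, correcting phylogenetic distribution counts for
    transcriptome false negatives, reconstructing parsimony-unambiguous
    gains and losses of foreign ortholog groups on a dated species
    phylogeny, and estimating per-branch Poisson gain/loss rates with
    highest-density intervals. Includes the statistical tests used in the
    accompanying comparative analyses (proportion tests, Fisher's exact
    test, Spearman correlation, Monte-Carlo chi-square, Welch t,
    phylogenetic generalized least squares with Pagel's lambda, GC-content
    amelioration trends) and a synthetic-data generator that emulates gene
    content evolving on a dated tree, GC amelioration, bitscore structure
    and binomial survival data, so the whole pipeline is testable without
    external sequence databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
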