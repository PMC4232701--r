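Package: famscan
Title: Profile-HMM Discovery and Classification of Gene-Family Members in
    Draft Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and classifying members of multi-subfamily
    protein-coding gene families (such as the GnRH receptor family of
    G-protein coupled receptors) in fragmented draft genome assemblies.
    Implements six-frame translation scanning of nucleotide contigs,
    from-scratch profile hidden Markov models with local-alignment forward and
    Viterbi scoring and Gumbel E-value calibration, subfamily- and
    fragment-region-restricted HMM libraries, best-E-value classification with
    reciprocal validation and exon-level evidence aggregation, parsimony
    reconstruction of gene presence/absence histories on a species tree,
    per-site protein likelihoods under JTT with discrete-gamma rates and
    invariant sites, Shimodaira-Hasegawa and approximately unbiased
    constrained-topology tests, and a synthetic gene-family generator with
    truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
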