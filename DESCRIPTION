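Package: dinucontext
Title: Neighbor-Context-Dependent Nucleotide Substitution Models and
    Dinucleotide Composition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the influence of neighboring bases on nucleotide
    substitution rates and the resulting dinucleotide composition of DNA and
    RNA sequences. Provides a composition scanner computing observed/expected
    dinucleotide ratios from FASTA input, a parameterized rate model in which
    context-dependent factors modify an HKY-style default matrix, a
    deterministic solver for the equilibrium dinucleotide proportions under
    the trinucleotide-independence approximation, greedy forward selection of
    context-dependent mutation factors by root-mean-square minimization
    against G+C compositional trends, a stochastic (Gillespie) sequence
    evolution simulator used as an independent oracle and fixture generator,
    and a flanking-context mutation-spectrum analysis for SNP records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
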