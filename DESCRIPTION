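Package: hmmsnv
Title: Hidden Markov Model Genotyping and SNV Calling from Pileup Data
Version: 0.1.0
Authors@R:
    person("hmmsnv", "maintainers", email = "maintainers@hmmsnv.dev",
           role = c("aut", "cre"))
Description: Calls single-nucleotide variants from SAMtools-style pileup
    text by modelling the per-position genotype (homozygous reference,
    heterozygous, homozygous non-reference) as the hidden state of a
    three-state discrete hidden Markov model. The emission model is a
    quality-aware generalized binomial that folds per-read mapping
    quality and per-base base quality into the likelihood of the
    observed allele counts. Parameters are estimated by Baum-Welch with
    a damped Newton sub-step for the per-state reference-allele
    frequencies, seeded from Dirichlet/Beta priors, and decoded by
    Viterbi. Includes a generative simulator with known ground truth,
    benchmarking metrics (sensitivity, specificity, accuracy, F-score),
    TSV/VCF writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
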