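Package: lesionphylo
Title: Persistent DNA Lesions in Somatic Phylogenies
Version: 0.9.0
Authors@R:
    person("lesionphylo", "developers", email = "lesionphylo@example.org",
           role = c("aut", "cre"))
Description: Detects and characterizes somatic mutations generated by
    persistent (long-lived) DNA lesions in high-resolution somatic
    phylogenies built from single-cell-derived colonies. Identifies
    multi-allelic variants (MAVs) and phylogeny-violating variants (PVVs)
    from per-sample variant read counts via maximum-likelihood
    branch assignment and beta-binomial overdispersion screening, traces
    lesion paths to bound lesion lifetimes in molecular time (MMLD),
    phases lesion alleles against nearby germline heterozygous SNPs,
    calibrates artefact rates with weighted branch-pair and somatic
    reversion null simulations, derives expected 96-channel mutational
    signatures for true lesions and artefact mechanisms, tests branches
    for lesion segregation (strand asymmetry), and infers mean lesion
    duration and per-cell lesion prevalence by rejection approximate
    Bayesian computation over simulated stem-cell population phylogenies.
    A synthetic-data generator with machine-readable ground truth supports
    fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
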