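Package: dysrec
Title: Recombination Mapping and Mitotic Cluster Inference in Hybrid
    Dysgenesis Backcrosses
Version: 0.1.0
Authors@R:
    person("Riley", "Kastner", email = "rkastner@example.org", role = c("aut", "cre"))
Description: Tools for mapping female recombination in Drosophila virilis
    backcross cohorts genotyped by shallow multiplexed shotgun sequencing.
    Includes a cohort simulator with known crossover and mitotic-cluster
    truth, a two-state ancestry hidden Markov model for sparse allele
    counts, crossover calling with the standard exclusion filters, genetic
    map and windowed recombination-rate construction, detection of
    sibling-shared (germline mitotic) recombination clusters with
    transmission-distortion and transposon-enrichment tests, and a
    truncated-binomial maximum-likelihood model of mitotic cluster
    formation (alpha) and transmission (beta) with nested model comparison
    and profile confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
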