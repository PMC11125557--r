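Package: lineagedist
Title: Distance-Based Cell Lineage Tree Reconstruction from Single-Cell
    DNA Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs cell lineage trees of healthy, diploid tissue from
    whole-genome-amplified single-cell DNA sequencing reads together with a
    bulk sample. A per-site probabilistic model of allelic dropout,
    amplification error (generalized Polya-urn amplification trees) and
    Phred-scaled sequencing error yields, for every pair of cells, the
    posterior probability that their genotypes differ; these probabilities
    are aggregated into a distance matrix and passed to neighbor joining.
    Includes read-phasing via nearby germline SNVs (paired sites), candidate
    site selection heuristics, site-bootstrap trees with transfer bootstrap
    expectation supports, Metropolis-Hastings estimation of the dropout and
    amplification-error rates, and a full synthetic-data simulator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
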