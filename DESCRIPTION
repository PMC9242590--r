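Package: ethotouch
Title: Social Touch Ethogram Analysis for Group-Housed Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-animal social behavior derived from
    body-point tracking of group-housed mice. Converts per-frame nose, mass
    centre and tail-base coordinates into a behavioral ethogram (pairwise
    contacts by type, isolated versus in-contact locomotion states, social
    approach and escape, stretch-attend posture), aggregates events into
    per-mouse trait tables over dark phases or post-injection checkpoints,
    computes the cage-normalized LMT index (each mouse's trait value divided
    by the mean of its two control cage-mates), classifies reciprocal,
    unilateral and passive interactions, and quantifies group dynamics:
    dyadic interaction probabilities against combinatorial chance baselines
    and the creation, breaking and persistence of groups of three. A seeded
    agent-based cage simulator produces pose streams with ground-truth
    contact episodes so the full pipeline is testable without recorded data.
    Includes the self-contained statistics used throughout: contingency-table
    chi-square, two-sample and paired t tests, Holm-Sidak step-down
    correction, and a seeded permutation test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
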