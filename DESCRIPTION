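Package: pertnet
Title: Perturbance-Weighted Network Analysis of Case/Control Genetic Data
Version: 0.1.0
Authors@R:
    person("pertnet", "developers", email = "pertnet@example.org",
           role = c("aut", "cre"))
Description: Discovers disease modules in a directed gene-gene interactome
    from case/control gene-level scores. Every interactome edge is weighted
    by its "perturbance", the p-value of the combined group effect on both
    endpoint genes and their link, transformed as w = 1/(-log p). A
    significance-filtered Steiner tree (shortest-path heuristic with
    Fisher-combined path p-values and Bonferroni correction) connects
    disease seed genes through maximally perturbed paths. The tree is then
    fitted as a structural equation model with a binary group node under
    several constraint schemes, extended with latent-variable common causes
    between disconnected target genes, and characterised topologically
    (weighted betweenness, springs/sinks/hubs/bottlenecks, essential nodes)
    and functionally (hypergeometric gene-set enrichment). Includes a
    supervised-PCA SNP-to-gene collapsing stage and a synthetic-data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
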