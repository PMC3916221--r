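Package: metgap
Title: Comparative Gapless Metabolic Network Reconstruction on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase comparative reconstruction of genome-scale, gapless,
    atom-mapped metabolic networks for all species of a rooted phylogeny.
    Phase one integrates reciprocal-search (BLAST-style) and remote-homology
    (GTG-style) enzyme evidence in a per-enzyme Bayesian network whose
    topology follows the phylogeny, with edge transition probabilities
    estimated by Fitch parsimony from reference enzyme calls and evidence
    densities estimated by Gaussian kernel density estimation. Phase two
    greedily assembles, for every present and ancestral species, a network in
    which each substrate atom of each accepted reaction can be traced to a
    declared nutrient set through reaction atom mappings, adding weakly
    supported gap-filling reactions only when connectivity demands them.
    Includes integer-programming mass balancing of reaction equations,
    EC-set ROC evaluation with poor-sequencing and distant-species
    perturbation scenarios, a synthetic-universe simulator, SBML export, and
    steady-state flux balance analyses (biomass component yields and
    complex-aware gene-knockout growth prediction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
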