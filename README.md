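# metgap: comparative gapless metabolic network reconstruction

Genome-scale metabolic models are usually curated by hand, one species at
a time, and most of that labor goes into *gap filling* — adding the
reactions without which the network cannot actually synthesize anything
from its nutrients. metgap implements a comparative, two-phase alternative
for whole clades at once: given a rooted phylogeny and homology-evidence
scores for each species' proteome, it reconstructs a gapless, atom-mapped
metabolic network for **every species of the tree — the present species at
the leaves and the hypothetical ancestors at the internal nodes**. It is
aimed at computational biologists who have many related (possibly poorly
sequenced) genomes and want usable constraint-based models with minimal
manual effort.

## The model

**Phase one — enzyme presence on the phylogeny.** For each enzyme $e$
(complete EC number), presence $x_s \in \{0,1\}$ in species $s$ evolves
along the tree under a Bayesian network whose topology follows the
phylogeny: a Bernoulli root prior $\pi_0$, per-edge transition
probabilities $p_{\text{gain}} = P(x_v{=}1 \mid x_u{=}0)$ and
$p_{\text{stay}} = P(x_v{=}1 \mid x_u{=}1)$ estimated by Fitch parsimony
plus transition counting on an independent reference detector, and, at the
leaves, two evidence channels — a reciprocal-search score
$b(e,s) = -\log_{10} p_f - \log_{10} p_r$ and a remote-homology
shared-feature fraction $g(e,s)$ — entering through four kernel-density
class-conditional distributions $f(b \mid x)$, $f(g \mid x)$. Belief
propagation (the polytree algorithm on a tree) yields the exact posterior
$P(x_s{=}1 \mid \text{data})$ for every node and enzyme.

**Phase two — gapless assembly.** Each reaction $r$ costs
$c(r) = -\ln \max_{e \in EC(r)} P(e \mid \text{data}) + b_0$. Reactions
are accepted greedily, cheapest estimated addition first, but only when a
biosynthesis pathway can *trace every substrate atom of the reaction back
to the nutrient set* through reaction atom mappings; weakly supported
reactions are pulled in as explicit gap fills only when connectivity
demands them, and pathways costlier than a rejection threshold are
refused. The result is gapless by construction (an invariant the test
suite certifies with an independent BFS oracle) and exports to SBML L3
with per-reaction EC, cost, provenance and carbon-map annotations.

The package also ships integer-programming mass balancing of reaction
equations (coefficients ≤ 15, water/proton additions, at most one
carbonic-acid unit), EC-set ROC evaluation with the poor-sequencing and
distant-species perturbation scenarios, steady-state flux analyses
(biomass component yields, complex-aware gene-knockout growth calls), and
a synthetic-universe generator so every part is testable offline.

## Worked example

```r
library(metgap)

study <- synthetic_study(n_species = 8, n_reactions = 60,
                         n_molecules = 40, n_ec = 40, seed = 42)
fit <- presence_model(study$tree, study$scores, study$reference,
                      ecs = study$ec_universe)
fit
#> Comparative enzyme-presence model
#>   phylogeny: 8 species, 7 ancestral nodes
#>   enzymes: 32 ECs; root prior 0.5

post <- predict(fit, nodes = "sp01")
round(post[1, 1:4], 3)
#> 0.977 0.039 0.025 0.894

rec <- reconstruct(study$universe$db,
                   reaction_costs(post[1, ], study$universe$db),
                   species = "sp01")
rec
#> gapless reconstruction [sp01]: 37 reactions (5 gapfill), 0 rejected

pred <- reconstruction_ecs(rec, study$universe$db)
compare_ec_sets(intersect(pred, study$ec_universe),
                study$gold_ecs[["sp01"]], study$ec_universe)
#> TP 18  FP 1  TN 12  FN 1 | TPR 0.947 FPR 0.077 prec 0.947 F1 0.947
```

The posteriors are per-(species, enzyme) presence probabilities (here
0.977 and 0.894 for two enzymes the species really has, 0.039 and 0.025
for two it lacks). The reconstruction accepted 37 reactions, 5 of them
gap fills added purely for connectivity, and its EC content recovers the
species' true network ECs at F1 0.947 against the simulated gold
standard.

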