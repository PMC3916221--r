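---
title: "Comparative gapless metabolic reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative gapless metabolic reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metgap)
```

metgap reconstructs genome-scale, gapless, atom-mapped metabolic networks
for every species of a rooted phylogeny — present species at the leaves and
hypothetical ancestors at the internal nodes — from homology-evidence
scores. This vignette describes the two statistical/algorithmic phases, the
tunable parameters and their defaults, the synthetic data generator that
stands in for real proteome searches, and the numerical and design choices
a user or reviewer would want spelled out.

## Phase one: enzyme presence on a phylogeny

For each enzyme (a complete four-field EC number), presence or absence in
each species is a binary character evolving along the tree. The model is a
Bayesian network whose topology follows the phylogeny:

* a Bernoulli root prior $P(\text{present at root}) = \pi_0$ (default 0.5,
  a uniform root distribution);
* for every edge from parent $u$ to child $v$, transition probabilities
  $p_{\text{gain}} = P(x_v = 1 \mid x_u = 0)$ and
  $p_{\text{stay}} = P(x_v = 1 \mid x_u = 1)$;
* for every present species (leaf), two evidence channels: a
  reciprocal-search (BLAST-style) score $b$ and a remote-homology
  (GTG-style) shared-feature fraction $g$, entering the model through four
  class-conditional densities $f(b \mid x)$, $f(g \mid x)$ shared by all
  species and enzymes.

The reciprocal score is $-\log_{10} p_f - \log_{10} p_r$ over the forward
and reverse search p-values (floored at $10^{-300}$): symmetric,
non-increasing in each p-value, and large only when both directions are
significant. The scoring function is pluggable (`score_fun` argument of
`reciprocal_score()`) should a different combination rule be preferred.
Per (species, EC) cell the pipeline keeps the best annotated hit in each
channel; a cell with no hit scores exactly $(0, 0)$ and is treated as an
observation, not as missing data — absence of a hit is evidence of
absence.

**CPD estimation.** Transition probabilities are estimated from an
independent reference detector (in the original setting, protein-signature
scans): Fitch parsimony (`fitch_parsimony()`) extends the leaf reference
calls to all ancestors with the minimal number of gains and losses, and
per-edge transitions are counted over all reference enzymes and smoothed
with a pseudocount (default 1):
$\hat p_{\text{gain}} = (n_{01} + c)/(n_{0\cdot} + 2c)$. Fitch ties are
resolved deterministically: in the top-down pass a node takes its parent's
state whenever its state set allows it, and an ambiguous root resolves to
absent. Edges with no observation of a parent state fall back to globally
pooled counts; `mode = "global"` pools all edges unconditionally (whether
the original method pooled globally or per edge is ambiguous; per-edge is
the default here).

**Evidence densities.** The four densities are Gaussian-kernel density
estimates over scores pooled across all (species, EC) reference cells,
with Silverman's rule-of-thumb bandwidth
($0.9\,\min(\hat\sigma, \mathrm{IQR}/1.34)\, n^{-1/5}$). To keep densities
strictly positive and to damp overfitting near empty score regions, 100
regularization points uniformly spaced on $[0, \max \text{score}]$ are
appended to each class before fitting (the count is configurable).
Degenerate samples receive a floor bandwidth of $10^{-3}$ times the score
range. Density evaluation is the exact mean of Gaussian kernels — no grid
interpolation — so the naive-sum oracle in the tests is an identity check,
not an approximation check.

**Inference.** `posterior_inference()` runs belief propagation — the
polytree algorithm specialized to trees — with one upward (likelihood)
pass and one downward (marginalization) pass; messages are rescaled to
guard against underflow, which leaves marginals untouched. The tests
verify exactness against brute-force enumeration of all joint states on
hundreds of random trees at $10^{-9}$ tolerance. `presence_model()` wires
the three estimation steps and per-EC inference into a single fitted
object with `print`, `summary`, `coef`, `predict`, `plot` and `simulate`
methods.

## Phase two: gapless atom-level assembly

Every reaction is assigned a logarithmic cost
$-\ln(\max_e P(e \mid \text{data})) + b_0$ over its annotated ECs — the
enzyme with maximal support carries the reaction (the wording in the
source is contradictory on min/max; max support, i.e. minimal cost, is
used). Unannotated (spontaneous) reactions get a fixed cost. The base
cost $b_0$ defaults to 1 and the spontaneous cost to 2; the published
values are not recoverable from the available text, so these defaults are
package choices, configurable everywhere they matter.

The assembler works on the *atom graph*: nodes are (molecule, atom)
pairs, and each reaction contributes a directed edge from every mapped
substrate atom to its product atom (both directions if reversible). A
network is *gapless* when every substrate atom of every accepted reaction
is reachable from some nutrient atom through accepted reactions only.
Candidates with cost at most $\rho_{\text{accept}}$ (default: posterior
0.5) are visited in increasing order of estimated addition cost — the sum
over substrate atoms of the cheapest reaction path from the nutrients,
with accepted reactions free — re-estimated after every addition. For
each candidate, `find_gapfill_pathway()` runs a best-first search over
partial pathways kept in a priority queue ordered by accumulated cost
(each member reaction counted once): the cheapest partial pathway is
expanded through the `k` (default 5) cheapest linear reaction paths that
connect the nutrients to its first flagged atom, and the first complete
pathway popped is cost-minimal, because costs are non-negative and
monotone along expansions. Pathways costlier than
$\rho_{\text{reject}}$ (default: posterior $10^{-4}$) are pruned; a
search budget (default 10,000 expansions) bounds the queue, and budget
exhaustion is reported separately from cost rejection. On failure the
candidate is either rejected (policy `reject`, preserving gaplessness as
an invariant — certified in the tests by an independent BFS oracle) or
added with an explicit gap flag (policy `add_with_gap`). Gapfill pathway
members, once accepted, are permanent; members whose own cost exceeds
$\rho_{\text{accept}}$ carry provenance `gapfill`. All ties break by
reaction id, making reconstructions bit-reproducible.

With exhaustive settings (`k` large, generous budget) the search
provably returns the minimum-cost gapfilling set; the tests confirm this
against subset enumeration on universes of up to a dozen reactions.

## Mass balancing and atom mappings

Reaction equations are balanced by an integer program per reaction:
existing reactant coefficients are bounded below by their original values
and above by 15, water and protons may be added to either side (also up
to 15 — the source does not state whether additions share the bound;
bounding them keeps the program finite), at most one carbonic-acid unit
may be added in total, and the total coefficient sum is minimized over
elementwise balance constraints for C, H, O, N, S and P (charge is
absorbed by protons). Reactions with a reactant lacking a formula are
flagged for manual curation; molecules appearing on both sides are
flagged, since atom-transfer semantics become ambiguous. The ILP runs on
a small dense two-phase simplex written for this package (with Bland's
anti-cycling rule) under a plain branch-and-bound; a closed-form addition
repair at the original coefficients seeds the search and a single LP
relaxation bound usually certifies it immediately. Optimality is checked
in the tests against exhaustive search over the coefficient grid.

`greedy_map()` produces element-wise greedy atom mappings — valid
complete bijections whenever the reaction balances, with no claim of
chemical optimality; curated mappings can be supplied through the mapping
table instead, and `validate_mapping()` checks bijectivity and element
preservation either way. The synthetic universes track carbon only, as
published genome-scale models of this kind are fully carbon mapped.

## The synthetic data generator

`generate_universe()` builds a layered carbon-skeleton chemistry:
nutrients first, then molecules each first created by a designated
producer reaction whose substrates are already producible — so the
planted network is gapless by construction — plus carbon-conserving extra
reactions among existing molecules. Defaults are 80 molecules and 120
reactions, i.e. about 1.5 reactions per molecule. This density was chosen
to match real reaction repositories (roughly 1.4 reactions per compound):
at substantially higher densities the toy chemistry becomes promiscuous
in a way real chemistry is not, cheap spurious connectors abound, and the
atom-tracing signal that phase two exploits dissolves. H/O imbalances of
generated equations are repaired by the balancing ILP itself, which
doubles as a continuous exercise of that machinery.

`simulate_evolution()` draws presence along the tree (defaults: gain
0.05, loss 0.1 per edge, root presence 0.5), and `simulate_scores()`
draws the two evidence channels from class-conditional distributions
(`score_profile()`): gamma-shaped BLAST scores and near-one beta GTG
fractions for present enzymes, mostly no hit for absent enzymes but with
a high spurious-hit rate (0.8) whose scores overlap the present class.
The overlap is deliberate: permissive homology searches (E-value cutoff
10) hand almost every query some weak best hit, single channels are
imperfect classifiers, and only then do channel combination and
phylogenetic borrowing have room to show their value — with separable
channels every classifier tier ties and comparisons are vacuous. About
half the present BLAST scores exceed 600 and a fair share of GTG scores
exceed 0.99, so the distant-species capping perturbation has signal to
destroy. The reference detector is emulated with detection probability
0.95 and false-call probability 0.01 per cell.

What the generator does *not* emulate: real sequence-level correlation
structure (paralog families sharing hits), compartmentalization,
cofactor/currency metabolites, EC-annotation errors, and the actual score
distributions of any real search pipeline. Passing the synthetic
benchmarks therefore demonstrates correctness of the machinery and the
qualitative behavior of the method under its own assumptions — not
performance on any particular real proteome.

## Evaluation design

`perturbation_benchmark()` mirrors the published evaluation at synthetic
scale. The perturbed species form a four-leaf clade — perturbing a clade
matters, because within a clade no intact sister species remains to
rescue clade-specific enzymes, which is precisely the regime where
comparative reconstruction is claimed to help. Two perturbations are
provided: removing half of a species' query sequences
(`simulate_poor_sequencing()`, floor rounding, seeded) and capping BLAST
scores above 600 / GTG scores above 0.99 with draws from an uninformative
donor pool (`simulate_distant_species()`).

Two gold standards are used, each matched to what a tier can know. The
enzyme-detection tiers — single-channel scores, the naive Bayesian
classifier (a single-node model using only the four evidence densities
and the reference-frequency prior), and phase-one posteriors — are scored
by ROC/AUC against the simulated presence truth, averaged over the focal
clade. The phase-one/phase-two comparison is scored against the focal
species' gapless truth-network EC set (the closure of its present-EC
reactions plus spontaneous reactions), the synthetic analogue of grading
a reconstruction against a curated consensus network; phase two's curve
comes from reconstructing under a 13-point acceptance-threshold sweep.
ROC curves use threshold sweeps with ties grouped and trapezoidal
integration; `roc_auc()` agrees with the Mann-Whitney statistic and with
an independent ROC implementation in the tests.

The replicated orderings asserted in the acceptance tests (20 seeded
replicates, inequalities at the replicate-mean level) are: under poor
sequencing, phase one > naive > each single channel; under the
distant-species capping, phase two > phase one.

## Flux analyses

`flux_model()` assembles the stoichiometric matrix with direction-derived
bounds (reversible $[-M, M]$, forward $[0, M]$, $M = 1000$ by default),
exchange reactions opened only for media metabolites (uptake = negative
exchange flux), a biomass pseudo-reaction from a composition table, an
optional linear coupling enforcing CO2 production ≤ bicarbonate uptake,
and an optional ATP/O flux-ratio equality (reaction ids are model
specific and therefore supplied by the caller). A biomass component no
reaction produces leaves a metabolite row whose only entry is the biomass
reaction, so steady state forces zero biomass flux — structural
unproducibility needs no special casing. `max_yield()` reports LP maxima
with a $10^{-6}$ degeneracy tolerance (values below it are 0).

Gene knockouts follow the complex-aware rule: deleting a gene inactivates
every complex containing it; a co-member is lost only when no complex
containing it remains functional (evaluated to a fixpoint); and a
reaction is removed only when no functional gene annotated with any of
its ECs remains — functional paralogs rescue the reaction. Growth calls
normalize mutant biomass by the wild type and count a prediction correct
when it is within 0.5 of the observed normalized rate; growth predictions
(normalized rate > 0.5) classify as TP/FP and no-growth predictions as
TN/FN, cases with empty deletion sets are flagged trivial and excluded
from headline metrics. The observation is binarized at the same symmetric
0.5 (configurable), which the source leaves unspecified.

## Numerical choices and limitations

* LP/ILP: dense two-phase simplex with Bland's rule, pivot tolerance
  $10^{-9}$; branch-and-bound caps at 50,000 nodes (never approached at
  package problem sizes). Suitable for the small systems here, not for
  genome-scale LP beyond a few hundred reactions.
* Belief propagation messages are normalized per node; posteriors are
  exact, not approximate.
* Problem sizes in tests and the acceptance script (tree sizes 2–12
  species, universes of 9–120 reactions, 8–20 benchmark replicates) were
  chosen to give stable oracle comparisons and replicate means; the
  vignette-stated defaults are the study conditions everywhere.
* The gapless invariant is only guaranteed under policy `reject`; under
  `add_with_gap` the gap flags mark the reactions to curate.
* Horizontal gene transfer, tree estimation, compartmentalization,
  stereochemistry and thermodynamic direction inference are out of scope;
  direction constraints are inputs.
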