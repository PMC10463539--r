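---
title: "Path-rule classification of gene pairs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-rule classification of gene pairs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathrules)
```

This vignette documents the science implemented by `pathrules`: the data
model, the training procedure and its assumptions, every tunable parameter
with its default and rationale, the synthetic study generator, and the
design decisions taken where the method leaves room. It states no empirical
result beyond what the package's tests and `scripts/acceptance.R` compute.

## The knowledge-graph substrate

The package operates on typed knowledge graphs following the BOCK schema:
10 node types (`kg_node_types()`) and 17 edge types (`kg_metaedges()`),
each edge type (metaedge) defined by its source type, relation and target
type. Nodes carry a unique URI and optional properties (genes: `RVIS`,
`GDI`); edges carry an optional confidence score in $[0,1]$ and, for
tissue co-expression, the set of supporting tissues (`in`).

Conventions enforced by the constructor (`knowledge_graph()`):

* undirected metaedges (`GeG`, `GpG`, `GsG`, `PrP`, `BPrBP`, `MFrMF`,
  `CCrCC`) are stored once, endpoints in lexicographic URI order; duplicate
  reversed entries are merged keeping the maximum score and the union of
  tissue sets — the same collapsing convention used when protein-level
  edges are merged into gene-level edges (`collapse_to_genes()`);
* multi-edges between a node pair are allowed only across distinct
  metaedges;
* `validate_kg()` reports (never throws) every schema violation: unknown
  types, endpoint/metaedge mismatches, scores outside $[0,1]$.

GraphML is the primary exchange format; a Neo4j-style node/edge TSV dialect
is also supported with a configurable column map, because deposited TSV
headers vary. Save→load round trips are the identity on nodes, edges,
scores and properties, and re-saving a reloaded graph is byte-stable
(deterministic node and edge ordering, 15 significant digits for reals).

### Edge scoring formulas

Gene–annotation edges are scored by *functional information*: for a term
$t$ with descendant terms $t_s$ and annotated gene sets $g(\cdot)$,

$$\mathrm{FI}(t) = \frac{-\log\big(|g(t \cup \bigcup t_s)| / |g(T)|\big)}
                       {\log |g(T)|} \in [0,1],$$

rare terms scoring near 1 and ubiquitous terms near 0. The logarithm base
cancels; natural logarithms are used. A term annotating no gene (even
through descendants) has no defined FI and is an error.

Term–term `resembles` edges use SimGIC — shared-ancestor information
content over union-ancestor information content, with ancestors inclusive
of the terms — and are emitted above similarity 0.5. Sequence-similarity
edges use the BLAST score ratio, normalized by the *smaller* self-alignment
score and clamped to 1 (the cited score ratio is query-relative; the
symmetric min-normalization is this package's choice, keeping the stated
$[0,1]$ bound), gated on alignments covering at least 50% of the shorter
protein and emitted at ratio ≥ 0.2. Co-expression edges pass four gates —
tissue sample size ≥ 70, per-gene expression z-score > −3, adjusted
p < 0.01, correlation $\rho \ge 0.80$ — and are scored by the maximum
correlation across surviving tissues. The "adjusted by tissue sample size
with the Fisher transformation" refinement is not fully specified by its
sources; the package implements it as the allowance
$\operatorname{atanh}\rho \ge \operatorname{atanh}(0.80) - z_{1-\alpha}/\sqrt{n-3}$
with $\alpha = 0.05$, i.e. the correlation floor is relaxed by one
sampling standard error of Fisher's $z$; passing `fisher_alpha = NULL`
disables the allowance and applies the hard $\rho \ge 0.80$ floor.

## Path enumeration

For an ordered gene pair, `enumerate_paths()` collects all *simple* paths
(no repeated node) of at most `path_cutoff` edges, traversing edges in
either direction. Choices:

* **Anchoring.** The source gene is the one with the lower RVIS; ties
  break on lexicographic URI, and a missing RVIS sorts after a present
  one. This makes the metapath encoding of a pair deterministic.
* **Exclusions.** `Disease` and `OligogenicCombination` nodes are never
  traversed — they encode the training answer. `Phenotype` can be added to
  the exclusion set to train a phenotype-free model, since phenotype
  annotation is strongly biased toward well-studied disease genes.
* **Simplicity.** Paths never revisit nodes. Cyclic walks add no semantic
  content at cutoff 3 and would inflate path counts.
* **Tissue consistency.** A path crossing ≥ 2 coexpression edges is kept
  only if their tissue sets intersect; an edge without an `in` property is
  treated as tissue-universal (permissive default).
* **Direction encoding.** The traversal ignores edge direction but the
  metapath records it: `GaBPaG` renders two `associated` edges of which
  the second is traversed target→source, recoverable from the type
  sequence; an explicit per-step `forward` flag is kept internally so the
  encoding is never ambiguous.

Path reliability is the geometric mean of edge scores, with unscored edges
contributing 1. It is permutation-invariant and bounded by the extreme
edge scores; a zero-score edge yields reliability 0.

`path_cutoff = 3` is the default: at that depth integrated multi-network
graphs connect essentially all curated pathogenic pairs
(`connectivity_ratio()` reproduces that analysis on any graph/metaedge
subset), while depth 4 multiplies path counts without adding
discriminative signal.

## Rule mining

Each positive pair becomes a transaction whose items are the metapaths
with at least one path, weighted by the pair's label-confidence weight
$w \in (0,1]$. `apriori_mine()` performs the level-wise search with
*weighted relative support* — covered weight over total weight — which is
anti-monotone, so candidate generation is the classical join-and-prune.
Defaults `minsup_ratio = 0.2` and `max_rule_length = 3` keep rules general
(every rule is supported by at least a fifth of the positive weight) and
readable.

*Unifications* extend an itemset with the constraint that paths of two
different conditions share the node at stated intermediate positions
(endpoint genes are not unification candidates). At most one unification
per rule; candidates are all position pairs of equal node type across
exactly two conditions, and the unified pattern must itself meet
`minsup_ratio` under full matching. `closed_only()` then discards any
pattern with a strictly more specific mined pattern — a proper superset of
its conditions, or the same conditions plus a unification — of equal
support (tolerance $10^{-9}$), removing redundancy without changing
coverage semantics. Itemsets and rules are processed and returned in
lexicographic serialization order for determinism.

Rule *confidence* — the likelihood that a pair satisfying the rule is
pathogenic — is operationalized with the same imbalance-corrected formula
as the class probability below; the method's sources describe confidence
qualitatively and this is the one quantitative definition consistent with
the rest of the procedure (documented assumption).

## Threshold optimization

Raising a condition's reliability threshold filters noisy paths but can
shrink support. The fitness of thresholds $\Theta$ for rule $r$ balances
the two:

$$f(r, \Theta) = \tfrac12 \left( \frac{|C_{r|\Theta}(D)|}{|C_r(D)|}
  + 1 - \frac{\bar P_{r|\Theta}(D)}{\bar P_r(D)} \right),$$

with $f = 0$ whenever support at $\Theta$ falls below `minsup_ratio`.
Coverage and the mean path count $\bar P$ are weighted: $\bar P =
\sum_d w_d |P_r(d)| / \sum_{d \in C} w_d$ (the plain-mean printed form of
the quantity is superseded by the stated use of pair weights in both
support and path counts). For unified rules, $|P_r(d)|$ counts individual
qualifying paths per condition, not joint tuples — the un-stated
alternative would make counts quadratic in path multiplicity.

The search uses DE/best/1/bin: population 50, up to 1000 generations,
recombination constant 0.7, mutation constant drawn uniformly from
$[0.5, 1]$ each generation, box constraints $[0,1]^k$ by clipping.
Numerical choices:

* the zero vector is injected into the initial population, so the search
  always holds a feasible incumbent and the returned fitness is never
  below the baseline 0.5 when the rule is feasible at $\Theta = 0$;
* ties in the selection step go to the trial vector, letting the
  population drift across the plateaus of this piecewise-constant fitness;
* early stop after 50 generations without improvement beyond $10^{-6}$
  (the budget is otherwise fixed; the stopping rule is this package's);
* threshold comparisons use a $10^{-12}$ slack so a path exactly at a
  threshold qualifies despite floating-point representation.

## Decision-set training

Candidate rules are combined by greedy weighted set cover of

$$w(R) = \alpha \left(1 - \frac{|C_R(D)|}{|D|}\right)
       + (1-\alpha)\, \frac{|C_R(N)|}{|N|}, \qquad \alpha = 0.5,$$

adding at each step the rule with the most negative marginal weight and
stopping when none is negative; $w$ strictly decreases along the trace.
Ties break on higher class probability, then lexicographic serialization.
Selected rules carry

$$p(l_D \mid r) = \frac{|C_r(D)|}{|C_r(D)| + \frac{|D|}{|N|}\,|C_r(N)|},$$

the rule's precision corrected for class imbalance (equal to plain
precision for balanced unit-weight classes). Prediction returns the
maximum probability among matched rules, with the matched rules for
explanation. A pair matching no rule is predicted neutral with the same
formula applied to the *uncovered* training instances — the procedure's
sources say only "based on uncovered training instances"; reusing the one
calibration convention keeps the probability scale coherent (documented
choice). A model with full positive coverage would leave the uncovered-D
weight at zero and the default probability at 0.

## Training-set construction

`aggregate_positive_pairs()` keeps two-gene variant combinations at weak
evidence or better and aggregates them per gene pair with the maximum
evidence weight. The evidence-level weight map defaults to weak 0.25 /
moderate 0.5 / strong 1.0 and is configurable, the curated map not being
printed in the method's public description. `select_holdout_pairs()` scans
pairs recent-first and accepts gene-disjoint pairs of at least moderate
evidence, up to `k = 15`.

`build_neutral_pairs()` reproduces the healthy-cohort pipeline: MAF ≤ 0.03
filter, per-individual per-gene maximum deleteriousness score, within-
individual pair generation, ≥ 50 carriers, pair maximum score > 3.57 (a
fixed quartile-derived constant, configurable rather than recomputed),
different chromosomes or ≥ 10 kb separation (measured between the closest
gene boundaries — the anchor being this package's choice), pair score =
mean over carriers of the smaller gene score, descending rank, top
$100 \times |D|$. Weights map scores monotonically into $(\epsilon, 1]$ by
min–max normalization with floor $\epsilon = 0.05$; constant scores map
to 1.

## The synthetic study generator

`simulate_kg()` builds a schema-conformant KG plus labelled pair sets so
the whole pipeline is testable without external downloads. It emulates:

* per-metaedge background edges (Erdős–Rényi style within the type
  constraints) with Beta(2, 2) confidence scores and random tissue sets on
  coexpression edges;
* genes with standard-normal RVIS (exercising pair anchoring);
* planted metapath patterns: each full pattern is inserted for a positive
  pair with probability `p_pos` and for a negative pair with probability
  `p_neg`, with planted edge scores uniform in the pattern's reliability
  range (default $[0.7, 1]$), so planted path reliabilities respect the
  range; fresh intermediate term nodes per instance, existing genes reused
  at intermediate gene positions;
* *decoy* partial patterns: every single condition of a multi-condition
  pattern is additionally planted with probability `decoy_prob` in any
  pair, of either class. This emulates a property of real biology that
  matters to the decision-set stage: neutral pairs frequently share
  *partial* context (one common annotation, one similarity edge) while the
  full coordinated pattern stays rare. Without decoys, the proper subsets
  of a planted conjunction would cover almost no negatives, the greedy
  cover would select the subsets first, and the conjunction — whose
  coverage is contained in its subsets' — could never enter the model;
  no parameter of the classifier could change that, because it is a
  property of set cover itself.

Defaults define the study conditions used throughout the tests and the
acceptance script: 100 genes (plus smaller term/phenotype/disease layers),
150 positive and 1500 negative pairs (a 1:10 imbalance — a desk-scale
stand-in for the 1:100 of full-scale studies, keeping the imbalance
correction active while path enumeration for all pairs stays in seconds),
`p_pos = 0.8`, `p_neg = 0.002`, `decoy_prob = 0.05`, and three planted
patterns: a shared protein domain (`GuPDuG`), a shared-family/shared-
complex conjunction (`GbPFbG & GfPCfG`), and a unified molecular-function
pattern (`GaMFaG & GaMFrMFaG`, `MF1 = MF2`). Background gene–gene edge
counts are kept low (degree ≈ 4) deliberately: dense gene–gene layers make
every 3-hop gene-chain metapath frequent, which explodes the frequent-
itemset lattice without adding signal. What the generator does *not*
emulate: scale-free degree distributions, realistic ontology depth and
annotation correlation, and literature-driven annotation bias — so passing
tests demonstrate algorithmic correctness and end-to-end signal recovery,
not performance on real curated data.

Everything is a pure function of the configuration seed; regeneration is
byte-identical.

## Evaluation utilities

`stratified_cv()` re-runs the *entire* training workflow inside each
training fold — mining, threshold optimization, selection — so no test
pair influences rule discovery. (Whether full-scale studies re-mine per
fold or mine once globally is not documented; per-fold re-mining is the
leak-free choice and the global alternative can be had by mining up front
and passing the rules explicitly.) Path enumeration is per-pair and
therefore shared across folds. Curves are averaged vertically on a fixed
101-point grid with linear interpolation; areas use the trapezoid rule,
and the per-fold area spread is reported alongside. The operating
threshold maximizes $\sqrt{\text{sensitivity} \times \text{specificity}}$.

The topology-only baseline is a random walk with restart (default restart
0.7) on the direction-agnostic graph minus the excluded node types, with
uniform degree normalization across metaedges (the cited technique's exact
heterogeneous normalization is unspecified), iterated to an $L_1$
tolerance of $10^{-10}$, walkers at degree-zero nodes restarting; the
pair score averages the two directions. `metapath_influence()` compares
rule-confidence distributions with a one-tailed Wilcoxon rank-sum test per
metapath, Bonferroni-corrected, reporting rank-biserial correlations
$2U/(n_1 n_2) - 1$.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
the default 150/1500-pair study for end-to-end recovery (three seeds), a
40/300-pair study for module-level checks, 60/600 pairs for
cross-validation behaviour, random ≤ 30-node graphs against the exhaustive
path oracle, and ≤ 50-transaction instances against the brute-force
itemset oracle. These sizes were chosen so each property is measured at
full precision while any single test file runs in well under a minute
(end-to-end recovery: a few minutes).

## Known limitations

* Mining is exhaustive up to `max_rule_length`; on dense graphs with many
  frequent metapaths the itemset lattice grows combinatorially. The
  support threshold is the only pruning device.
* Unifications span exactly two conditions; constraints across three or
  more conditions, or several unifications per rule, are out of scope.
* Rule probabilities are imbalance-corrected precisions, not calibrated
  probabilities; no recalibration is applied.
* The DE fitness treats path counts per condition independently for
  unified rules; joint-tuple counting would penalize unification-heavy
  rules differently.
* The RWR baseline uses uniform edge weights; score-weighted transition
  probabilities are a straightforward variant but not what the baseline
  represents here.
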