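---
title: "The quantitative efficacy-toxicity network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The quantitative efficacy-toxicity network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etnet)
```

## The problem

Traditional herb-pair prescriptions combine an efficacious but toxic
principal herb with a helper herb intended to enhance the effect and
attenuate the toxicity. `etnet` quantifies that compatibility on a
molecular network: given the chemical components of the two herbs, the
genes/proteins those components act on, a protein-protein interaction
(PPI) graph, gene expression from the disease context, toxic-target
annotations for the principal herb, and a list of pathogenic genes, it
scores *gene transmission chains* (GTCs) — paths along which a component's
influence propagates from its direct target to a pathogenic gene — and
ranks cross-herb component pairs by a synergy score. Throughout, the
principal herb is labelled `LGT` and the helper herb `JQC`; these are
just column values, and any pair of labels works.

## Stage 1 — ADMET screening of components

Components are screened with rule-based drug-likeness criteria: molecular
weight at most 500 Da, at most 5 hydrogen-bond donors, at most 10
acceptors, at most 10 rotatable bonds, high gastrointestinal absorption,
and no high hERG-inhibition risk. All numeric bounds are *inclusive*:
the packaged 97-row component table contains passing rows that sit
exactly on a bound (quercetin with 5 donors, dibutyl phthalate with 10
rotatable bonds), so a strict reading would contradict its own screened
output. The hERG rule excludes only the `high_risk` class;
`medium_risk` and `ambiguous` components pass. Components with missing
screened properties are rejected as incomplete rather than crashing the
run. Component identity for the shared/unique partition is the `id`
column, never the display name, whose case and spacing vary between
sources. The partition reports both the multiset count (rows across both
herbs; 97 for the packaged table) and the number of distinct chemical
entities (96, since kaempferol occurs in both herbs).

## Stage 2 — the component-target network

Screened components and their targets form an undirected bipartite C-T
graph. Betweenness centrality is computed on the full bipartite graph
with unit edge lengths and normalized by $(n-1)(n-2)/2$, so every value
lies in $[0,1]$; this choice (rather than a one-mode projection) is what
guarantees the synergy term $s_3 = x\,y$ below stays in $[0,1]$. Degree
summaries are reported per side and overall.

## Stage 3 — initial influence coefficients by matrix decomposition

The influence of component $i$ on target $j$ is estimated from the
target-gene expression matrix $A$ (targets $\times$ samples) with a
structured low-rank decomposition:

1. **Truncated SVD.** $A_L = U_L \Sigma_L V_L^{\top}$ is the rank-$L$
   Eckart-Young-Mirsky approximation — the Frobenius-optimal rank-$L$
   matrix, with error $\lVert A - A_L\rVert_F = \sqrt{\sum_{i>L}\sigma_i^2}$.
   Set $W = U_L$. By default $L = M$, the number of components, which is
   accurate and cheap.
2. **Structured mixing matrix.** For each component $i$, the rows of $W$
   are partitioned into $W_c$ (the targets adjacent to $i$ in the C-T
   network) and $W_r$ (all other targets); after reordering, column $i$
   of the mixing matrix has the structure $y_i = [\tilde y_i; 0]$. The
   estimate takes the last $L-M+1$ right singular vectors $X_0$ of
   $W_r$ and sets $\tilde y_i$ to the first left singular vector of
   $W_c X_0 X_0^{\top}$, i.e. of $W_c$ projected onto the orthogonal
   complement of the dominant row space of $W_r$. When $L = M$, $X_0$
   degenerates to the last right singular vector $x$ of $W_r$ and
   $\tilde y_i = W_c x$ directly. The adjacency-based row partition is
   the one component-specific structure the data offer; nothing else
   distinguishes the sources.
3. **Sources.** $S = Y^{\dagger} A_L$ via the Moore-Penrose
   pseudoinverse. When the supports of the components' target sets are
   disjoint and noise is absent, this recovers the planted factors
   exactly (up to per-column scale and sign) — the property the
   synthetic generator is built to exercise.

Per-edge coefficients are read off $Y$: $a_{ij} = \max(Y_{ji}, 0)$,
then max-normalized within each component, so every emitted $a$ lies in
$[0,1]$, is scale-free, and cannot flip sign with the SVD's inherent
sign ambiguity (which is additionally pinned by forcing each singular
vector's largest-magnitude entry positive). Edges whose target has no
expression row get $a = 0$ with a warning.

**Preprocessing.** For measured expression (counts, intensities) the
matrix is log2(x+1)-transformed and row-centered before decomposition —
the standard variance-stabilizing choice. Both steps are arguments:
factor-model data such as the synthetic generator's
$A = Y_{\text{true}} S_{\text{true}} + \varepsilon$ carries signal in
its scale and sign, so recovery analyses run with `transform = "none",
center = FALSE`.

## Stage 4 — chain enumeration by deterministic Dijkstra

Gene-gene Pearson correlations $s_{u,x}$ (log2 scale,
pairwise-complete samples; constant genes get 0 with a warning) weight
the PPI graph with edge costs

$$c_{u,x} = \max(1 - |s_{u,x}|,\ \varepsilon), \qquad \varepsilon = 10^{-6},$$

so strongly co-expressed neighbours are cheap to traverse and all costs
stay strictly positive, as Dijkstra's correctness requires. Pairs with
no recorded correlation cost 1. A `hop` mode with unit costs (plain
BFS distances) is provided for sensitivity analysis, and each run's
metadata records which mode produced it.

For each (component target, pathogenic gene) pair with finite distance,
exactly one minimal-cost simple path is returned. Two tie-break rules
make the output fully deterministic: equal-distance frontier nodes are
settled in lexicographic gene-symbol order, and among equal-cost
predecessors the lexicographically smaller symbol wins. One chain per
pair — not $k$-shortest paths — keeps chain counts equal to the number
of reachable source-sink pairs.

## Stage 5 — chain scoring

Nodes are labelled: `[JQC]` for helper-herb targets, `[TOX]` for toxic
targets of the principal herb; a node may carry both. With $s_k$ the
correlation between consecutive chain genes:

* $v_0$ — sum of the initial influence coefficients $a$ onto the first
  gene;
* $v_1 = v_0 \prod_k s_k$ — the fully propagated ("spread") value;
  $\text{loss} = v_0 - v_1$;
* $v_2$ — toxicity-truncated value: with $X$ the *first* `[TOX]` node,
  $\text{tox\_begin}$ is the partial product up to $X$ and
  $v_2 = \text{tox\_fin} = \text{tox\_begin}\cdot s_{X,\text{end}}$;
* $v_3$ — helper-shortcut value, identically with the *first* `[JQC]`
  node;
* $v = v_1 - v_2 + v_3$ — the final score. Chains scoring strictly
  above the cohort median are retained (an all-equal cohort retains
  nothing; even counts use the midpoint median).

Three conventions are forced by the packaged 50-row worked example:
only the earliest occurrence of each label enters $v_2$/$v_3$ (the
table has single scalar tox/JQC columns even for multi-labelled
chains); the shortcut correlation from a *terminal* labelled node to
itself is 1, so a terminal `[TOX]` makes $v_2$ equal the full spread
value; and a dual-labelled node contributes to *both* $v_2$ and $v_3$.
Correlations are signed — products may be negative — with an `abs_cor`
switch for absolute-value propagation. The helper shortcut uses the
literal direct correlation $s_{J,\text{end}}$ without renormalizing
the skipped steps.

**Monotonicity of the penalty.** "The later the toxic node, the smaller
the accumulated toxicity" holds in two senses. The partial product
$\text{tox\_begin}$ is strictly nonincreasing in the toxic position for
step correlations in $(0,1]$. The truncated value $v_2$ additionally
depends on the direct toxic-to-terminal correlation; for arbitrary,
mutually inconsistent correlation values it can move either way, but
when non-adjacent correlations obey the multiplicative consistency the
propagation model itself assumes (exact for Gaussian Markov chains:
$s_{X,E} = \prod$ of the step correlations between $X$ and $E$), $v_2$
is nonincreasing across all placements. The test suite checks both
statements under that consistent-correlation model.

## Stage 6 — synergy ranking of component pairs

For principal-herb component $A$ (targets $T_A$, $a = |T_A|$),
helper component $B$ ($b = |T_B|$) and toxic set $X$:

$$s_1 = \frac{|T_A \cap T_B| - c}{a + b}, \qquad c = |T_A \cap X|,$$

read as intersection *cardinalities* (the only dimensionless reading);
$c$ counts $A$'s toxic targets among its own target set, with a
configurable variant restricting $c$ to the overlap. $s_1$ is min-max
scaled across all evaluated pairs to $s_2 \in [0,1]$ (a degenerate
all-equal range yields $s_2 = 0$ with a warning), $s_3 = x\,y$
multiplies the two components' normalized betweenness values, and pairs
are ranked by $s = s_2 + s_3$ (descending, ties broken
lexicographically).

## Toxic-target selection

A gene qualifies as a toxic target when its adverse reactions span at
least 2 distinct organ systems *and* its literature reports total
strictly more than 10. Both thresholds are arguments; the strict
inequality follows the "greater than" reading of the rule.

## The synthetic generator

`make_synthetic_study(seed)` emulates a complete study at desk scale:
by default 6 components per herb with 1 shared (realistic for a
two-herb pair), 60 target genes, a 150-gene preferential-attachment PPI
graph (connected by construction), 200 expression samples,
within-block correlation $\rho = 0.6$ for non-target genes, 10% toxic
targets and 10% pathogenic genes, and factor-model noise
$\sigma = 0.1$. Target-gene expression follows
$A = Y_{\text{true}} S_{\text{true}} + \sigma\varepsilon$ with
target-disjoint primary blocks, so the decomposition has a well-posed
recovery target; the shared component keeps the same target block in
both herbs, as the same compound would. Toxicity annotations are
constructed so the multi-system/report-count rule recovers exactly the
planted toxic set, and decoys violate exactly one clause. A
misspecified generator (`make_block_expression`) with pure block
covariance and no factor structure probes robustness. All randomness
flows from the single seed; the caller's RNG state is saved and
restored, and equal seeds give byte-identical written studies.

What the generator does *not* emulate: real expression marginals
(library-size variation, overdispersed counts, batch effects),
scale-free degree exponents of curated PPI databases, correlated
annotation noise, or target-prediction error in the C-T edges. Passing
tests therefore demonstrate correctness of the algorithms under the
model's own assumptions, not performance on measured data.

## Numerical choices

* Edge-cost clamp $\varepsilon = 10^{-6}$ keeps perfectly correlated
  pairs at a positive cost.
* SVD sign ambiguity is fixed by making each vector's
  largest-magnitude entry positive; row-permutation equivariance of
  the mixing estimate is tested.
* `MASS::ginv` supplies the pseudoinverse (tolerance-based rank
  decisions); all-zero mixing columns (components with no expressed
  targets) are flagged rather than inverted.
* Undefined correlations (constant genes, unknown pairs) are 0, which
  in cost space means an uninformative cost of 1.
* Median retention uses `stats::median` (midpoint rule) and strict
  inequality.
* Problem sizes in the test suite — graphs of at most 8 nodes for
  exhaustive path enumeration, 20x15 matrices for spectral checks,
  1000-chain cohorts for order statistics — are chosen so every
  brute-force oracle is exact and the whole suite runs in well under a
  minute.

## Limitations

* Influence coefficients are identified only up to the row-partition
  rule; overlapping target sets between principal-herb components blur
  the block structure and degrade recovery (quantified by the
  misspecified generator).
* Chain scoring ignores transmission loss mechanisms beyond
  correlation products, and the helper shortcut deliberately skips
  intermediate attenuation.
* One chain per source-sink pair means parallel near-optimal routes
  are invisible to the score.
* The worked-example fixtures validate the scoring arithmetic and the
  screening rules; database-scale quantities (tens of thousands of
  coefficient edges, millions of chains) require the corresponding
  external expression, interaction and annotation resources and are
  out of scope here.
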