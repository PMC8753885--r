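---
title: "coremet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coremet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coremet` identifies disease core genes from a three-state expression study
(one reference state, two disease subtypes) and a metabolic reaction table.
This vignette records the model, its assumptions, the parameters that
matter, what the synthetic generator does and does not emulate, and the
design choices made where the design was genuinely open.

## The model and its assumptions

**Expression contract.** All statistics assume log2-scale expression, so a
log2 fold change is a difference of group means. Mixed array/RNA-seq inputs
must be log-transformed upstream; the package performs missing-value
filtering (> 50% missing deleted), kNN imputation and probe collapsing but
no normalisation.

**DEG calling.** For a contrast the moderated statistic is
`d = (mean2 − mean1)/(s + s0)`, `s` the pooled standard error and `s0` a
fixed quantile (default 0.05) of the gene-wise standard errors. `s0` as a
quantile rather than the original coefficient-of-variation search keeps the
regulariser simple and configurable; it protects near-constant genes from
exploding `d`. The q-value at each `|d|` is the permutation-expected count
of larger permuted `|d|` divided by the observed count, capped at 1 and
monotonised; when the label space `choose(n, n1)` is at most 10,000 all
assignments are enumerated, which makes small-sample q-values exact.

**Network reconstruction.** Two genes interact when the product of one
gene's reaction is the substrate of another gene's reaction. The rule is
strictly cross-reaction: isozymes and complex members of one reaction are
*not* connected by default (`intra_reaction = TRUE` restores cliques per
reaction). Currency metabolites are excluded before chaining because their
ubiquity would create biologically meaningless hubs; the default list
(water, CO2, the adenylate pool, phosphate, protons, redox carriers,
coenzyme A) is deliberately open-ended and config-overridable. Compartment
suffixes (`[c]`, `_m`, ...) are stripped before matching; reversible
reactions play both substrate and product roles.

**Module mining (MCODE).** Vertex weight is the highest core number `k` of
the node's closed neighbourhood times the density of that highest k-core;
nodes under the degree cutoff weigh 0. Seeds are taken in descending weight,
neighbours join when their weight is at least `(1 − node_score_cutoff)`
times the seed weight, complexes must contain a 2-core, the haircut reduces
each complex to its 2-core, and a complex-level k-core filter (default
order 3) plus a size filter (default 4) follow. One consequence of the
published weight definition is worth knowing: two cliques joined by a
*direct* bridge edge merge into one complex, because each bridge endpoint
inherits the full weight of its own clique; separation requires a low-weight
connector node between them. Ties (equal weights, equal scores) are always
broken lexicographically by gene id, so mining is deterministic.

**Differential co-expression.** `W(M) = |H − H'|`, with `H` the mean
absolute pairwise Pearson correlation over the module's gene pairs in one
state. `W ∈ [0, 1]`, is symmetric in the state order, and is exactly 0 when
the states carry identical data. Zero-variance genes contribute correlation
0 with a warning rather than an error, because a single flat gene should not
abort a module.

**Permutation nulls.** Both module statistics are referenced to 1000
size-conserved (same cardinality) and 1000 degree-conserved (same degree
multiset) random node sets, `p = 1 − t/n_rand` with `t` the count of random
sets *strictly* below the observed score — ties count against significance.
Random sets are not required to be connected: the null constrains only size
and degrees. When an exact degree pool is exhausted (high-degree nodes are
often unique) the match relaxes to the nearest degree on a log2 scale and
the relaxation is reported. Failed statistic evaluations on a random set are
redrawn, never silently dropped.

**MRF module score.** Per-gene expression difference `E` defaults to
`Φ⁻¹(1 − p)` of a Welch t-test, with `p` clipped to `[1e−16, 1 − 1e−16]`
and `E` to `[0, 8.2]` — the conventional transform in MRF subnetwork
scoring; `|t|` is available as an alternative. The smoothness sum runs over
*induced module edges* whose endpoints are both non-DEGs (an MRF is
neighbour-based); summing over all non-DEG pairs is available behind
`g2_pairs = "all"`. `b` is the count of all induced module edges, and the
degrees `d` come from the full network. Mutual information uses
equal-frequency binning (`⌈log2 n⌉ + 1` bins by default) on the contrast's
pooled samples, in bits; the plug-in estimate carries an upward
`O(bins²/n)` bias, which is harmless here because MI enters only as a
non-negative weight common to all modules being ranked. The Gibbs
temperature and normalising constant of the underlying distribution never
enter any computation — only score comparisons matter — and the identity
`MRFms = −F(E)` is enforced by test against an independently coded energy
function.

**Core genes.** `B(x)` counts known-gene pairs `(s, t)` with
`dist(s,x) + dist(x,t) = dist(s,t)` (unweighted hops), which is equivalent
to `x` lying on at least one shortest path; the equivalence is guarded by an
exhaustive path-enumeration oracle in the tests. Candidates are risk-module
genes with `B > 0` (known genes inside the module remain eligible). The top
`⌊0.25·n⌋` ranks are selected with boundary ties *included*: the rank rule
is ambiguous under ties and dropping tied genes would be arbitrary, so the
selection can exceed the quartile count. With fewer than four candidates the
cut degenerates and all candidates are returned with a warning.

**Classification.** No SVM library is assumed to be available, so the
radial-kernel SVM is implemented as a least-squares SVM: identical kernel
and `C`/`gamma` semantics, squared loss instead of hinge loss, training by
one symmetric linear solve — exact and deterministic, which matters for
byte-identical pipeline reruns. Training uses class-balanced per-sample
weights (the `class.weights` option of classical SVMs); without them every
leave-one-out fold is unbalanced against the left-out sample's class and the
permuted-label AUC sits far below 0.5. Features are standardised on the
training fold only; `gamma` defaults to `1/(n_features · var)` of the
standardised training matrix. The AUC is computed from the pooled left-out
decision values (each fold contributes one score). Two caveats are inherent
to the protocol rather than to this implementation: (i) with strongly
clustered features, label-permuted LOOCV AUC is pessimistically biased below
0.5 (the left-out sample's "vote" is missing from its own cluster); (ii) a
one-sample Wilcoxon of `n_reps` random AUCs against the single core-gene AUC
is not calibrated under the null — it rejects whenever the core AUC misses
the random median — so its p-value is evidence of separation only when the
core set was chosen independently of the comparison, and the tests assert
null calibration on the rank of the core AUC among the random AUCs instead.

## Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| `fc_threshold` | 1 | log2 units | conventional 2-fold cut |
| `q_threshold` | 0.05 | FDR | conventional |
| `s0_quantile` | 0.05 | quantile of gene SEs | moderation strength |
| `knn_k` | 10 | neighbours | usual kNN-imputation choice |
| `degree_cutoff` / `k_core` / `node_score_cutoff` | 2 / 3 / 0.2 | — | standard MCODE setting |
| `min_module_size` | 4 | nodes | small modules are uninformative for pair statistics |
| `n_rand` | 1000 | draws per null | p-granularity 0.001 |
| `alpha` | 0.05 | per null | both nulls must pass |
| `quartile` | 0.25 | fraction | top-quartile core cut |
| `n_reps` | 100 | random sets | comparison protocol |
| `C` / `gamma` | 1 / `1/(p·var)` | SVM | library-default policy |

## The synthetic world

The generator emulates the statistical structure the pipeline assumes, at a
desk scale (defaults: 200 genes, 3 states × 25 samples):

* a planted 8-gene module wired as a clique through private metabolites, so
  it survives any 3-core filter;
* module-gene correlation induced by a single shared latent factor per
  state — always positive definite — at 0.9 in the disease state and 0.0
  elsewhere; DEGs get a +2 log2 shift (0.5 sd noise) in that state;
* 8 known disease genes attached as degree-1 spokes to four module hubs
  (3/3/1/1), which forces every known-pair geodesic through the hubs and
  makes `B` computable in closed form: a hub with `c` spokes among `K`
  known genes links `C(c,2) + c(K − c)` pairs (18/18/7/7 at the defaults),
  every other gene links 0 — the planted core genes are the two 18s;
* a background graph whose hub nodes span the module genes' degree range.
  This last point is load-bearing: degree-conserved null sets are drawn from
  the pools at the module's degrees, and if the module genes were the unique
  high-degree nodes the null would collapse onto the module itself. Real
  metabolic networks are heavy-tailed with thousands of nodes, so rich pools
  are the realistic case; 200 genes with ~20% background hubs of degree
  5–14 reproduces that property at test scale.

Not emulated: RNA-seq counts and library-size effects, probe-level artifacts,
compartmentalised metabolism, gene-protein-reaction boolean logic, and the
size of a genome-scale network. A green recovery test therefore establishes
that the statistics find the structure they define, under their own
assumptions — not that the pipeline reproduces any real-data gene list.

## Numerical choices and degenerate inputs

* Exactly-at-threshold rows (50% missing) are kept: only "more than" the
  threshold deletes.
* Zero-distance imputation neighbours are averaged directly (restoring
  masked duplicates exactly); otherwise weights are `1/distance` over
  RMS-scaled co-observed columns.
* `s = 0` with unequal means yields a huge finite `d` (denominator floored
  at machine epsilon), never a division error.
* `E`: `p = 1` maps to `E = 0`; `p ≤ 1e−16` caps at 8.2 (`qnorm`'s value at
  the clip).
* Constant vectors have MI 0 by definition; rank ties in binning are broken
  by position (deterministic).
* Modules with no induced G2 edges get `term2 = 0`; `b = 0` cannot then
  contribute a 0/0.
* All orderings (seeds, module ids, gene lists, reports) are
  lexicographically tie-broken; one global seed fans out to per-stage seeds
  by hashing the stage name, so stages are independently reproducible and
  `run-all` is byte-identical under a fixed seed.

## Known limitations

* The MCODE re-implementation follows the published algorithm, not any
  particular plugin build; complex counts on real networks may differ from
  versioned plugin output (fluff post-processing is not implemented).
* The permutation nulls treat random sets as unconstrained node sets;
  requiring connectedness would yield a different (stricter) null.
* The LS-SVM replaces hinge loss by squared loss; decision values differ
  from a C-SVC's, though AUCs on separable and null data behave identically
  in the test suite.
* Mutual information at the default bin rule is upward-biased for small
  samples; comparisons across modules are unaffected, absolute MI values
  should not be interpreted.
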