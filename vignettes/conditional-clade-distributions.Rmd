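---
title: "Conditional clade distributions: models, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional clade distributions: models, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdtree)
```

## The problem

A Bayesian phylogenetic analysis leaves you with a large sample of rooted
binary tree topologies. Two tasks recur constantly: estimating the
posterior probability of individual topologies (for credible sets,
information content, concordance analyses), and condensing the sample into
one summary tree. The raw sample distribution handles both badly once the
number of taxa grows, because topology space grows super-exponentially and
every individual topology is sampled zero or one times.

Conditional clade distributions solve this by assuming *conditional
independence across clades*: given that a clade occurs, the way it splits
is independent of everything outside the clade. Under that assumption a
distribution over all topologies factorizes into per-clade conditional
split distributions on a clade graph, and the sample is only needed to
estimate those local conditionals, which requires far fewer observations
than estimating whole-topology frequencies.

## Objects and conventions

* Taxon sets are ordered character vectors; a clade is a bit vector over
  that order, stored as a `"0"`/`"1"` key string. String order on keys is
  the canonical order used everywhere a deterministic order is needed
  (split sides, tie-breaks).
* A topology (`tree_topology`) is the map from each non-leaf clade to its
  child clades. Identity is clade-set identity: branch lengths, node
  labels and rotations are ignored, matching how topology frequencies are
  counted. Trees parsed from files keep the taxon order of the first tree
  (so BEAST translate indices remain stable); comparisons across sources
  should remap to a common order first.
* A `tree_sample` merges identical topologies with multiplicities;
  `tally()` produces the sufficient statistics `f(C)`, `f(S)`, `k`.
* Burn-in is a fraction of trees removed from the head of the file (in
  file order, before merging), default 0.1. Non-binary or unrooted input
  trees are rejected rather than silently accommodated; the only place an
  unresolved tree is produced is the greedy consensus output.

## The three parametrizations

**CCD1** uses observed clade splits: `Pr(S | C) = f(S)/f(C)`. It has one
parameter per observed split and reproduces Monte Carlo clade frequencies
exactly: `clade_probability()` of a CCD1 equals `f(C)/k` for every
observed clade (a property the test suite checks to 1e-12).

**CCD0** uses only observed clades. Its split set is the *expansion*: all
splits `{C1, C2}` with `C1`, `C2`, `C1 ∪ C2` observed, found by hashing
complements of observed subsets (quadratic in the number of observed
clades; this is the scalability hot spot and is documented as such). Its
defining contract is that a displayed tree's probability is proportional
to the product of its clades' Monte Carlo credibilities `f(C)/k`. We
realize the contract with one bottom-up pass of subtree sums

    z(leaf) = 1,   z(C) = (f(C)/k) * Σ_{S ∈ S(C)} z(C1) z(C2)

and set `Pr({C1,C2} | C) = z(C1) z(C2) / Σ_S z(C1') z(C2')`. Telescoping
the product along any displayed tree shows `Pr(T) = Π f(C)/k / z(X)`, so
probabilities are proportional to the clade-credibility product and sum to
one by construction. The enumeration oracle in the tests verifies both
facts on every fixture.

**CCD2** conditions each split additionally on the sibling clade (the
root has a unique ROOT context), the core structure of a subsplit DAG
populated by sample frequencies. It has the most parameters and therefore
needs the most samples; on the worked five-taxon example it degenerates to
exactly the three sampled topologies.

The displayed-tree sets are always nested, CCD2 ⊆ CCD1 ⊆ CCD0, because
each model's split vocabulary is a restriction of the next.

## Queries

All queries are dynamic programs over the clade graph (clade-in-context
vertices for CCD2) and are linear in clades plus splits:

* `tree_probability()` multiplies conditional split probabilities along
  the tree, in log space; absent clades or splits give probability 0, not
  an error.
* `count_trees()` runs `t(C) = Σ_S t(C1) t(C2)`. Counts can exceed the
  range where doubles are exact, so the recursion runs in exact
  base-1e7 arbitrary-precision arithmetic implemented in the package
  (about forty lines; no big-integer package ships with this stack); the
  result is numeric when it fits into 2^53 and a decimal digit string
  otherwise.
* `entropy()` uses the per-clade recursion
  `H*(C) = Σ_S −Pr(S)(log Pr(S) − H*(C1) − H*(C2))` with natural
  logarithms — required so that the number equivalent `Ne = exp(H)` is an
  effective count of topologies.
* `clade_probability()` propagates `Pr(root) = 1` top-down; the split
  instances pointing at a clade are disjoint events within one tree, so
  their contributions add.
* `sample_trees()` draws a split at the root and recurses, so the
  sampling distribution equals `tree_probability()` (checked by a
  chi-square goodness-of-fit test at fixed seed).
* `enumerate_trees()` expands the graph into every displayed topology. It
  is deliberately implemented as a direct recursive expansion, independent
  of the dynamic programs, so it can serve as the oracle that the DPs are
  tested against; a cap (default 1e6) guards against combinatorial
  explosion.
* `detect_outliers()` implements the advisory burn-in check: a topology
  sharing no nontrivial clade with the rest of the sample keeps CCD1/CCD2
  probability `multiplicity/k`, a vast overestimate for a stray burn-in
  state. We flag such topologies when they are the minority side of the
  sample, and report once-observed clades/splits; nothing is removed
  automatically, and we invent no thresholds beyond "observed once".

## Point estimators and tie-breaking

`mcc_tree()` (sample-restricted argmax of the clade-credibility product),
`greedy_consensus()`, `map_tree()` (CCD-MAP via the max-product recursion,
backtracked), and `mscc_tree()` (max-sum of clade credibilities over a
CCD0) are all deterministic. Where the procedures are classically
"ties broken arbitrarily", we fix explicit orders so results are
reproducible across runs and platforms:

* MCC: higher multiplicity first, then canonical clade-set order.
* Greedy consensus: frequency descending, then clade size descending,
  then canonical key order. The output may be unresolved; the test suite
  contains a hand-traced five-taxon example where an accepted clade blocks
  both resolvers of its parent and a polytomy remains. Majority clades
  (`f(C)/k > 0.5`) are always present since they are mutually compatible
  and processed first.
* CCD-MAP / MSCC: canonical split order within a clade.

Products of clade credibilities are taken over nontrivial clades only
(trivial clades contribute a factor of one); MSCC sums likewise exclude
trivial clades, which shifts every tree's score by the same constant and
changes no argmax. Scores attached to a `point_estimate` always equal a
recomputation of the criterion on the returned tree; annotations can be
Monte Carlo frequencies (`support = "montecarlo"`) or CCD clade
probabilities (`support = "ccd"`) — identical for a CCD1, different in
general for a CCD0.

The "highest sampled posterior density" topology is available only as the
pass-through `max_density_tree()` when per-state densities are supplied;
it is excluded from the CLI defaults.

## Evaluation metrics

Against an enumerable reference ("golden") distribution we provide: MAE of
tree probabilities over the reference support; MRE within the 50%/95%
credible sets (prefixes of the probability ordering, ties by canonical
key) and over all reference clades; the rank of the reference's top tree
in an estimate's ordering (enumerated when the support is within the cap,
otherwise ranked within a stated candidate pool — reference support plus
the estimate's MAP tree); mean absolute probability difference between
replicates over the union of supports; and rooted Robinson-Foulds
distances between point estimates, always divided by two, with the
relative version dividing by the `n − 2` nontrivial clades of the true
tree.

## Synthetic data and what it does (not) show

`yule_topology()` draws topologies by uniform random joins, the topology
law of the pure-birth process; divergence times are never generated
because every computation in scope is topology-level. `random_ccd()`
builds a ground-truth CCD graph from the splits of a *correlated* pool —
a Yule base tree followed by a random walk of rooted
nearest-neighbour-interchange moves (`nni_topology()`) — with symmetric
Dirichlet conditional probabilities at each clade. The NNI walk matters:
independent random topologies on 8+ taxa share almost no clades, giving
truths supported on a handful of mutually disjoint trees, which no
clade-factorized model can smooth usefully; an NNI walk produces the
clade-sharing structure that consecutive MCMC samples actually have.

`synth_posterior()` draws i.i.d. trees from the truth and nests subsample
prefixes within a replicate, mirroring how subsamples of one chain relate.
It does *not* emulate MCMC autocorrelation, multimodal posteriors, or
model misspecification; passing benchmarks on these fixtures shows that
the estimators behave as designed when the truth really factorizes or is
supported on NNI-connected neighbourhoods, not that CCDs capture every
real posterior.

The benchmark harness (`run_benchmark()`) runs at desk scale: taxon counts
near 6–10, subsample sizes of a few to a few dozen, truths with entropy
roughly 2–5 nats (for the small-sample accuracy experiment we use
30-tree NNI pools with Dirichlet concentration 5, giving entropies around
4 nats and supports of order 10²–10³ topologies). The golden reference is
the generating distribution itself — exact, rather than a giant reference
MCMC run, which is the reason these experiments are cheap. In this regime
the characteristic orderings are reproduced: CCD0 beats the raw sample
distribution at subsample sizes 3–30 on diffuse truths, and estimate
errors shrink with sample size.

## Numerical choices and degenerate inputs

* All probability products run in log space; zero probabilities short-
  circuit to 0.
* Split probability normalization is validated to 1e-9 on load and
  construction (`validate_ccd()`); equality-style test tolerances are
  1e-12 where arithmetic is exact in rationals.
* Two-taxon trees are legal everywhere (the unique cherry has an empty
  nontrivial clade set); duplicate taxon labels and empty post-burn-in
  samples are rejected.
* CCD0 subtree sums are computed in plain doubles: at the package's
  intended scale (tens of taxa) the sums stay far from underflow. For
  very large, very diffuse samples a log-space version would be the first
  upgrade.
* The JSON-lines serialization stores clades as hexadecimal bitmasks
  (taxon i = bit i−1) and revalidates every invariant on load. CCD2
  graphs are not serialized: they are cheap to rebuild from the sample.

## Known limitations

* The conditional-independence assumption biases all CCDs; with enough
  uncorrelated samples the raw sample distribution eventually wins, and
  the package makes no attempt to select the best model automatically
  (information criteria would need a tree-ESS estimate, which is an open
  problem).
* Split expansion is quadratic in observed clades; fine for thousands of
  clades, not for millions.
* Parameters are always populated from observed frequencies; maximum
  likelihood or variational fitting of CCD parameters is out of scope.
* Summary trees are topologies only: annotating divergence times onto
  them is an independent second step that this package does not perform.
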