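---
title: "Agreement forests, the Red-Blue algorithm, and its LP certificates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement forests, the Red-Blue algorithm, and its LP certificates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agreeforest)
```

## The problem

Two rooted binary phylogenetic trees on the same species frequently
disagree — different genes, different data types, or genuinely reticulate
evolution (hybridization, horizontal transfer) all produce conflicting
topologies.  A standard way to quantify the conflict is the rooted
subtree-prune-and-regraft (rSPR) distance: the minimum number of times a
subtree must be cut off and reattached elsewhere to turn one tree into the
other.  Computing it is NP-hard, but it equals the optimum of the Maximum
Agreement Forest (MAF) problem: delete a minimum number of edges from each
tree so that the resulting two forests consist of pairwise isomorphic
trees.  The equality requires a technical adjustment first — both trees
receive a new root with an extra leaf (labelled `rho` here) as its
sibling, which pins the original roots into a common component.
`augment_rho()` applies it, and the command-line front end does so by
default.

A solution is encoded as a partition $\mathcal{P}$ of the leaf labels in
which every component is *compatible* (its minimal spanning subtrees in
the two trees are isomorphic, equivalently all its rooted triples resolve
identically in both trees) and no two components *overlap* (the node sets
spanned by two components are disjoint in both trees).  The cost is
$|\mathcal{P}| - 1$, the number of cuts.

## The Red-Blue algorithm

`red_blue()` implements a combinatorial 2-approximation.  It maintains a
partition that never overlaps in the second tree $T_2$ — i.e., always the
leaf sets of a forest obtained by deleting $T_2$-edges — and repeatedly:

1. finds a lowest *root of infeasibility* $u$ in $T_1$: a node witnessing
   that the current partition restricted to the leaves below $u$ is
   incompatible (condition a), overlapping (condition b), or compatible
   but not extendable by any leaf of a component that leaves the subtree
   (condition c);
2. colors the leaves: blue below $u$'s left child, red below the right
   child, white elsewhere;
3. refines the partition in three stages —
   `make_rb_compatible()` cuts components at lowest $T_2$-nodes where red
   and blue meet incompatibly, `make_splittable()` cuts components whose
   color classes overlap in $T_2$, and `split_components()` replaces each
   multicolored component by its color classes, except that a tricolored
   *top* component containing a compatible tricolored triple receives a
   more careful *special split* (two parts when every tricolored triple is
   compatible, four parts — cut at the $T_2$-lca of its red/blue part —
   otherwise);
4. records, when one exists, a pair of red/blue leaves whose components
   can be merged back without breaking feasibility restricted to the
   current red and blue leaves (`find_merge_pair()`).  All recorded merges
   are applied once, at the very end (`merge_components()`), which keeps
   the accounting of the certificate simple.

Each iteration permanently settles the partition of its red and blue
leaves (they are never separated again), which bounds the number of
iterations by the number of leaves.

### The certificate

Alongside the partition, the algorithm maintains an integral dual solution
for a set-partition LP relaxation: a value $y_v \le 0$ on internal nodes
of both trees, decremented at the iteration's root of infeasibility and at
every cut node selected by the refinement stages (the *starred* nodes),
and an indicator $z_A$ on current components.  The *load* of a leaf set
$L$ is $\sum_{v \in V[L] \setminus \mathcal{L}} y_v + \sum_{A : A \cap L
\neq \emptyset} z_A$; the maintained dual keeps the load of every
compatible set at most 1 (`verify_dual_feasibility()` checks this by
exhaustive enumeration on small instances).  Weak duality then makes $D =
\sum_v y_v + |\mathcal{P}| - 1$ a lower bound on the optimum, and the
update schedule guarantees $2\Delta D \ge \Delta P$ in every iteration,
hence `cuts` $\le 2D \le 2\,\mathrm{OPT}$.  The bound is checked at run
time; the per-run certificate is returned in `$certificate`.

```{r}
pr <- augment_rho(tree_pair("((a,(b,c)),d);", "(((a,c),d),b);"))
res <- red_blue(pr)
res$cuts
res$certificate$dual_objective
format_forest(pr, res$forest)
```

## The LP relaxations

The relaxation behind the certificate has one variable per compatible leaf
set: cover every leaf exactly once, use every internal node of either tree
at most once, minimize total weight minus one.
`solve_lp_enumerated()` builds it explicitly (practical to roughly a dozen
leaves); its integer restriction, computed exactly by branch-and-bound
over the same compatible sets, equals the MAF optimum and cross-checks the
independent edge-deletion oracle `exact_maf()`.

`build_compact_lp()` reformulates the same LP with polynomially many
variables.  Every compatible set $L$ with $|L| \ge 2$ is encoded as an
out-arborescence on ordered leaf pairs: the pair $(i_1, i_2)$ stands for
the tree node identified by the lca of $i_1$ and $i_2$, the root of the
encoding takes the smallest labels of the two subtrees below the root of
the restricted tree, and left/right arcs recurse into those subtrees
(`arborescence_of()`).  A flow-style cone description — equal left and
right outflow at every internal pair, outflow at least inflow — captures
exactly the nonnegative combinations of such arborescences; per-leaf
accounting ties arc inflow at $(i,i)$ plus a singleton weight to 1, and
occupancy constraints replay the internal-node packing constraints by
attributing to each arc the chain of tree nodes from its head's lca
(inclusive) up to its tail's lca (exclusive), with the lca of a pair
itself charged to the pair's root excess.  This attribution counts every
spanned internal node exactly once per arborescence, which is what makes
the occupancy constraint the exact image of the packing constraint; the
equivalence of the two formulations is exercised wholesale by the test
suite (exhaustive up to five leaves plus seeded random instances) rather
than assumed.

```{r}
solve_lp_enumerated(pr, integer_opt = FALSE)$optimum
solve_compact_lp(pr)$optimum
```

### Integrality gap

The approximation guarantee implies the relaxation's integrality gap is at
most 2.  The package ships a synthetic eight-leaf instance
(`worked_examples()$gap54`, found by a randomized search over small
instances maximizing the ratio, and verified exactly) whose optimum is 5
while the LP optimum is exactly 4 — certified in exact rational arithmetic
by `certify_lp_value()`, which rationalizes the solver's primal and dual
basic solutions and re-checks them in integer arithmetic.  The sweeps run
by the test suite and the acceptance script never exceed this ratio, and
the theory bounds it by 2.

```{r}
gap <- integrality_gap(worked_examples()$gap54)
c(opt = gap$opt, lp = gap$lp, gap = gap$gap)
```

## The exact oracle

`exact_maf()` enumerates $k$-subsets of the first tree's edges for
increasing $k$ and returns the first induced leaf-set partition that is a
feasible agreement forest.  Enumerating deletions in one tree suffices
because the components of any feasible partition span pairwise-disjoint
node sets in the first tree, so the partition arises from some edge
deletion set there; the tests also confirm symmetry under swapping the two
trees.  The inner loop is compiled (Rcpp) with leaf sets as bit masks; the
guard `max_labels = 14` keeps it at desk scale.

## Synthetic instances

`random_tree()` draws uniformly from the $(2n-3)!!$ labelled rooted
binary topologies by sequential random insertion.  `random_spr_pair()`
applies a chosen number of random rooted SPR moves (prune a non-root
subtree, regraft onto an edge outside it other than its original
position), guaranteeing the rSPR distance — and hence the rho-augmented
MAF optimum — is at most the number of moves performed; the generator
reports the number actually applied.  These generators emulate topological
conflict only: no branch lengths, no sequence-level noise, no estimation
error in the input trees.  Passing tests therefore validate the
combinatorial machinery on clean topologies, not robustness to trees
inferred from data.

Default study conditions used by the tests and the acceptance script: the
exhaustive sweep of all 225 ordered 4-leaf topology pairs, 500 seeded
random pairs on 6–10 leaves for the approximation guarantee, 200 seeded
random pairs on up to 8 leaves for the LP equivalence and gap, and 100
SPR-perturbed pairs with up to 3 moves on 10 leaves.  These sizes keep the
brute-force oracle exact and the enumerated LP buildable while exercising
every code path (all three infeasibility conditions, both special-split
shapes, and merge conditions (a)–(c) all occur within them).

## Numerical and design choices

* **LP solving.**  A small dense two-phase primal simplex (Dantzig
  pricing, Bland fallback against cycling) solves all models; optima are
  compared at tolerance $10^{-6}$—$10^{-7}$, and the gap fixture is
  re-verified in exact rational arithmetic.  An independent solver
  (`pracma::linprog`) cross-checks optima in the tests where it is
  numerically able.
* **Determinism.**  Wherever the theory allows an arbitrary choice, the
  implementation fixes one for reproducibility: the lowest root of
  infeasibility is the first in post-order of $T_1$; candidate cut nodes
  are taken in post-order of $T_2$; components are always scanned in
  order of their smallest label; the merge search tests its three
  conditions in order and returns the lexicographically smallest leaf
  pair.  Left/right of a node follow the written child order and carry no
  meaning — the tests include a child-swap symmetry check.
* **Degenerate inputs.**  A singleton leaf set spans exactly its own
  leaf (so singleton components occupy their leaf and nothing else,
  matching the LP's leaf constraints); empty sets are compatible,
  splittable and cover nothing; sets of size at most two are always
  compatible.
* **Strictness.**  Non-binary input is rejected at parse time; the
  reserved label may only be introduced once.

## Limitations

The exact oracle and the enumerated LP are exponential and guarded by size
caps; beyond them only the approximation (with its per-run certificate)
and the compact LP remain available.  The algorithm targets instances of a
few hundred leaves comfortably; it uses straightforward polynomial data
structures rather than the asymptotically optimal machinery.  Only the
classical setting — two rooted binary trees — is supported: no unrooted or
multifurcating variants, no more than two trees, no branch lengths.
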