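# agreeforest

Maximum agreement forests and certified rSPR distances for rooted binary
phylogenetic trees.

Two rooted binary trees on the same taxa — say, from two genes — often
conflict.  The rooted subtree-prune-and-regraft (rSPR) distance measures
the conflict and lower-bounds the number of reticulation events needed to
reconcile the trees, and it equals the optimum of the Maximum Agreement
Forest (MAF) problem: partition the leaf labels into the fewest components
$\mathcal{P} = \{A_1,\dots,A_k\}$ such that every $A_i$ induces the same
subtree topology in both trees (*compatibility*: all rooted triples of
$A_i$ resolve identically) and no two components' spanned node sets
intersect in either tree (*non-overlap*); the cost is $k - 1$, the number
of edges cut.  The rSPR correspondence requires augmenting both trees with
a root leaf `rho` first; the package does this on request
(`augment_rho()`) and the CLI does it by default.

MAF is NP-hard.  The package provides:

* **`red_blue()`** — a combinatorial 2-approximation.  Each iteration
  finds a lowest node of the first tree witnessing infeasibility, colors
  the leaves red/blue/white by its two subtrees, refines the partition
  until it is feasible for the red-blue leaves, and occasionally records a
  pair of components to merge back at the end.  Crucially, the run also
  builds a *dual-fitting certificate*: integer values on tree nodes whose
  feasible-by-construction dual objective $D$ satisfies
  `cuts ≤ 2·D ≤ 2·OPT`, so every answer ships with a machine-checked
  lower bound.
* **`exact_maf()`** — brute-force exact optimum for small instances
  (edge-deletion enumeration, compiled inner loop).
* **`solve_lp_enumerated()` / `solve_compact_lp()`** — the set-partition
  LP relaxation behind the certificate, both as an explicit model over all
  compatible leaf sets and as an equivalent compact arborescence-flow
  formulation solvable at polynomial size; `integrality_gap()` compares
  the exact optimum against the relaxation.  A bundled synthetic instance
  achieves the worst gap we observe, exactly 5/4.
* **`random_tree()` / `random_spr_pair()`** — uniform random topologies
  and pairs a bounded number of SPR moves apart, for simulation studies.
* **`exec/agreeforest`** — a command-line front end
  (`approx | exact | lp | gap | simulate | sweep`).

## A worked example

```r
library(agreeforest)
pr  <- augment_rho(tree_pair("((a,(b,c)),d);", "(((a,c),d),b);"))
res <- red_blue(pr)
res
#> Red-Blue agreement forest: 3 components, 2 cuts in 1 iterations
#> dual lower bound: 1  (cuts <= 2 x lower bound)
format_forest(pr, res$forest)
#> [1] "a\tc"    "b"       "d\trho"
exact_maf(pr)$opt_cuts
#> [1] 1
solve_compact_lp(pr)$optimum
#> [1] 1
```

The algorithm cuts twice ({a,c}, {b}, {d,rho}); its certificate proves no
solution beats 1 cut, so the answer is within the guaranteed factor 2 —
and the exact solver confirms the optimum (the rSPR distance) is 1: moving
the subtree `b` alone turns one tree into the other.  The LP relaxation
also values the instance at 1.

Same thing from the shell:

```sh
$ exec/agreeforest approx t1.nwk t2.nwk
cuts: 2
lower_bound: 1
guarantee: cuts <= 2 (= 2 x lower_bound)
forest:
  a	c
  b
  d	rho
```

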