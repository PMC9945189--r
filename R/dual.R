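# Dual-fitting certificate.  The algorithm maintains, next to the
# partition, an integral dual solution for the set-partition LP: y-values
# on internal nodes of both trees (only ever decremented by starred
# steps) and z = 1 on exactly the current components.  Feasibility means
# every compatible leaf set carries a load of at most 1; the dual
# objective D = sum(y) + |P| - 1 is a lower bound on the optimal number
# of cuts, and the algorithm guarantees cuts <= 2 D.

#' Fresh dual solution for a pair
#'
#' All y-values zero; z indicates the single all-label component.
#'
#' @param pair a `maf_pair`.
#' @return a list with `y1`, `y2` (per-node values for each tree) and
#'   `z_components` (the current partition).
#' @export
dual_init <- function(pair) {
  list(y1 = numeric(pair$t1$N), y2 = numeric(pair$t2$N),
       z_components = canonical_partition(list(seq_len(pair$n))))
}

#' Replay one iteration's dual updates
#'
#' Decrements y at the iteration's root of infeasibility in the first
#' tree and at every starred node of the second tree, and points z at the
#' post-iteration components.  End-of-run merges leave the dual
#' untouched.
#'
#' @param pair a `maf_pair`.
#' @param dual a dual solution (see [dual_init()]).
#' @param trace one element of a [red_blue()] run's `traces`.
#' @return the updated dual solution.
#' @export
apply_iteration_updates <- function(pair, dual, trace) {
  dual$y1[[trace$coloring$u]] <- dual$y1[[trace$coloring$u]] - 1
  for (v in c(trace$star_rb, trace$star_split, trace$star_special)) {
    if (!length(pair$t2$children[[v]])) stop("starred node ", v, " is a leaf of T2")
    dual$y2[[v]] <- dual$y2[[v]] - 1
  }
  dual$z_components <- trace$P3
  dual
}

#' Load of the dual solution on a leaf set
#'
#' The sum of y over the internal nodes spanned by `L` in either tree,
#' plus the number of current components intersecting `L`.  Dual
#' feasibility requires load at most 1 on every compatible set; the
#' initial dual puts load exactly 1 on every nonempty set.
#'
#' @param pair a `maf_pair`.
#' @param dual a dual solution.
#' @param L label subset.
#' @return numeric load.
#' @export
dual_load <- function(pair, dual, L) {
  L <- as_label_idx(pair, L)
  if (!length(L)) return(0)
  s1 <- spanned_nodes(pair, L, 1L); s1 <- s1[s1 > pair$t1$ntip]
  s2 <- spanned_nodes(pair, L, 2L); s2 <- s2[s2 > pair$t2$ntip]
  zsum <- sum(vapply(dual$z_components,
                     function(A) length(intersect(A, L)) > 0L, logical(1)))
  sum(dual$y1[s1]) + sum(dual$y2[s2]) + zsum
}

#' Verify dual feasibility
#'
#' Exhaustive mode enumerates every compatible subset of the labels
#' (practical up to about 12 labels) and checks that each carries load at
#' most 1.  Sampled mode checks a seeded random sample of compatible
#' sets, all current components, and the leaf sets of all T2 subtrees.
#'
#' @param pair a `maf_pair`.
#' @param dual a dual solution.
#' @param mode `"exhaustive"` or `"sampled"`.
#' @param n_sample sample size for sampled mode.
#' @return list with `ok` and, when violated, the offending sets and
#'   their loads.
#' @export
verify_dual_feasibility <- function(pair, dual, mode = c("exhaustive", "sampled"),
                                    n_sample = 200L) {
  mode <- match.arg(mode)
  sets <- if (mode == "exhaustive") {
    enumerate_compatible_sets(pair, cap = 12L)
  } else {
    cand <- c(dual$z_components,
              lapply(seq_len(pair$t2$N), function(v) {
                A <- labels_below(pair, v, 2L)
                if (is_compatible(pair, A)) A else NULL
              }),
              lapply(seq_len(n_sample), function(i) {
                k <- sample(seq_len(pair$n), 1L)
                A <- sort(sample(seq_len(pair$n), k))
                if (is_compatible(pair, A)) A else NULL
              }))
    cand[!vapply(cand, is.null, logical(1))]
  }
  bad <- list(); loads <- numeric(0)
  for (L in sets) {
    ld <- dual_load(pair, dual, L)
    if (ld > 1 + 1e-9) {
      bad[[length(bad) + 1L]] <- L
      loads <- c(loads, ld)
    }
  }
  list(ok = length(bad) == 0L, violations = bad, loads = loads)
}

#' Certificate of the 2-approximation for a run
#'
#' Computes the dual objective D over the pre-merge partition, checks the
#' guarantee 2 D >= cuts of the returned forest, and reports the implied
#' lower bound on the optimum.
#'
#' @param dual a dual solution (after the run).
#' @param forest the final partition.
#' @param pairslist the run's recorded merge pairs.
#' @return list with `dual_objective`, `cuts`, `pairs`, `lower_bound` and
#'   `ratio_bound`.
#' @export
dual_certificate <- function(dual, forest, pairslist) {
  D <- sum(dual$y1) + sum(dual$y2) + length(dual$z_components) - 1L
  cuts <- length(forest) - 1L
  if (2 * D < cuts) stop("certificate violated: cuts = ", cuts, " > 2D = ", 2 * D)
  list(dual_objective = D, cuts = cuts, pairs = length(pairslist),
       lower_bound = D, ratio_bound = if (D > 0) cuts / D else 1)
}
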