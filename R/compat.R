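# Combinatorial predicates on a tree pair: compatibility, cover, overlap,
# splittability, feasibility.  These are the vocabulary of every step of
# the approximation algorithm and of the LP formulations.

# ---- partitions -----------------------------------------------------------

#' Build a partition of the label set
#'
#' A partition (the algorithm's evolving solution, and the final agreement
#' forest) is a list of disjoint nonempty label subsets covering the whole
#' label universe.  Internally components are sorted integer index vectors
#' and components are ordered by their smallest label, which fixes a
#' deterministic scan order everywhere.
#'
#' @param pair a `maf_pair`.
#' @param components list of label subsets (character labels or indices).
#' @return canonicalized list of integer vectors, class `maf_partition`.
#' @export
as_partition <- function(pair, components) {
  comps <- lapply(components, function(A) as_label_idx(pair, A))
  if (any(lengths(comps) == 0L)) stop("empty component")
  all_idx <- sort(unlist(comps))
  if (length(all_idx) != pair$n || !identical(all_idx, seq_len(pair$n))) {
    stop("components must partition the label set")
  }
  canonical_partition(comps)
}

canonical_partition <- function(comps) {
  comps <- lapply(comps, function(A) sort(as.integer(A)))
  comps <- comps[order(vapply(comps, `[`, integer(1), 1L))]
  class(comps) <- "maf_partition"
  comps
}

# pretty label form, used by print methods and the CLI
format_partition <- function(pair, P) {
  vapply(P, function(A) paste(pair$labels[A], collapse = " "), character(1))
}

partition_key <- function(P) {
  paste(vapply(P, function(A) paste(A, collapse = ","), character(1)),
        collapse = "|")
}

same_partition <- function(P, Q) {
  identical(partition_key(canonical_partition(P)), partition_key(canonical_partition(Q)))
}

# ---- triple and set compatibility ----------------------------------------

# In a binary tree every 3-set of leaves has a unique "cherry" pair whose
# lca lies strictly below the lca of the triple; a triple is compatible
# exactly when the two trees agree on that pair.
cherry_pair <- function(tree, tips3) {
  l12 <- lca_node(tree, tips3[c(1L, 2L)])
  l13 <- lca_node(tree, tips3[c(1L, 3L)])
  l23 <- lca_node(tree, tips3[c(2L, 3L)])
  d <- tree$depth[c(l12, l13, l23)]
  c(1L, 2L, 3L)[which.max(d)]   # 1 => {x1,x2}, 2 => {x1,x3}, 3 => {x2,x3}
}

#' Compatibility of a leaf triple
#'
#' Three leaves are compatible when both trees resolve them the same way,
#' i.e. the pair that forms a cherry in the restricted three-leaf topology
#' is the same in both trees.
#'
#' @param pair a `maf_pair`.
#' @param x1,x2,x3 three distinct labels (or label indices).
#' @return logical flag.
#' @export
triple_compatible <- function(pair, x1, x2, x3) {
  idx <- as_label_idx(pair, c(x1, x2, x3))
  if (length(idx) != 3L) stop("labels must be distinct")
  cherry_pair(pair$t1, pair$tip1[idx]) == cherry_pair(pair$t2, pair$tip2[idx])
}

# Definitional form (lca biconditional over all orderings); retained as an
# independent oracle for the cherry test.
triple_compatible_def <- function(pair, x1, x2, x3) {
  idx <- as_label_idx(pair, c(x1, x2, x3))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 3, 1))
  for (p in perms) {
    t1pair <- lca_node(pair$t1, pair$tip1[idx[p[1:2]]])
    t1all <- lca_node(pair$t1, pair$tip1[idx])
    t2pair <- lca_node(pair$t2, pair$tip2[idx[p[1:2]]])
    t2all <- lca_node(pair$t2, pair$tip2[idx])
    lhs <- t1pair != t1all   # strict descendant (pair lca is always <= triple lca)
    rhs <- t2pair != t2all
    if (lhs != rhs) return(FALSE)
  }
  TRUE
}

# Canonical form of the minimal spanning subtree of a tip set, unary nodes
# suppressed.  Equal strings <=> isomorphic leaf-labelled rooted topologies.
restricted_canonical <- function(tree, tips) {
  k <- length(tips)
  if (k == 0L) return("")
  insel <- rep(FALSE, tree$ntip); insel[tips] <- TRUE
  rec <- function(v) {
    ch <- tree$children[[v]]
    if (!length(ch)) return(if (insel[v]) tree$tip_label[[v]] else NA_character_)
    parts <- character(0)
    for (c0 in ch) {
      if (any(tree$desc[c0, insel])) parts <- c(parts, rec(c0))
    }
    if (length(parts) == 1L) return(parts)
    paste0("(", paste(sort(parts), collapse = ","), ")")
  }
  rec(lca_node(tree, tips))
}

#' Compatibility of a label subset
#'
#' A leaf set is compatible when the minimal subtrees spanning it in the
#' two trees are isomorphic (equivalently, all its triples are
#' compatible).  Sets of size at most two are always compatible.  The
#' implementation compares canonical forms of the restricted topologies;
#' the all-triples definition is exercised as an oracle in the tests.
#'
#' @param pair a `maf_pair`.
#' @param L label subset.
#' @return logical flag.
#' @export
is_compatible <- function(pair, L) {
  L <- as_label_idx(pair, L)
  if (length(L) <= 2L) return(TRUE)
  identical(restricted_canonical(pair$t1, pair$tip1[L]),
            restricted_canonical(pair$t2, pair$tip2[L]))
}

# brute-force all-triples version (test oracle)
is_compatible_triples <- function(pair, L) {
  L <- as_label_idx(pair, L)
  if (length(L) <= 2L) return(TRUE)
  cmb <- utils::combn(L, 3L)
  for (j in seq_len(ncol(cmb))) {
    if (!triple_compatible(pair, cmb[1L, j], cmb[2L, j], cmb[3L, j])) return(FALSE)
  }
  TRUE
}

# ---- cover and overlap ----------------------------------------------------

#' Does a label set cover a node?
#'
#' `A` covers node `v` of tree `t` when `v` lies on a path between two
#' leaves of `A` in that tree.
#'
#' @param pair a `maf_pair`.
#' @param A label subset.
#' @param v node id.
#' @param t which tree the node belongs to (1 or 2).
#' @return logical flag.
#' @export
covers <- function(pair, A, v, t = 1L) {
  v %in% spanned_nodes(pair, A, t)
}

# Resolve a node-universe argument U into per-tree node-id lists.
# U may be "all", "V1", "V2", or list(v1 = ids, v2 = ids).
resolve_U <- function(pair, U) {
  if (is.character(U) && length(U) == 1L) {
    switch(U,
      all = list(v1 = seq_len(pair$t1$N), v2 = seq_len(pair$t2$N)),
      V1  = list(v1 = seq_len(pair$t1$N), v2 = integer(0)),
      V2  = list(v1 = integer(0), v2 = seq_len(pair$t2$N)),
      stop("unknown node universe: ", U))
  } else if (is.list(U)) {
    list(v1 = as.integer(U$v1), v2 = as.integer(U$v2))
  } else stop("U must be \"all\", \"V1\", \"V2\" or list(v1=, v2=)")
}

#' Do two label sets overlap in a node universe?
#'
#' `A` and `A2` overlap in `U` when some node of `U` is spanned by both.
#' `U` defaults to all nodes of both trees; `"V1"`/`"V2"` restrict to one
#' tree, and `list(v1=, v2=)` gives explicit node ids.
#'
#' @param pair a `maf_pair`.
#' @param A,A2 label subsets.
#' @param U node universe.
#' @return logical flag.
#' @export
overlap <- function(pair, A, A2, U = "all") {
  u <- resolve_U(pair, U)
  (length(intersect(intersect(spanned_nodes(pair, A, 1L),
                              spanned_nodes(pair, A2, 1L)), u$v1)) > 0L) ||
  (length(intersect(intersect(spanned_nodes(pair, A, 2L),
                              spanned_nodes(pair, A2, 2L)), u$v2)) > 0L)
}

#' Does a partition overlap in a node universe?
#'
#' True when two distinct components overlap in `U`.
#'
#' @inheritParams overlap
#' @param P a partition (see [as_partition()]).
#' @return logical flag.
#' @export
partition_overlaps_in <- function(pair, P, U = "all") {
  u <- resolve_U(pair, U)
  for (t in 1:2) {
    uv <- if (t == 1L) u$v1 else u$v2
    if (!length(uv)) next
    tr <- tree_of(pair, t)
    seen <- rep(FALSE, tr$N)
    for (A in P) {
      s <- span_nodes(tr, tips_of(pair, A, t))
      s <- s[s %in% uv]
      if (any(seen[s])) return(TRUE)
      seen[s] <- TRUE
    }
  }
  FALSE
}

# ---- K-compatibility, splittability, feasibility --------------------------

#' K-compatibility of a partition
#'
#' A partition is K-compatible when the intersection of every component
#' with `K` is a compatible set.
#'
#' @param pair a `maf_pair`.
#' @param P a partition.
#' @param K label subset.
#' @return logical flag.
#' @export
is_K_compatible <- function(pair, P, K) {
  K <- as_label_idx(pair, K)
  for (A in P) if (!is_compatible(pair, intersect(A, K))) return(FALSE)
  TRUE
}

#' Splittability of a component under a coloring
#'
#' `A` is splittable when its three color classes `A` \eqn{\cap} R, B, W do
#' not overlap pairwise in the second tree, so that `A`'s tree in the
#' T2-forest can be cut into unicolored pieces.  Unicolored sets are
#' vacuously splittable.
#'
#' @param pair a `maf_pair`.
#' @param A label subset.
#' @param coloring a coloring from [make_coloring()].
#' @return logical flag.
#' @export
is_splittable <- function(pair, A, coloring) {
  A <- as_label_idx(pair, A)
  cls <- list(intersect(A, coloring$R), intersect(A, coloring$B),
              intersect(A, coloring$W))
  cls <- cls[lengths(cls) > 0L]
  if (length(cls) <= 1L) return(TRUE)
  spans <- lapply(cls, function(x) span_nodes(pair$t2, tips_of(pair, x, 2L)))
  tot <- unlist(spans)
  !anyDuplicated(tot)
}

#' Feasibility of a partition
#'
#' A feasible agreement forest: every component compatible and no two
#' components overlapping anywhere (in either tree).
#'
#' @param pair a `maf_pair`.
#' @param P a partition.
#' @return logical flag.
#' @export
is_feasible <- function(pair, P) {
  for (A in P) if (!is_compatible(pair, A)) return(FALSE)
  !partition_overlaps_in(pair, P, "all")
}

#' K-feasibility of a partition
#'
#' `P` is K-feasible when it is (K plus any single extra leaf)-compatible
#' and no two components overlap in the second tree or in the nodes of the
#' first tree spanned by `K`.  Full-label-set K-feasibility coincides with
#' [is_feasible()].
#'
#' @param pair a `maf_pair`.
#' @param P a partition.
#' @param K label subset.
#' @return logical flag.
#' @export
is_K_feasible <- function(pair, P, K) {
  K <- as_label_idx(pair, K)
  for (A in P) {
    AK <- intersect(A, K)
    if (!is_compatible(pair, AK)) return(FALSE)
    # only w in A \ K can change A's intersection with K u {w}
    for (w in setdiff(A, K)) {
      if (!is_compatible(pair, c(AK, w))) return(FALSE)
    }
  }
  U <- list(v1 = spanned_nodes(pair, K, 1L), v2 = seq_len(pair$t2$N))
  !partition_overlaps_in(pair, P, U)
}
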