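# The Red-Blue algorithm: a 2-approximation for maximum agreement forest.
#
# The algorithm maintains a partition P of the labels that never overlaps
# in the second tree (so P is always the set of leaf sets of a forest
# obtained by deleting edges from T2).  Each iteration picks a lowest
# "root of infeasibility" u in T1, colors the leaves (B = left subtree of
# u, R = right subtree, W = the rest) and refines P in three stages
# (Make-(RuB)-compatible, Make-Splittable, Split) until u is no longer a
# root of infeasibility; a merge opportunity between two of the freshly
# created components is recorded when one exists, and all recorded merges
# are applied at the very end.  A dual solution (y on internal nodes, z on
# components) is decremented alongside and certifies cuts <= 2 * OPT.

# ---- coloring -------------------------------------------------------------

#' Color the leaves from a node of the first tree
#'
#' Blue = leaves below the left (first-written) child of `u`, red = below
#' the right child, white = everything else.  Left/right follow stored
#' child order and carry no semantics; swapping them is a symmetry of the
#' algorithm.
#'
#' @param pair a `maf_pair`.
#' @param u an internal node id of the first tree.
#' @return a list with integer label-index sets `R`, `B`, `W` and nodes
#'   `u`, `u_l`, `u_r`, class `maf_coloring`.
#' @export
make_coloring <- function(pair, u) {
  ch <- pair$t1$children[[u]]
  if (length(ch) != 2L) stop("node ", u, " is not an internal node of T1")
  B <- labels_below(pair, ch[[1L]], 1L)
  R <- labels_below(pair, ch[[2L]], 1L)
  W <- setdiff(seq_len(pair$n), c(R, B))
  structure(list(R = R, B = B, W = sort(W), u = u,
                 u_l = ch[[1L]], u_r = ch[[2L]]),
            class = "maf_coloring")
}

# colors present in a component (subset of c("R","B","W"))
colors_of <- function(A, coloring) {
  out <- character(0)
  if (length(intersect(A, coloring$R))) out <- c(out, "R")
  if (length(intersect(A, coloring$B))) out <- c(out, "B")
  if (length(intersect(A, coloring$W))) out <- c(out, "W")
  out
}

# ---- roots of infeasibility ----------------------------------------------

#' Find the lowest root of infeasibility
#'
#' A node u of T1 witnesses the current partition's infeasibility when
#' (a) some component restricted to the leaves below u is incompatible,
#' (b) two components overlap in the nodes of T1 spanned by those leaves,
#' or (c) the partition is compatible below u but some component that
#' leaves the subtree cannot be extended by any of its outside leaves
#' without becoming incompatible.  Ancestors of a root of infeasibility
#' are roots of infeasibility too; the scan runs in post-order of T1 so
#' the first hit is a lowest one (ties broken by post-order position).
#'
#' @param pair a `maf_pair`.
#' @param P a partition that does not overlap in the second tree.
#' @return `NULL` when `P` is feasible; otherwise a list with the node
#'   `u` and the first condition `cond` in `c("a","b","c")` it satisfies.
#' @export
lowest_root_of_infeasibility <- function(pair, P) {
  if (partition_overlaps_in(pair, P, "V2")) {
    stop("partition overlaps in V2; algorithm invariant violated")
  }
  t1 <- pair$t1
  for (u in t1$postorder) {
    if (!length(t1$children[[u]])) next
    Lu <- labels_below(pair, u, 1L)
    cond <- root_condition(pair, P, Lu)
    if (!is.null(cond)) return(list(u = u, cond = cond))
  }
  NULL
}

# which of (a),(b),(c) holds at a node with leaf set Lu; NULL if none
root_condition <- function(pair, P, Lu) {
  compat_ok <- TRUE
  for (A in P) {
    if (!is_compatible(pair, intersect(A, Lu))) { compat_ok <- FALSE; break }
  }
  if (!compat_ok) return("a")
  U <- list(v1 = spanned_nodes(pair, Lu, 1L), v2 = integer(0))
  if (partition_overlaps_in(pair, P, U)) return("b")
  for (A in P) {
    inside <- intersect(A, Lu)
    outside <- setdiff(A, Lu)
    if (length(inside) < 2L || !length(outside)) next
    all_bad <- TRUE
    for (w in outside) {
      if (is_compatible(pair, c(inside, w))) { all_bad <- FALSE; break }
    }
    if (all_bad) return("c")
  }
  NULL
}

#' Classify the iteration case
#'
#' With `u` a lowest root of infeasibility, the start-of-iteration
#' partition falls in exactly one of three situations: case 1 (one
#' tricolored component, not (RuB)-compatible, with a white leaf above
#' the T2-lca of its red/blue part), case 2 (two bicolored components,
#' one without red and one without blue), case 3 (one tricolored
#' (RuB)-compatible component with no compatible tricolored triple).
#' These mirror conditions (a), (b), (c) of the root of infeasibility.
#'
#' @param pair a `maf_pair`.
#' @param P the start-of-iteration partition.
#' @param coloring from [make_coloring()] at a lowest root of
#'   infeasibility.
#' @return list with `case` in `c("case1","case2","case3")` and the
#'   witness component(s).
#' @export
classify_case <- function(pair, P, coloring) {
  ncol_ <- vapply(P, function(A) length(colors_of(A, coloring)), integer(1))
  multi <- which(ncol_ >= 2L)
  if (length(multi) == 2L) {
    A1 <- P[[multi[1L]]]; A2 <- P[[multi[2L]]]
    a1r <- length(intersect(A1, coloring$R)) > 0L
    a2r <- length(intersect(A2, coloring$R)) > 0L
    if (a1r == a2r) stop("two multicolored components sharing a color; not a lowest root")
    AB <- if (a1r) A2 else A1
    AR <- if (a1r) A1 else A2
    if (length(intersect(AR, coloring$B))) {
      stop("red-side component contains blue leaves; case classification failed")
    }
    return(list(case = "case2", A_B = AB, A_R = AR))
  }
  if (length(multi) != 1L) {
    stop("expected one tricolored or two bicolored components, found ",
         length(multi), " multicolored")
  }
  A0 <- P[[multi]]
  cols <- colors_of(A0, coloring)
  if (length(cols) != 3L) {
    stop("single multicolored component is bicolored; contradicts a lowest root")
  }
  RB <- c(coloring$R, coloring$B)
  if (!is_compatible(pair, intersect(A0, RB))) {
    uhat <- lca_of(pair, intersect(A0, RB), 2L)
    above <- setdiff(A0, labels_below(pair, uhat, 2L))
    if (!length(above)) {
      stop("case 1 without a white leaf above lca2(A0 n (R u B)); contradicts a lowest root")
    }
    return(list(case = "case1", A0 = A0, x_W = above))
  }
  if (has_compatible_tricolored_triple(pair, A0, coloring)) {
    stop("(RuB)-compatible tricolored component with a compatible tricolored triple; contradicts a lowest root")
  }
  list(case = "case3", A0 = A0)
}

has_compatible_tricolored_triple <- function(pair, A, coloring) {
  Rs <- intersect(A, coloring$R); Bs <- intersect(A, coloring$B)
  Ws <- intersect(A, coloring$W)
  for (r in Rs) for (b in Bs) for (w in Ws) {
    if (triple_compatible(pair, r, b, w)) return(TRUE)
  }
  FALSE
}

all_tricolored_triples_compatible <- function(pair, A, coloring) {
  Rs <- intersect(A, coloring$R); Bs <- intersect(A, coloring$B)
  Ws <- intersect(A, coloring$W)
  for (r in Rs) for (b in Bs) for (w in Ws) {
    if (!triple_compatible(pair, r, b, w)) return(FALSE)
  }
  TRUE
}

# ---- the three refinement stages -----------------------------------------

# state = list(P = list of comps, top = logical) used internally so that
# top-component identity survives across the stages of one iteration.

start_state <- function(pair, P, coloring, top = NULL) {
  P <- canonical_partition(P)
  if (is.null(top)) {
    top <- vapply(P, function(A) length(colors_of(A, coloring)) >= 2L, logical(1))
  }
  list(P = P, top = top)
}

# subdivide component at position i into A n L(uhat) and A \ L(uhat);
# the remainder inherits top status (Definition of top components)
subdivide_at <- function(pair, state, i, uhat) {
  A <- state$P[[i]]
  inside <- intersect(A, labels_below(pair, uhat, 2L))
  rest <- setdiff(A, inside)
  if (!length(inside) || !length(rest)) {
    stop("degenerate subdivision at node ", uhat)
  }
  was_top <- state$top[[i]]
  state$P[[i]] <- sort(inside)
  state$top[[i]] <- FALSE
  state$P[[length(state$P) + 1L]] <- sort(rest)
  state$top[[length(state$P)]] <- was_top
  state
}

# order components by their minimum label (deterministic scan order)
scan_order <- function(P) order(vapply(P, `[`, integer(1), 1L))

# lowest qualifying nodes of T2: nodes in `candidates` (logical over t2
# nodes) none of whose children qualify; returned in post-order.
lowest_qualifying <- function(t2, qual) {
  out <- integer(0)
  for (v in t2$postorder) {
    if (!qual[[v]]) next
    ch <- t2$children[[v]]
    if (!length(ch) || !any(qual[ch])) out <- c(out, v)
  }
  out
}

#' Refine a partition until it is (R u B)-compatible
#'
#' While some component `A` mixes red and blue leaves incompatibly, the
#' lowest node of the T2-span of `A` whose leaf set meets both red and
#' blue is selected and `A` is cut there.  Each selected node triggers a
#' unit decrement of the dual variable there (a "starred" node).
#'
#' @param pair a `maf_pair`.
#' @param P partition not overlapping in the second tree (and compatible
#'   when restricted to red alone and to blue alone).
#' @param coloring from [make_coloring()].
#' @param top optional logical flags marking top components (defaults to
#'   the multicolored components of `P`).
#' @return list with the refined `partition`, integer `star_nodes` (T2
#'   node ids, one per cut) and the updated `top` flags.
#' @export
make_rb_compatible <- function(pair, P, coloring, top = NULL) {
  state <- start_state(pair, P, coloring, top)
  RB <- sort(c(coloring$R, coloring$B))
  t2 <- pair$t2
  stars <- integer(0)
  repeat {
    idx <- NULL
    for (i in scan_order(state$P)) {
      if (!is_compatible(pair, intersect(state$P[[i]], RB))) { idx <- i; break }
    }
    if (is.null(idx)) break
    A <- state$P[[idx]]
    span <- span_nodes(t2, tips_of(pair, A, 2L))
    hasR <- node_has_labels(pair, intersect(A, coloring$R), 2L)
    hasB <- node_has_labels(pair, intersect(A, coloring$B), 2L)
    qual <- rep(FALSE, t2$N)
    qual[span] <- hasR[span] & hasB[span]
    cand <- lowest_qualifying(t2, qual)
    if (!length(cand)) stop("no admissible cut node found; invariant violated")
    uhat <- cand[[1L]]
    stars <- c(stars, uhat)
    state <- subdivide_at(pair, state, idx, uhat)
  }
  st <- canonical_state(state)
  list(partition = st$P, star_nodes = stars, top = st$top)
}

# logical over nodes of tree t: does the node have a descendant leaf in A?
node_has_labels <- function(pair, A, t) {
  tr <- tree_of(pair, t)
  if (!length(A)) return(rep(FALSE, tr$N))
  tips <- tips_of(pair, A, t)
  as.logical(tr$desc[, tips, drop = FALSE] %*% rep(1L, length(tips)) > 0L)
}

canonical_state <- function(state) {
  o <- scan_order(state$P)
  P <- state$P[o]
  class(P) <- "maf_partition"
  list(P = P, top = state$top[o])
}

#' Refine a partition until every component is splittable
#'
#' A multicolored component whose color classes overlap in the second
#' tree is cut at a lowest node where two of its color-class spans meet,
#' chosen so that the part below the cut is bicolored and the remainder
#' keeps all of the component's colors.  Each cut node is starred (dual
#' decrement).
#'
#' @inheritParams make_rb_compatible
#' @param P an (R u B)-compatible partition not overlapping in the second
#'   tree.
#' @return list with `partition`, `star_nodes` and `top` as in
#'   [make_rb_compatible()].
#' @export
make_splittable <- function(pair, P, coloring, top = NULL) {
  state <- start_state(pair, P, coloring, top)
  t2 <- pair$t2
  stars <- integer(0)
  repeat {
    idx <- NULL
    for (i in scan_order(state$P)) {
      if (!is_splittable(pair, state$P[[i]], coloring)) { idx <- i; break }
    }
    if (is.null(idx)) break
    A <- state$P[[idx]]
    cols <- colors_of(A, coloring)
    class_sets <- list(R = intersect(A, coloring$R),
                       B = intersect(A, coloring$B),
                       W = intersect(A, coloring$W))
    pairs_to_try <- if (length(cols) == 3L) {
      list(c("R", "W"), c("B", "W"))
    } else {
      list(cols)
    }
    cand <- integer(0)
    for (pp in pairs_to_try) {
      s1 <- span_nodes(t2, tips_of(pair, class_sets[[pp[[1L]]]], 2L))
      s2 <- span_nodes(t2, tips_of(pair, class_sets[[pp[[2L]]]], 2L))
      I <- intersect(s1, s2)
      if (!length(I)) next
      qual <- rep(FALSE, t2$N); qual[I] <- TRUE
      cand <- c(cand, lowest_qualifying(t2, qual))
    }
    cand <- cand[!duplicated(cand)]
    # keep candidates that leave a bicolored lower part and preserve the
    # component's colors in the remainder, then take the post-order first
    ok <- logical(length(cand))
    for (j in seq_along(cand)) {
      below <- intersect(A, labels_below(pair, cand[[j]], 2L))
      rest <- setdiff(A, below)
      ok[[j]] <- length(rest) > 0L &&
        length(colors_of(below, coloring)) == 2L &&
        identical(colors_of(rest, coloring), cols)
    }
    cand <- cand[ok]
    if (!length(cand)) stop("no admissible split node found; invariant violated")
    uhat <- cand[[order(t2$porank[cand])[[1L]]]]
    stars <- c(stars, uhat)
    state <- subdivide_at(pair, state, idx, uhat)
  }
  st <- canonical_state(state)
  list(partition = st$P, star_nodes = stars, top = st$top)
}

#' Split multicolored components into (mostly) unicolored pieces
#'
#' Every multicolored component of a splittable, (R u B)-compatible
#' partition is replaced by its nonempty color classes, except for a
#' tricolored component containing at least one compatible tricolored
#' triple, which undergoes a Special-Split: if every tricolored triple is
#' compatible, it is cut into its red part and the rest (two-way);
#' otherwise it is cut at the T2-lca of its red/blue part into the three
#' color classes below that node plus the leaves above it (four-way,
#' starring that node).  A Special-Split may only hit a top component.
#'
#' @inheritParams make_rb_compatible
#' @param P a splittable, (R u B)-compatible partition not overlapping in
#'   the second tree.
#' @return list with `partition`, `star_nodes` (the four-way cut nodes)
#'   and `special_events`, a list of records with `kind` in
#'   `c("two_way","four_way")`, the affected component and its parts.
#' @export
split_components <- function(pair, P, coloring, top = NULL) {
  state <- start_state(pair, P, coloring, top)
  stars <- integer(0)
  events <- list()
  newP <- list()
  for (i in scan_order(state$P)) {
    A <- state$P[[i]]
    cols <- colors_of(A, coloring)
    if (length(cols) <= 1L) { newP[[length(newP) + 1L]] <- A; next }
    tric <- length(cols) == 3L
    if (tric && has_compatible_tricolored_triple(pair, A, coloring)) {
      if (!state$top[[i]]) {
        stop("Special-Split selected for a non-top component; contradicts the splittability analysis")
      }
      if (all_tricolored_triples_compatible(pair, A, coloring)) {
        red <- intersect(A, coloring$R)
        rest <- setdiff(A, red)
        newP <- c(newP, list(sort(red), sort(rest)))
        events[[length(events) + 1L]] <-
          list(kind = "two_way", comp = A, parts = list(sort(red), sort(rest)))
      } else {
        u0 <- lca_of(pair, intersect(A, c(coloring$R, coloring$B)), 2L)
        below <- labels_below(pair, u0, 2L)
        inside <- intersect(A, below)
        parts <- list(intersect(inside, coloring$R),
                      intersect(inside, coloring$B),
                      intersect(inside, coloring$W),
                      setdiff(A, below))
        parts <- lapply(parts[lengths(parts) > 0L], sort)
        newP <- c(newP, parts)
        stars <- c(stars, u0)
        events[[length(events) + 1L]] <-
          list(kind = "four_way", comp = A, parts = parts, u_hat0 = u0)
      }
    } else {
      parts <- list(intersect(A, coloring$R), intersect(A, coloring$B),
                    intersect(A, coloring$W))
      parts <- lapply(parts[lengths(parts) > 0L], sort)
      newP <- c(newP, parts)
    }
  }
  list(partition = canonical_partition(newP), star_nodes = stars,
       special_events = events)
}

# ---- merge search ---------------------------------------------------------

# nodes of T2 that a component can "reach": its own span, plus the chain
# of ancestors of its T2-lca as long as intermediate nodes are uncovered
# by every component of the partition
reach_set <- function(pair, A, covered) {
  t2 <- pair$t2
  S <- span_nodes(t2, tips_of(pair, A, 2L))
  v <- lca_of(pair, A, 2L)
  repeat {
    p <- t2$parent[[v]]
    if (p == 0L) break
    S <- c(S, p)
    if (covered[[p]]) break
    v <- p
  }
  sort(unique(S))
}

chain_up <- function(tree, a, b) {
  # inclusive ancestor chain from a up to b (a must be a descendant of b)
  out <- a
  while (a != b) {
    a <- tree$parent[[a]]
    if (a == 0L) stop("nodes not ancestor-comparable")
    out <- c(out, a)
  }
  out
}

#' Search for a mergeable pair of components
#'
#' Looks for two leaves of R u B lying in one component at the start of
#' the iteration but in two components now, such that merging those two
#' components keeps the partition (R u B)-feasible.  Existence is decided
#' through three exhaustive conditions on the components refined out of a
#' start component: a leftover bicolored component (undoing a two-way
#' Special-Split), two same-colored components that can reach a common
#' node of the second tree, or a red and a blue component reaching a
#' common uncovered node with a clean path up to the start component's
#' T2-lca.  At most one pair per iteration is returned.
#'
#' @param pair a `maf_pair`.
#' @param P3 the partition after [split_components()].
#' @param coloring the iteration's coloring.
#' @param P0 the partition at the start of the iteration.
#' @param events optional `special_events` from [split_components()]
#'   (used to locate the partner of a leftover bicolored component
#'   directly; otherwise it is found by a feasibility scan).
#' @return integer vector `c(x1, x2)` of label indices, or `NULL`.
#' @export
find_merge_pair <- function(pair, P3, coloring, P0, events = NULL) {
  t2 <- pair$t2
  RB <- sort(c(coloring$R, coloring$B))
  covered <- rep(FALSE, t2$N)
  for (A in P3) covered[span_nodes(t2, tips_of(pair, A, 2L))] <- TRUE

  key <- function(A) paste(sort(A), collapse = ",")
  p3keys <- vapply(P3, key, character(1))

  # condition (a): a bicolored component left by a two-way Special-Split
  for (i0 in scan_order(P0)) {
    A0 <- P0[[i0]]
    Q <- P3[vapply(P3, function(A) all(A %in% A0), logical(1))]
    if (length(Q) < 2L) next
    bic <- Q[vapply(Q, function(A) length(colors_of(A, coloring)) == 2L, logical(1))]
    if (!length(bic)) next
    Astar <- bic[[1L]]
    partner <- NULL
    if (!is.null(events)) {
      for (ev in events) {
        if (ev$kind == "two_way" && identical(key(ev$parts[[2L]]), key(Astar))) {
          partner <- ev$parts[[1L]]; break
        }
      }
    }
    if (is.null(partner)) {
      reds <- Q[vapply(Q, function(A) all(A %in% coloring$R), logical(1))]
      for (C in reds[scan_order(reds)]) {
        merged <- merge_two(P3, C, Astar)
        if (is_K_feasible(pair, merged, RB)) { partner <- C; break }
      }
    }
    if (!is.null(partner)) {
      x1 <- min(partner)
      x2 <- min(intersect(Astar, RB))
      return(sort(c(x1, x2)))
    }
  }

  best <- NULL
  take <- function(cand) {
    if (is.null(best) || cand[[1L]] < best[[1L]] ||
        (cand[[1L]] == best[[1L]] && cand[[2L]] < best[[2L]])) best <<- cand
    invisible(NULL)
  }

  # condition (b): two same-colored components reaching a common node
  for (i0 in scan_order(P0)) {
    A0 <- P0[[i0]]
    Q <- P3[vapply(P3, function(A) all(A %in% A0), logical(1))]
    if (length(Q) < 2L) next
    for (colset in list(coloring$R, coloring$B)) {
      mono <- Q[vapply(Q, function(A) all(A %in% colset), logical(1))]
      if (length(mono) < 2L) next
      reaches <- lapply(mono, reach_set, pair = pair, covered = covered)
      for (a in seq_along(mono)) for (b in seq_along(mono)) {
        if (a >= b) next
        if (length(intersect(reaches[[a]], reaches[[b]]))) {
          take(sort(c(min(mono[[a]]), min(mono[[b]]))))
        }
      }
    }
  }
  if (!is.null(best)) return(best)

  # condition (c): a red and a blue component reaching a common uncovered
  # node with an unobstructed path to lca2(A0)
  for (i0 in scan_order(P0)) {
    A0 <- P0[[i0]]
    Q <- P3[vapply(P3, function(A) all(A %in% A0), logical(1))]
    if (length(Q) < 2L) next
    reds <- Q[vapply(Q, function(A) all(A %in% coloring$R), logical(1))]
    blues <- Q[vapply(Q, function(A) all(A %in% coloring$B), logical(1))]
    if (!length(reds) || !length(blues)) next
    coveredRB <- rep(FALSE, t2$N)
    for (A in c(reds, blues)) {
      coveredRB[span_nodes(t2, tips_of(pair, A, 2L))] <- TRUE
    }
    lcaA0 <- lca_of(pair, A0, 2L)
    for (CR in reds) for (CB in blues) {
      own <- union(span_nodes(t2, tips_of(pair, CR, 2L)),
                   span_nodes(t2, tips_of(pair, CB, 2L)))
      common <- setdiff(intersect(reach_set(pair, CR, covered),
                                  reach_set(pair, CB, covered)), own)
      for (uhat in common) {
        path <- if (t2$depth[[uhat]] >= t2$depth[[lcaA0]]) {
          chain_up(t2, uhat, lcaA0)
        } else {
          chain_up(t2, lcaA0, uhat)
        }
        if (!any(coveredRB[path])) {
          take(sort(c(min(CR), min(CB))))
          break
        }
      }
    }
  }
  best
}

merge_two <- function(P, A, B) {
  keyA <- paste(sort(A), collapse = ","); keyB <- paste(sort(B), collapse = ",")
  out <- list()
  for (C in P) {
    k <- paste(sort(C), collapse = ",")
    if (k == keyA || k == keyB) next
    out[[length(out) + 1L]] <- C
  }
  out[[length(out) + 1L]] <- sort(c(A, B))
  canonical_partition(out)
}

#' Apply recorded merges to the final partition
#'
#' Returns the unique finest coarsening of `P` in which both members of
#' every recorded pair share a component; the result is independent of
#' the order of the pairs.
#'
#' @param P a partition.
#' @param pairslist list of integer label pairs.
#' @return the coarsened partition.
#' @export
merge_components <- function(P, pairslist) {
  if (!length(pairslist)) return(canonical_partition(P))
  n_comp <- length(P)
  comp_of <- integer(max(unlist(P)))
  for (i in seq_along(P)) comp_of[P[[i]]] <- i
  parent <- seq_len(n_comp)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (pr in pairslist) {
    if (any(pr > length(comp_of)) || any(comp_of[pr] == 0L)) {
      stop("merge pair refers to an absent label")
    }
    a <- find(comp_of[[pr[[1L]]]]); b <- find(comp_of[[pr[[2L]]]])
    if (a != b) parent[[b]] <- a
  }
  groups <- split(seq_len(n_comp), vapply(seq_len(n_comp), find, integer(1)))
  canonical_partition(lapply(groups, function(g) sort(unlist(P[g]))))
}

# ---- the main loop --------------------------------------------------------

#' Run the Red-Blue algorithm
#'
#' Computes a feasible agreement forest of the pair with at most twice the
#' optimal number of cuts, together with the dual-fitting certificate
#' that proves the factor for this very run.  For rSPR-distance semantics
#' the pair should be rho-augmented first (see [augment_rho()]).
#'
#' @param pair a `maf_pair`.
#' @return an object of class `maf_run`: `forest` (the final partition),
#'   `cuts` (`|forest| - 1`), `pairslist`, `traces` (one record per
#'   iteration with partition snapshots `P0`..`P3`, the coloring, case
#'   label, starred nodes, special events and the dual deltas), `dual`
#'   (`y` values per tree and the pre-merge component list) and
#'   `certificate` (dual objective, cuts and the 2-approximation bound).
#' @examples
#' pr <- augment_rho(tree_pair("((a,b),c);", "((a,c),b);"))
#' res <- red_blue(pr)
#' res$cuts
#' res$certificate
#' @export
red_blue <- function(pair) {
  stopifnot(inherits(pair, "maf_pair"))
  P <- canonical_partition(list(seq_len(pair$n)))
  y1 <- numeric(pair$t1$N); y2 <- numeric(pair$t2$N)
  traces <- list()
  pairslist <- list()
  iter <- 0L
  repeat {
    roi <- lowest_root_of_infeasibility(pair, P)
    if (is.null(roi)) break
    iter <- iter + 1L
    if (iter >= pair$n + 1L) {
      stop("iteration count reached |L|; termination guarantee violated")
    }
    coloring <- make_coloring(pair, roi$u)
    case <- classify_case(pair, P, coloring)
    P0 <- P
    D_before <- sum(y1) + sum(y2) + length(P) - 1L

    s1 <- make_rb_compatible(pair, P0, coloring)
    s2 <- make_splittable(pair, s1$partition, coloring, top = s1$top)
    s3 <- split_components(pair, s2$partition, coloring, top = s2$top)
    mp <- find_merge_pair(pair, s3$partition, coloring, P0,
                          events = s3$special_events)

    y1[[coloring$u]] <- y1[[coloring$u]] - 1
    for (v in c(s1$star_nodes, s2$star_nodes, s3$star_nodes)) {
      if (!length(pair$t2$children[[v]])) stop("starred node is a leaf of T2")
      y2[[v]] <- y2[[v]] - 1
    }

    P <- s3$partition
    if (!is.null(mp)) pairslist[[length(pairslist) + 1L]] <- mp

    D_after <- sum(y1) + sum(y2) + length(P) - 1L
    delta_D <- D_after - D_before
    delta_P <- (length(P) - length(P0)) - (!is.null(mp))
    if (2 * delta_D < delta_P) {
      stop("per-iteration dual accounting failed: 2*", delta_D, " < ", delta_P)
    }
    traces[[iter]] <- list(
      u = roi$u, cond = roi$cond, case = case$case, coloring = coloring,
      P0 = P0, P1 = s1$partition, P2 = s2$partition, P3 = s3$partition,
      top1 = s1$top, top2 = s2$top,
      star_rb = s1$star_nodes, star_split = s2$star_nodes,
      star_special = s3$star_nodes, special_events = s3$special_events,
      merge_pair = mp, delta_D = delta_D, delta_P = delta_P)
  }
  pre_merge <- P
  forest <- merge_components(P, pairslist)
  D <- sum(y1) + sum(y2) + length(pre_merge) - 1L
  cuts <- length(forest) - 1L
  if (2 * D < length(pre_merge) - 1L - length(pairslist)) {
    stop("final dual certificate failed")
  }
  structure(
    list(forest = forest, cuts = cuts, traces = traces,
         pairslist = pairslist, iterations = iter,
         dual = list(y1 = y1, y2 = y2, z_components = pre_merge),
         certificate = list(dual_objective = D, cuts = cuts,
                            pairs = length(pairslist),
                            lower_bound = D,
                            ratio_bound = if (D > 0) cuts / D else 1)),
    class = "maf_run")
}

#' @export
print.maf_run <- function(x, ...) {
  cat("Red-Blue agreement forest:", length(x$forest), "components,",
      x$cuts, "cuts in", x$iterations, "iterations\n")
  cat("dual lower bound:", x$certificate$dual_objective,
      " (cuts <= 2 x lower bound)\n")
  invisible(x)
}

#' Format a forest for output
#'
#' One component per line: labels tab-separated, labels sorted, components
#' ordered by their smallest label.
#'
#' @param pair a `maf_pair`.
#' @param P a partition.
#' @return character vector, one entry per component.
#' @export
format_forest <- function(pair, P) {
  vapply(canonical_partition(P),
         function(A) paste(pair$labels[A], collapse = "\t"), character(1))
}
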