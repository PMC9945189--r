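# Linear-programming relaxations of MAF.
#
# Two routes to the same optimum:
#   * the enumerated formulation: one variable per compatible leaf set,
#     partition equalities on the leaves and packing inequalities on the
#     internal nodes of both trees (practical only while the compatible
#     sets can be enumerated);
#   * the compact formulation: compatible sets are encoded as
#     out-arborescences in a directed graph on leaf pairs, the cone of
#     which has a polynomial description; occupancy constraints replay the
#     packing inequalities through a per-arc attribution of tree nodes.
# Their optima agree (proved by the arborescence-cone decomposition;
# exercised wholesale by the equivalence tests).

# ---- a small dense two-phase simplex -------------------------------------

# Minimize c'x subject to A x (dir) b, x >= 0, dir in {"<=", "=", ">="}.
# Dantzig pricing with a fallback to Bland's rule to rule out cycling.
# Written for the small dense models built here (no LP solver package is
# assumed); optima are cross-checked against an independent solver in the
# test suite.
lp_solve_dense <- function(obj, A, dir, rhs, tol = 1e-9) {
  m <- nrow(A); nv <- ncol(A)
  stopifnot(length(obj) == nv, length(dir) == m, length(rhs) == m)
  A <- as.matrix(A); rhs <- as.numeric(rhs)
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }
  n_le <- sum(dir == "<="); n_ge <- sum(dir == ">=")
  n_art <- sum(dir != "<=")
  ncols <- nv + n_le + n_ge + n_art
  T <- matrix(0, m, ncols + 1L)
  T[, seq_len(nv)] <- A
  T[, ncols + 1L] <- rhs
  basis <- integer(m)
  sl <- nv; su <- nv + n_le; ar <- nv + n_le + n_ge
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (dir[[i]] == "<=") {
      sl <- sl + 1L; T[i, sl] <- 1; basis[[i]] <- sl
    } else if (dir[[i]] == ">=") {
      su <- su + 1L; T[i, su] <- -1
      ar <- ar + 1L; T[i, ar] <- 1; basis[[i]] <- ar
      art_cols <- c(art_cols, ar)
    } else {
      ar <- ar + 1L; T[i, ar] <- 1; basis[[i]] <- ar
      art_cols <- c(art_cols, ar)
    }
  }

  run_simplex <- function(T, basis, cost, allowed) {
    # reduced-cost row
    z <- c(cost, 0)
    for (i in seq_len(m)) {
      if (abs(z[[basis[[i]]]]) > 0) z <- z - z[[basis[[i]]]] * T[i, ]
    }
    maxit <- 200L * (m + length(allowed))
    bland_after <- maxit %/% 2L
    for (it in seq_len(maxit)) {
      zj <- z[allowed]
      cand <- which(zj < -tol)
      if (!length(cand)) return(list(T = T, basis = basis, z = z, status = "optimal"))
      j <- if (it > bland_after) allowed[[cand[[1L]]]]
           else allowed[[cand[[which.min(zj[cand])]]]]
      col <- T[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(T = T, basis = basis, z = z, status = "unbounded"))
      ratios <- T[pos, ncols + 1L] / col[pos]
      rmin <- min(ratios)
      tie <- pos[ratios <= rmin + tol]
      r <- tie[[which.min(basis[tie])]]
      piv <- T[r, j]
      T[r, ] <- T[r, ] / piv
      fac <- T[, j]; fac[r] <- 0
      T <- T - outer(fac, T[r, ])
      z <- z - z[[j]] * T[r, ]
      basis[[r]] <- j
    }
    list(T = T, basis = basis, z = z, status = "maxiter")
  }

  # phase 1
  if (length(art_cols)) {
    cost1 <- numeric(ncols); cost1[art_cols] <- 1
    res <- run_simplex(T, basis, cost1, seq_len(ncols))
    if (res$status != "optimal") return(list(status = "infeasible_phase1"))
    val1 <- -res$z[[ncols + 1L]]
    if (val1 > 1e-7) return(list(status = "infeasible"))
    T <- res$T; basis <- res$basis
    # drive artificials out of the basis where possible
    drop_rows <- integer(0)
    for (i in seq_len(m)) {
      if (basis[[i]] %in% art_cols) {
        j <- which(abs(T[i, seq_len(nv + n_le + n_ge)]) > tol)
        if (length(j)) {
          j <- j[[1L]]
          piv <- T[i, j]
          T[i, ] <- T[i, ] / piv
          fac <- T[, j]; fac[i] <- 0
          T <- T - outer(fac, T[i, ])
          basis[[i]] <- j
        } else {
          drop_rows <- c(drop_rows, i)
        }
      }
    }
    if (length(drop_rows)) {
      T <- T[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
      m <- nrow(T)
    }
  }
  cost2 <- c(obj, numeric(ncols - nv))
  allowed <- setdiff(seq_len(ncols), art_cols)
  res <- run_simplex(T, basis, cost2, allowed)
  if (res$status != "optimal") return(list(status = res$status))
  x <- numeric(ncols)
  x[res$basis] <- res$T[, ncols + 1L]
  # row duals from the reduced costs of the unit columns (slack: -z;
  # surplus: +z; equality rows read from their artificial column)
  m0 <- length(dir)
  duals <- numeric(m0)
  sl <- nv; su <- nv + n_le; ar <- nv + n_le + n_ge
  for (i in seq_len(m0)) {
    if (dir[[i]] == "<=") {
      sl <- sl + 1L; duals[[i]] <- -res$z[[sl]]
    } else if (dir[[i]] == ">=") {
      su <- su + 1L; ar <- ar + 1L; duals[[i]] <- res$z[[su]]
    } else {
      ar <- ar + 1L; duals[[i]] <- -res$z[[ar]]
    }
    if (any(neg) && neg[[i]]) duals[[i]] <- -duals[[i]]
  }
  list(status = "optimal", objective = sum(obj * x[seq_len(nv)]),
       x = x[seq_len(nv)], duals = duals)
}

# ---- enumerated formulation ----------------------------------------------

#' Enumerate all compatible subsets of the label set
#'
#' Every nonempty label subset whose restricted topologies agree between
#' the trees; includes all singletons and pairs.  Guarded by a size cap
#' because the count is exponential (use the compact formulation beyond
#' it).
#'
#' @param pair a `maf_pair`.
#' @param cap maximum number of labels (default 10).
#' @return list of sorted integer label vectors.
#' @export
enumerate_compatible_sets <- function(pair, cap = 10L) {
  n <- pair$n
  if (n > cap) {
    stop("label set too large (", n, " > cap ", cap,
         "); use the compact formulation")
  }
  bad <- integer(0)
  if (n >= 3L) {
    cmb <- utils::combn(n, 3L)
    for (j in seq_len(ncol(cmb))) {
      if (!triple_compatible(pair, cmb[1L, j], cmb[2L, j], cmb[3L, j])) {
        bad <- c(bad, bitwOr(bitwOr(bitwShiftL(1L, cmb[1L, j] - 1L),
                                    bitwShiftL(1L, cmb[2L, j] - 1L)),
                             bitwShiftL(1L, cmb[3L, j] - 1L)))
      }
    }
  }
  masks <- seq_len(2L^n - 1L)
  keep <- rep(TRUE, length(masks))
  for (t in bad) keep <- keep & (bitwAnd(masks, t) != t)
  lapply(masks[keep], function(m) which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0L))
}

# span of each compatible set as internal-node indicator rows
lp_constraint_matrix <- function(pair, sets) {
  n <- pair$n
  int1 <- which(lengths(pair$t1$children) == 2L)
  int2 <- which(lengths(pair$t2$children) == 2L)
  m <- n + length(int1) + length(int2)
  A <- matrix(0, m, length(sets))
  for (j in seq_along(sets)) {
    L <- sets[[j]]
    A[L, j] <- 1
    s1 <- intersect(spanned_nodes(pair, L, 1L), int1)
    s2 <- intersect(spanned_nodes(pair, L, 2L), int2)
    A[n + match(s1, int1), j] <- 1
    A[n + length(int1) + match(s2, int2), j] <- 1
  }
  list(A = A, n_leaf_rows = n, n_pack_rows = length(int1) + length(int2))
}

#' Solve the enumerated LP relaxation
#'
#' One nonnegative variable per compatible set; each leaf must be covered
#' exactly once and each internal node of either tree is spanned by sets
#' of total weight at most one; the objective is total weight minus one
#' (the number of cuts).  Also computes the integer-restricted optimum of
#' the same model by exact branch-and-bound, which equals the MAF
#' optimum.
#'
#' @param pair a `maf_pair`.
#' @param cap passed to [enumerate_compatible_sets()].
#' @param integer_opt also compute the integral optimum (default TRUE).
#' @return list with `optimum` (LP value, cuts scale), `status`,
#'   `solution` (weights per compatible set), `sets`, and when requested
#'   `integer_optimum` and `integer_partition`.
#' @export
solve_lp_enumerated <- function(pair, cap = 10L, integer_opt = TRUE) {
  sets <- enumerate_compatible_sets(pair, cap = cap)
  cm <- lp_constraint_matrix(pair, sets)
  m <- nrow(cm$A)
  dir <- c(rep("=", cm$n_leaf_rows), rep("<=", cm$n_pack_rows))
  rhs <- rep(1, m)
  res <- lp_solve_dense(rep(1, length(sets)), cm$A, dir, rhs)
  if (res$status != "optimal") stop("LP solve failed: ", res$status)
  out <- list(optimum = res$objective - 1, status = res$status,
              solution = res$x, sets = sets)
  if (integer_opt) {
    ip <- integer_partition_optimum(pair, sets)
    out$integer_optimum <- ip$opt
    out$integer_partition <- ip$partition
  }
  out
}

# Exact integral optimum of the set-partition model: branch on the
# compatible sets containing the smallest uncovered label, maintaining
# pairwise non-overlap (disjoint spans in both trees).
integer_partition_optimum <- function(pair, sets = NULL, cap = 10L) {
  if (is.null(sets)) sets <- enumerate_compatible_sets(pair, cap = cap)
  n <- pair$n
  spans1 <- lapply(sets, function(L) spanned_nodes(pair, L, 1L))
  spans2 <- lapply(sets, function(L) spanned_nodes(pair, L, 2L))
  by_min <- vector("list", n)
  for (j in seq_along(sets)) {
    mn <- sets[[j]][[1L]]
    by_min[[mn]] <- c(by_min[[mn]], j)
  }
  # larger sets first: finds good solutions early, tightens the bound
  for (v in seq_len(n)) {
    js <- by_min[[v]]
    by_min[[v]] <- js[order(-lengths(sets[js]))]
  }
  best <- list(k = n, comps = lapply(seq_len(n), identity))
  covered <- rep(FALSE, n)
  used1 <- rep(FALSE, pair$t1$N); used2 <- rep(FALSE, pair$t2$N)
  chosen <- integer(0)
  rec <- function(k) {
    if (k >= best$k) return(invisible(NULL))
    v <- which(!covered)
    if (!length(v)) {
      best <<- list(k = k, comps = lapply(chosen, function(j) sets[[j]]))
      return(invisible(NULL))
    }
    v <- v[[1L]]
    for (j in by_min[[v]]) {
      L <- sets[[j]]
      if (any(covered[L])) next
      if (any(used1[spans1[[j]]]) || any(used2[spans2[[j]]])) next
      covered[L] <<- TRUE
      used1[spans1[[j]]] <<- TRUE; used2[spans2[[j]]] <<- TRUE
      chosen <<- c(chosen, j)
      rec(k + 1L)
      chosen <<- chosen[-length(chosen)]
      covered[L] <<- FALSE
      used1[spans1[[j]]] <<- FALSE; used2[spans2[[j]]] <<- FALSE
    }
    invisible(NULL)
  }
  rec(0L)
  list(opt = best$k - 1L, partition = canonical_partition(best$comps))
}

# ---- arborescence graph and compact formulation --------------------------

#' Build the leaf-pair arborescence graph
#'
#' Vertices are ordered label pairs `(i1, i2)` with `i1 <= i2` (the pairs
#' `(i,i)` stand for the leaves).  An arc points from pair `r` to pair
#' `s` when the node `s` identifies (the lca of its two labels) lies
#' strictly below the node `r` identifies in both trees; "left" arcs
#' share the first label, "right" arcs chain the second label of `r` to
#' the first of `s`.  Every compatible set corresponds to an arborescence
#' in this graph (see [arborescence_of()]).
#'
#' @param pair a `maf_pair`.
#' @return list with the pair table `Z` (columns `i1`, `i2`), the lookup
#'   `zid[i1, i2]`, per-tree lca node of every pair (`lca1`, `lca2`), the
#'   arc table `arcs` (columns `from`, `to`, `class` with 1 = left and
#'   2 = right), and per-arc per-tree cover sets used by the occupancy
#'   constraints (`cover1`, `cover2`: the chain of internal nodes from
#'   the head's lca, inclusive, up to the tail's lca, exclusive).
#' @export
build_arbor_graph <- function(pair) {
  n <- pair$n
  i1 <- rep(seq_len(n), times = n:1)
  i2 <- unlist(lapply(seq_len(n), function(i) i:n))
  nz <- length(i1)
  zid <- matrix(NA_integer_, n, n)
  zid[cbind(i1, i2)] <- seq_len(nz)
  lca1 <- integer(nz); lca2 <- integer(nz)
  for (z in seq_len(nz)) {
    lca1[[z]] <- lca_node(pair$t1, unique(pair$tip1[c(i1[[z]], i2[[z]])]))
    lca2[[z]] <- lca_node(pair$t2, unique(pair$tip2[c(i1[[z]], i2[[z]])]))
  }
  anc <- function(tree) {
    # anc[a, b]: b is an ancestor of a or a itself
    M <- matrix(FALSE, tree$N, tree$N)
    for (a in seq_len(tree$N)) {
      v <- a
      repeat { M[a, v] <- TRUE; v <- tree$parent[[v]]; if (v == 0L) break }
    }
    M
  }
  anc1 <- anc(pair$t1); anc2 <- anc(pair$t2)
  strict_below <- function(s, r) {
    (lca1[[s]] != lca1[[r]] && anc1[lca1[[s]], lca1[[r]]]) &&
    (lca2[[s]] != lca2[[r]] && anc2[lca2[[s]], lca2[[r]]])
  }
  from <- integer(0); to <- integer(0); cls <- integer(0)
  for (r in seq_len(nz)) {
    a1 <- i1[[r]]; a2 <- i2[[r]]
    if (a1 == a2) next   # leaf pairs identify leaves: nothing strictly below
    for (j2 in a1:n) {   # left arcs: head keeps the first label
      s <- zid[a1, j2]
      if (is.na(s) || s == r) next
      if (strict_below(s, r)) { from <- c(from, r); to <- c(to, s); cls <- c(cls, 1L) }
    }
    for (j2 in a2:n) {   # right arcs: head starts at the tail's second label
      s <- zid[a2, j2]
      if (is.na(s) || s == r) next
      if (strict_below(s, r)) { from <- c(from, r); to <- c(to, s); cls <- c(cls, 2L) }
    }
  }
  chain_internal <- function(tree, lo, hi) {
    # nodes v with lo <= v < hi on the ancestor chain, internal only
    out <- integer(0); v <- lo
    while (v != hi) {
      if (length(tree$children[[v]])) out <- c(out, v)
      v <- tree$parent[[v]]
    }
    out
  }
  narc <- length(from)
  cover1 <- vector("list", narc); cover2 <- vector("list", narc)
  for (a in seq_len(narc)) {
    cover1[[a]] <- chain_internal(pair$t1, lca1[[to[[a]]]], lca1[[from[[a]]]])
    cover2[[a]] <- chain_internal(pair$t2, lca2[[to[[a]]]], lca2[[from[[a]]]])
  }
  list(n = n, Z = cbind(i1 = i1, i2 = i2), zid = zid,
       lca1 = lca1, lca2 = lca2,
       arcs = cbind(from = from, to = to, class = cls),
       cover1 = cover1, cover2 = cover2,
       is_leaf_pair = i1 == i2)
}

#' Arborescence encoding of a compatible set
#'
#' Recursively encodes the restricted topology of a compatible set `L` as
#' an out-arborescence on label pairs: a singleton maps to its leaf pair;
#' otherwise the root is the pair of smallest labels of the two subtrees
#' below the root of the restricted first tree, with a left arc into the
#' first part's arborescence and a right arc into the second's.
#'
#' @param pair a `maf_pair`.
#' @param graph from [build_arbor_graph()].
#' @param L a compatible label subset.
#' @return list with `root` (Z index), `nodes` (Z indices) and `arcs`
#'   (rows `from`, `to`, `class`).
#' @export
arborescence_of <- function(pair, graph, L) {
  L <- as_label_idx(pair, L)
  if (!is_compatible(pair, L)) stop("set is not compatible")
  rec <- function(L) {
    if (length(L) == 1L) {
      return(list(root = graph$zid[L, L], nodes = graph$zid[L, L],
                  arcs = matrix(integer(0), 0, 3,
                                dimnames = list(NULL, c("from", "to", "class")))))
    }
    v <- lca_of(pair, L, 1L)
    ch <- pair$t1$children[[v]]
    L1 <- intersect(L, labels_below(pair, ch[[1L]], 1L))
    L2 <- setdiff(L, L1)
    if (min(L1) > min(L2)) { tmp <- L1; L1 <- L2; L2 <- tmp }
    r <- graph$zid[min(L1), min(L2)]
    f1 <- rec(L1); f2 <- rec(L2)
    list(root = r,
         nodes = c(r, f1$nodes, f2$nodes),
         arcs = rbind(f1$arcs, f2$arcs,
                      c(r, f1$root, 1L), c(r, f2$root, 2L)))
  }
  out <- rec(L)
  colnames(out$arcs) <- c("from", "to", "class")
  out
}

# match an arborescence's arcs to graph arc indices (error if absent)
arc_indices <- function(graph, arcs) {
  if (!nrow(arcs)) return(integer(0))
  key <- paste(graph$arcs[, "from"], graph$arcs[, "to"], graph$arcs[, "class"])
  i <- match(paste(arcs[, "from"], arcs[, "to"], arcs[, "class"]), key)
  if (anyNA(i)) stop("arborescence uses an arc missing from the graph")
  i
}

#' Build the compact LP model
#'
#' Variables: one nonnegative weight per arc and one per leaf (the
#' fractional weight of its singleton component).  Constraints: (i) at
#' every internal pair, the left and right outflows are equal and the
#' left outflow is at least the inflow (the arborescence-cone
#' description); (ii) every leaf is accounted for exactly once by arc
#' inflow at its pair plus its singleton weight; (iii) every internal
#' tree node is occupied at most once, where an arc occupies the chain
#' from its head's lca (inclusive) to its tail's lca (exclusive) and the
#' root excess at a pair occupies the pair's lca.  The objective is the
#' total root excess plus the singleton weights, minus one.
#'
#' @param pair a `maf_pair`.
#' @param graph from [build_arbor_graph()]; rebuilt when `NULL`.
#' @return list with `obj`, `A`, `dir`, `rhs`, `graph`, `n_arc` and the
#'   objective constant `const` (-1).
#' @export
build_compact_lp <- function(pair, graph = NULL) {
  if (is.null(graph)) graph <- build_arbor_graph(pair)
  n <- pair$n
  narc <- nrow(graph$arcs)
  nv <- narc + n         # y arcs then xbar leaves
  afrom <- graph$arcs[, "from"]; ato <- graph$arcs[, "to"]
  acls <- graph$arcs[, "class"]
  internal_z <- which(!graph$is_leaf_pair)
  head_internal <- !graph$is_leaf_pair[ato]

  rows <- list(); dirs <- character(0); rhs <- numeric(0)
  add_row <- function(coef, d, b) {
    rows[[length(rows) + 1L]] <<- coef
    dirs <<- c(dirs, d); rhs <<- c(rhs, b)
  }
  # (i) cone constraints at internal pairs
  for (r in internal_z) {
    coef <- numeric(nv)
    coef[which(afrom == r & acls == 1L)] <- 1
    coef[which(afrom == r & acls == 2L)] <- coef[which(afrom == r & acls == 2L)] - 1
    add_row(coef, "=", 0)
    coef <- numeric(nv)
    coef[which(afrom == r & acls == 1L)] <- 1
    ent <- which(ato == r)
    coef[ent] <- coef[ent] - 1
    add_row(coef, ">=", 0)
  }
  # (ii) leaf accounting
  for (i in seq_len(n)) {
    coef <- numeric(nv)
    coef[which(ato == graph$zid[i, i])] <- 1
    coef[narc + i] <- 1
    add_row(coef, "=", 1)
  }
  # (iii) occupancy of internal tree nodes
  for (t in 1:2) {
    tr <- tree_of(pair, t)
    lcat <- if (t == 1L) graph$lca1 else graph$lca2
    covert <- if (t == 1L) graph$cover1 else graph$cover2
    for (v in which(lengths(tr$children) == 2L)) {
      coef <- numeric(nv)
      for (a in seq_len(narc)) {
        c0 <- 0
        if (v %in% covert[[a]]) c0 <- c0 + 1
        if (acls[[a]] == 1L && lcat[[afrom[[a]]]] == v) c0 <- c0 + 1
        if (head_internal[[a]] && lcat[[ato[[a]]]] == v) c0 <- c0 - 1
        coef[[a]] <- c0
      }
      if (any(coef != 0)) add_row(coef, "<=", 1)
    }
  }
  obj <- numeric(nv)
  obj[seq_len(narc)] <- (acls == 1L) - head_internal
  obj[narc + seq_len(n)] <- 1
  A <- do.call(rbind, rows)
  list(obj = obj, A = A, dir = dirs, rhs = rhs, graph = graph,
       n_arc = narc, const = -1)
}

#' Solve the compact LP
#'
#' @param pair a `maf_pair`.
#' @param model optional prebuilt model from [build_compact_lp()].
#' @return list with `optimum` (cuts scale), `status`, `y` (arc weights),
#'   `xbar` (singleton weights) and the `graph`.
#' @export
solve_compact_lp <- function(pair, model = NULL) {
  if (is.null(model)) model <- build_compact_lp(pair)
  res <- lp_solve_dense(model$obj, model$A, model$dir, model$rhs)
  if (res$status != "optimal") stop("compact LP solve failed: ", res$status)
  narc <- model$n_arc
  list(optimum = res$objective + model$const, status = res$status,
       y = res$x[seq_len(narc)],
       xbar = res$x[narc + seq_len(model$graph$n)],
       graph = model$graph)
}

#' Integrality gap of an instance
#'
#' The ratio of the exact MAF optimum to the LP-relaxation optimum
#' (compact formulation by default); defined as 1 when both vanish.
#'
#' @param pair a `maf_pair`.
#' @param method `"compact"` or `"enumerated"`.
#' @param cap cap for the exact solver / enumeration.
#' @return list with `opt`, `lp`, `gap`.
#' @export
integrality_gap <- function(pair, method = c("compact", "enumerated"), cap = 12L) {
  method <- match.arg(method)
  opt <- exact_maf(pair, cap = cap)$opt_cuts
  lp <- if (method == "compact") solve_compact_lp(pair)$optimum
        else solve_lp_enumerated(pair, cap = cap, integer_opt = FALSE)$optimum
  lp <- max(lp, 0)
  gap <- if (opt == 0 && lp <= 1e-7) 1 else opt / lp
  list(opt = opt, lp = lp, gap = gap)
}

#' Certify the enumerated LP optimum as an exact rational
#'
#' Rounds the solver's primal and dual basic solutions to small-denominator
#' rationals and re-verifies feasibility and the objective in exact integer
#' arithmetic.  A successful primal certificate proves the LP optimum is at
#' most `num/den`; a successful dual certificate proves it is at least
#' `num/den`; together they pin the optimum exactly.
#'
#' @param pair a `maf_pair`.
#' @param num,den the claimed optimum as a fraction (cuts scale, i.e. the
#'   claimed total-weight optimum is `num/den + 1`).
#' @param max_den largest denominator tried when rationalizing.
#' @param cap passed to [enumerate_compatible_sets()].
#' @return TRUE invisibly; stops with a message when certification fails.
#' @export
certify_lp_value <- function(pair, num, den, max_den = 120L, cap = 12L) {
  sets <- enumerate_compatible_sets(pair, cap = cap)
  cm <- lp_constraint_matrix(pair, sets)
  m <- nrow(cm$A)
  dir <- c(rep("=", cm$n_leaf_rows), rep("<=", cm$n_pack_rows))
  res <- lp_solve_dense(rep(1, length(sets)), cm$A, dir, rep(1, m))
  if (res$status != "optimal") stop("LP solve failed")
  rationalize <- function(v) {
    for (d in seq_len(max_den)) {
      p <- round(v * d)
      if (max(abs(v * d - p)) < 1e-6) return(list(p = p, d = d))
    }
    stop("solution is not a small rational")
  }
  # primal: A p == d on leaf rows, <= d on packing rows, objective exact
  pq <- rationalize(res$x)
  lhs <- as.vector(cm$A %*% pq$p)
  if (!all(lhs[seq_len(cm$n_leaf_rows)] == pq$d)) {
    stop("primal certificate violates a leaf equality")
  }
  if (!all(lhs[-seq_len(cm$n_leaf_rows)] <= pq$d)) {
    stop("primal certificate violates a packing inequality")
  }
  if (sum(pq$p) * den != (num + den) * pq$d) {
    stop("primal certificate has the wrong objective")
  }
  # dual: y' A <= 1 with nonpositive multipliers on packing rows,
  # objective y' 1 == num/den + 1
  dq <- rationalize(res$duals)
  if (!all(dq$p[-seq_len(cm$n_leaf_rows)] <= 0)) {
    stop("dual certificate has a positive packing multiplier")
  }
  red <- as.vector(dq$p %*% cm$A)
  if (!all(red <= dq$d)) stop("dual certificate violates a column constraint")
  if (sum(dq$p) * den != (num + den) * dq$d) {
    stop("dual certificate has the wrong objective")
  }
  invisible(TRUE)
}

# Greedy peeling of a cone point into arborescence characteristic
# vectors (the constructive direction of the cone description); used by
# the tests to certify that constrained-feasible y's decompose.
decompose_cone_point <- function(pair, graph, y, tol = 1e-8) {
  afrom <- graph$arcs[, "from"]; ato <- graph$arcs[, "to"]
  acls <- graph$arcs[, "class"]
  out <- list()
  y <- as.numeric(y)
  guard <- 0L
  while (any(y > tol)) {
    guard <- guard + 1L
    if (guard > 10000L) stop("cone decomposition did not terminate")
    inflow <- vapply(seq_len(nrow(graph$Z)),
                     function(r) sum(y[ato == r]), numeric(1))
    outflow <- vapply(seq_len(nrow(graph$Z)),
                      function(r) sum(y[afrom == r]), numeric(1))
    r0 <- which(inflow <= tol & outflow > tol)
    if (!length(r0)) stop("no root with zero inflow found; not a cone point")
    r0 <- r0[[1L]]
    # grow an arborescence in the support
    arcs_used <- integer(0)
    grow <- function(r) {
      if (graph$is_leaf_pair[[r]]) return(invisible(NULL))
      a1 <- which(afrom == r & acls == 1L & y > tol)
      a2 <- which(afrom == r & acls == 2L & y > tol)
      if (!length(a1) || !length(a2)) stop("support node lacks out-arcs; not a cone point")
      arcs_used <<- c(arcs_used, a1[[1L]], a2[[1L]])
      grow(ato[[a1[[1L]]]]); grow(ato[[a2[[1L]]]])
    }
    grow(r0)
    eps <- min(y[arcs_used])
    y[arcs_used] <- y[arcs_used] - eps
    leafz <- unique(ato[arcs_used][graph$is_leaf_pair[ato[arcs_used]]])
    out[[length(out) + 1L]] <- list(root = r0, weight = eps,
                                    arcs = arcs_used,
                                    leaves = sort(graph$Z[leafz, "i1"]))
  }
  out
}
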