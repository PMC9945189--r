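# The worked example instance: T1 groups blue leaves B1,B2 and red leaves
# R1,R2 under one node u with whites W1..W3 attached above; T2 interleaves
# the colors.  The three stored partitions exercise the three
# root-of-infeasibility conditions, and the refinement procedures have
# fully determined outputs on them.

test_that("the lowest root of infeasibility and its condition are recognized", {
  pr <- rbw()
  u <- lca_node(pr$t1, c("R1", "B1"))

  P_a <- as_partition(pr, list(pr$labels))
  roi <- lowest_root_of_infeasibility(pr, P_a)
  expect_equal(roi$u, u); expect_equal(roi$cond, "a")

  P_b <- as_partition(pr, list("B1", c("B2", "W1"), c("R1", "R2", "W2", "W3")))
  roi <- lowest_root_of_infeasibility(pr, P_b)
  expect_equal(roi$u, u); expect_equal(roi$cond, "b")

  P_c <- as_partition(pr, list("R1", c("B1", "B2", "W1", "R2", "W2"), "W3"))
  roi <- lowest_root_of_infeasibility(pr, P_c)
  expect_equal(roi$u, u); expect_equal(roi$cond, "c")

  # ancestors of a root of infeasibility also qualify
  anc <- pr$t1$parent[[u]]
  while (anc != 0L) {
    expect_false(is.null(agreeforest:::root_condition(
      pr, P_a, agreeforest:::labels_below(pr, anc, 1L))))
    anc <- pr$t1$parent[[anc]]
  }

  expect_null(lowest_root_of_infeasibility(
    pr, as_partition(pr, as.list(pr$labels))))
  expect_error(lowest_root_of_infeasibility(
    pair_id(), as_partition(pair_id(), list(c("a", "c"), c("b", "d")))),
    "overlaps in V2")
})

test_that("coloring partitions the labels by the children of u", {
  pr <- rbw()
  u <- lca_node(pr$t1, c("R1", "B1"))
  col <- make_coloring(pr, u)
  expect_setequal(pr$labels[col$R], c("R1", "R2"))
  expect_setequal(pr$labels[col$B], c("B1", "B2"))
  expect_setequal(pr$labels[col$W], c("W1", "W2", "W3"))
  expect_equal(length(col$R) + length(col$B) + length(col$W), pr$n)
  col_root <- make_coloring(pr, pr$t1$root)
  expect_length(col_root$W, 0L)
  expect_error(make_coloring(pr, match("R1", pr$t1$tip_label)), "internal")
})

test_that("the three iteration cases are classified with their witnesses", {
  pr <- rbw()
  col <- make_coloring(pr, lca_node(pr$t1, c("R1", "B1")))
  expect_equal(classify_case(pr, as_partition(pr, list(pr$labels)), col)$case, "case1")
  cc2 <- classify_case(pr, as_partition(pr,
    list("B1", c("B2", "W1"), c("R1", "R2", "W2", "W3"))), col)
  expect_equal(cc2$case, "case2")
  expect_setequal(pr$labels[cc2$A_B], c("B2", "W1"))
  expect_setequal(pr$labels[cc2$A_R], c("R1", "R2", "W2", "W3"))
  expect_equal(classify_case(pr, as_partition(pr,
    list("R1", c("B1", "B2", "W1", "R2", "W2"), "W3")), col)$case, "case3")
})

test_that("make_rb_compatible reproduces the forced refinement and keeps the V2 invariant", {
  pr <- rbw()
  col <- make_coloring(pr, lca_node(pr$t1, c("R1", "B1")))
  s <- make_rb_compatible(pr, as_partition(pr, list(pr$labels)), col)
  expect_partition_equal(pr, s$partition,
                         list(c("B1", "R1"), c("B2", "W1", "R2", "W2", "W3")))
  expect_equal(s$star_nodes, lca_node(pr$t2, c("R1", "B1")))
  expect_false(partition_overlaps_in(pr, s$partition, "V2"))
  expect_true(is_K_compatible(pr, s$partition, c(col$R, col$B)))

  # already-compatible partitions are untouched
  s0 <- make_rb_compatible(pr, s$partition, col)
  expect_partition_equal(pr, s0$partition,
                         list(c("B1", "R1"), c("B2", "W1", "R2", "W2", "W3")))
  expect_length(s0$star_nodes, 0L)
})

test_that("make_splittable picks the forced node and leaves splittable non-overlapping parts", {
  pr <- rbw()
  col <- make_coloring(pr, lca_node(pr$t1, c("R1", "B1")))
  P_c <- as_partition(pr, list("R1", c("B1", "B2", "W1", "R2", "W2"), "W3"))
  s <- make_splittable(pr, P_c, col)
  expect_partition_equal(pr, s$partition,
                         list("R1", c("B2", "W1"), c("B1", "R2", "W2"), "W3"))
  expect_equal(s$star_nodes, lca_node(pr$t2, c("B2", "W1")))
  expect_false(partition_overlaps_in(pr, s$partition, "V2"))
  expect_true(all(vapply(s$partition, function(A) is_splittable(pr, A, col), logical(1))))

  pr5 <- worked_examples()$not_rb_feasible
  col5 <- make_coloring(pr5, lca_node(pr5$t1, c("B1", "R1")))
  s5 <- make_splittable(pr5, as_partition(pr5, list(pr5$labels)), col5)
  expect_partition_equal(pr5, s5$partition,
                         list(c("B1", "W1"), c("B2", "W2", "R1")))
})

test_that("split separates color classes, with the special cases on top components", {
  pr <- rbw()
  col <- make_coloring(pr, lca_node(pr$t1, c("R1", "B1")))
  # plain splitting: everything becomes a singleton
  P_t <- as_partition(pr, list("R1", c("B2", "W1"), c("B1", "R2", "W2"), "W3"))
  s <- split_components(pr, P_t, col)
  expect_partition_equal(pr, s$partition, as.list(pr$labels))
  expect_length(s$special_events, 0L)

  # the four-way special split: one tricolored top component with a
  # compatible and an incompatible tricolored triple
  P <- as_partition(pr, list(c("B1", "R1"), c("B2", "W1", "R2", "W2", "W3")))
  expect_true(triple_compatible(pr, "B2", "R2", "W3"))
  expect_false(triple_compatible(pr, "B2", "R2", "W2"))
  s4 <- split_components(pr, P, col)
  expect_partition_equal(pr, s4$partition,
    list("B1", "R1", "B2", "R2", c("W1", "W2"), "W3"))
  ev <- Filter(function(e) e$kind == "four_way", s4$special_events)
  expect_length(ev, 1L)
  expect_equal(ev[[1L]]$u_hat0, lca_node(pr$t2, c("B2", "R2")))
  expect_equal(s4$star_nodes, ev[[1L]]$u_hat0)

  # unicolored-only partitions pass through
  singles <- as_partition(pr, as.list(pr$labels))
  expect_partition_equal(pr, split_components(pr, singles, col)$partition,
                         as.list(pr$labels))
})

test_that("two-way special splits are undone by the merge search", {
  # this seeded instance is known to trigger a two-way Special-Split (a
  # tricolored top component in which every tricolored triple is
  # compatible); condition (a) of the merge search must then undo it
  pr <- random_pair(5, seed = 7002, rho = TRUE)
  res <- red_blue(pr)
  two_iter <- NULL
  for (k in seq_along(res$traces)) {
    evs <- res$traces[[k]]$special_events
    if (any(vapply(evs, function(e) e$kind == "two_way", logical(1)))) two_iter <- k
  }
  expect_false(is.null(two_iter))
  tr <- res$traces[[two_iter]]
  col <- tr$coloring
  mp <- find_merge_pair(pr, tr$P3, col, tr$P0, events = tr$special_events)
  expect_false(is.null(mp))
  expect_identical(mp, tr$merge_pair)
  expect_true(all(mp %in% c(col$R, col$B)))
  # the pair spans two current components but one start component
  in_comp <- function(P, x) which(vapply(P, function(A) x %in% A, logical(1)))
  expect_false(in_comp(tr$P3, mp[[1L]]) == in_comp(tr$P3, mp[[2L]]))
  expect_equal(in_comp(tr$P0, mp[[1L]]), in_comp(tr$P0, mp[[2L]]))
  # merging those two components keeps (RuB)-feasibility
  merged <- agreeforest:::merge_two(tr$P3,
                                    tr$P3[[in_comp(tr$P3, mp[[1L]])]],
                                    tr$P3[[in_comp(tr$P3, mp[[2L]])]])
  expect_true(is_K_feasible(pr, merged, c(col$R, col$B)))
  expect_true(is_feasible(pr, res$forest))
})

test_that("merge_components is an order-independent transitive coarsening", {
  P <- agreeforest:::canonical_partition(list(1L, 2L, 3L, 4L))
  expect_equal(length(merge_components(P, list())), 4L)
  chain <- list(c(1L, 2L), c(2L, 3L))
  M <- merge_components(P, chain)
  expect_equal(length(M), 2L)
  expect_setequal(M[[1L]], 1:3)
  pairs3 <- list(c(1L, 2L), c(3L, 4L), c(2L, 3L))
  keys <- vapply(list(pairs3, rev(pairs3), pairs3[c(2, 1, 3)]),
                 function(pl) agreeforest:::partition_key(merge_components(P, pl)),
                 character(1))
  expect_equal(length(unique(keys)), 1L)
  expect_error(merge_components(P, list(c(1L, 9L))), "absent")
})

test_that("full runs return feasible forests with the certified guarantee", {
  id <- pair_id()
  res <- red_blue(id)
  expect_equal(res$cuts, 0L)
  expect_equal(length(res$forest), 1L)

  pr <- pair3_rho()
  res <- red_blue(pr)
  opt <- exact_maf(pr)$opt_cuts
  expect_equal(opt, 1L)
  expect_gte(res$cuts, 1L)
  expect_lte(res$cuts, 2L * opt)

  # exhaustive 3-leaf sweep plus random instances: feasibility,
  # iteration bound, dual inequality, 2-approximation
  pairs <- c(lapply(enumerate_all_tree_pairs(3), augment_rho),
             random_small_pairs(12, seed0 = 500))
  for (prr in pairs) {
    r <- red_blue(prr)
    expect_true(is_feasible(prr, r$forest))
    expect_lt(r$iterations, prr$n)
    expect_equal(r$cuts, length(r$dual$z_components) - 1L - length(r$pairslist))
    D <- r$certificate$dual_objective
    expect_gte(2 * D, r$cuts)
    o <- exact_maf(prr)$opt_cuts
    expect_lte(r$cuts, 2 * max(o, 0L) + (o == 0L) * 0L)
    expect_lte(D, o)
    if (o == 0L) expect_equal(r$cuts, 0L)
  }
})

test_that("iteration traces satisfy the structural invariants of the refinement stages", {
  # properties checked on every trace of a varied instance collection:
  #  - at iteration start the multicolored components are one tricolored
  #    or at most two bicolored
  #  - only multicolored components are subdivided before Split
  #  - Make-Splittable preserves the tricolored count
  #  - non-top tricolored components have no compatible tricolored triple
  #  - non-top bicolored components sit below an lca whose two child
  #    subtrees are unicolored within the component
  #  - once an iteration ends, its R u B labels are never re-separated
  pairs <- c(list(rbw()), random_small_pairs(10, seed0 = 520))
  for (prr in pairs) {
    r <- red_blue(prr)
    for (tr in r$traces) {
      col <- tr$coloring
      ncols <- function(A) length(agreeforest:::colors_of(A, col))
      multi0 <- Filter(function(A) ncols(A) >= 2L, tr$P0)
      tri0 <- Filter(function(A) ncols(A) == 3L, tr$P0)
      expect_true((length(tri0) == 1L && length(multi0) == 1L) ||
                  (length(tri0) == 0L && length(multi0) <= 2L))

      key <- function(A) paste(A, collapse = ",")
      p2keys <- vapply(tr$P2, key, character(1))
      for (A in tr$P0) {
        if (!(key(A) %in% p2keys)) expect_gte(ncols(A), 2L)
      }
      expect_equal(sum(vapply(tr$P2, function(A) ncols(A) == 3L, logical(1))),
                   sum(vapply(tr$P1, function(A) ncols(A) == 3L, logical(1))))
      for (i in seq_along(tr$P2)) {
        A <- tr$P2[[i]]
        if (tr$top2[[i]]) next
        if (ncols(A) == 3L) {
          expect_false(agreeforest:::has_compatible_tricolored_triple(prr, A, col))
        }
        if (ncols(A) == 2L) {
          lca2A <- agreeforest:::lca_of(prr, A, 2L)
          for (ch in prr$t2$children[[lca2A]]) {
            part <- intersect(A, agreeforest:::labels_below(prr, ch, 2L))
            expect_lte(ncols(part), 1L)
          }
        }
      }
      # the V2 non-overlap invariant after every stage
      for (Pst in list(tr$P1, tr$P2, tr$P3)) {
        expect_false(partition_overlaps_in(prr, Pst, "V2"))
      }
      # white-leaf persistence: a white leaf of A0 above lca2(A0 n (RuB))
      # either keeps its component intact or lands in a top component
      for (A in tr$P0) {
        rb <- intersect(A, c(col$R, col$B))
        if (!length(rb) || !length(intersect(A, col$W))) next
        below <- agreeforest:::labels_below(prr, agreeforest:::lca_of(prr, rb, 2L), 2L)
        for (xw in setdiff(intersect(A, col$W), below)) {
          inP2 <- key(A) %in% p2keys
          if (!inP2) {
            i <- which(vapply(tr$P2, function(C) xw %in% C, logical(1)))
            expect_true(tr$top2[[i]])
          }
        }
      }
    }
    # no-resplit across iterations (also binds the final forest)
    later_parts <- c(lapply(r$traces, `[[`, "P3"), list(r$dual$z_components))
    for (i in seq_along(r$traces)) {
      col <- r$traces[[i]]$coloring
      RB <- c(col$R, col$B)
      Pend <- r$traces[[i]]$P3
      for (A in Pend) {
        ARB <- intersect(A, RB)
        if (length(ARB) < 2L) next
        for (j in seq(i, length(later_parts))) {
          if (j == i) next
          comp_of <- vapply(ARB, function(x) {
            which(vapply(later_parts[[j]], function(C) x %in% C, logical(1)))
          }, integer(1))
          expect_equal(length(unique(comp_of)), 1L)
        }
      }
    }
  }
})

test_that("swapping left and right children keeps feasibility and the guarantee", {
  swap_children <- function(nwk) {
    tr <- parse_newick(nwk)
    rec <- function(v) {
      ch <- tr$children[[v]]
      if (!length(ch)) return(tr$tip_label[[v]])
      paste0("(", rec(ch[[2L]]), ",", rec(ch[[1L]]), ")")
    }
    paste0(rec(tr$root), ";")
  }
  for (i in 1:6) {
    sp <- random_spr_pair(6, 2, seed = 540 + i, rho = FALSE)
    pr <- augment_rho(tree_pair(sp$t1, sp$t2))
    prs <- augment_rho(tree_pair(swap_children(write_newick(sp$t1)),
                                 write_newick(sp$t2)))
    o <- exact_maf(pr)$opt_cuts
    for (p in list(pr, prs)) {
      r <- red_blue(p)
      expect_true(is_feasible(p, r$forest))
      if (o > 0) expect_lte(r$cuts, 2 * o)
    }
    expect_equal(exact_maf(prs)$opt_cuts, o)
  }
})
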