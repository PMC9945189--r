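test_that("triple compatibility matches the lca biconditional definition", {
  pr <- pair_id()
  cmb <- utils::combn(pr$n, 3L)
  for (j in seq_len(ncol(cmb))) {
    expect_true(triple_compatible(pr, cmb[1, j], cmb[2, j], cmb[3, j]))
  }
  bad <- pair3()
  expect_false(triple_compatible(bad, "a", "b", "c"))
  expect_error(triple_compatible(bad, "a", "a", "b"), "distinct|duplicate")

  # the cherry test agrees with the definitional biconditional everywhere
  for (rep in 1:5) {
    pr <- random_pair(6, seed = 200 + rep, rho = FALSE)
    cmb <- utils::combn(pr$n, 3L)
    for (j in seq_len(ncol(cmb))) {
      expect_equal(triple_compatible(pr, cmb[1, j], cmb[2, j], cmb[3, j]),
                   agreeforest:::triple_compatible_def(pr, cmb[1, j], cmb[2, j], cmb[3, j]))
    }
  }
})

test_that("set compatibility equals the all-triples brute force on every subset", {
  pr <- rbw()
  expect_true(is_compatible(pr, c("R1", "R2", "W3")))
  expect_true(is_compatible(pr, c("B1", "B2", "W3")))
  # the worked example's case-(c) discussion: {B1,B2} extended by W2 stays fine
  expect_true(is_compatible(pr, c("B1", "B2", "W2")))
  for (prr in c(list(pr), random_small_pairs(4, seed0 = 210, rho = FALSE))) {
    for (L in all_subsets(prr$n)) {
      expect_equal(is_compatible(prr, L),
                   agreeforest:::is_compatible_triples(prr, L))
    }
  }
  # monotonicity: subsets of compatible sets are compatible
  pr <- random_pair(7, seed = 321, rho = FALSE)
  for (L in all_subsets(pr$n)[sample.int(2^pr$n - 1, 40)]) {
    if (is_compatible(pr, L) && length(L) > 1L) {
      expect_true(is_compatible(pr, L[-1L]))
    }
  }
})

test_that("cover and overlap follow the spanned-node definitions", {
  pr <- tree_pair("((a,b),c);", "((a,c),b);")
  expect_true(covers(pr, "a", match("a", pr$t1$tip_label), 1L))
  expect_false(covers(pr, character(0), pr$t1$root, 1L))
  expect_true(covers(pr, c("a", "c"), pr$t1$root, 1L))

  pr4 <- pair_id("((a,b),(c,d));")
  expect_false(overlap(pr4, c("a", "b"), c("c", "d")))
  expect_true(overlap(pr4, c("a", "b"), c("a", "d")))
  # symmetry
  for (rep in 1:3) {
    prr <- random_pair(6, seed = 230 + rep, rho = FALSE)
    for (k in 1:10) {
      A <- sample(prr$n, sample(2:3, 1)); B <- sample(prr$n, sample(2:3, 1))
      expect_equal(overlap(prr, A, B), overlap(prr, B, A))
    }
  }
  # the stored non-(RuB)-feasible instance: those two components do not
  # meet anywhere in the second tree
  pr5 <- worked_examples()$not_rb_feasible
  expect_false(overlap(pr5, c("B1", "W1"), c("B2", "W2", "R1"), "V2"))
})

test_that("partition overlap detects shared nodes and edge-deletion forests never overlap in V2", {
  pr <- pair_id()
  singles <- as_partition(pr, as.list(pr$labels))
  expect_false(partition_overlaps_in(pr, singles, "all"))
  expect_false(partition_overlaps_in(pr, as_partition(pr, list(pr$labels)), "all"))

  set.seed(77)
  for (rep in 1:8) {
    prr <- random_pair(sample(5:8, 1), seed = 240 + rep, rho = FALSE)
    t2 <- prr$t2
    cuttable <- which(t2$parent != 0L)
    cuts <- sample(cuttable, sample(1:3, 1))
    # partition = leaf sets of the forest obtained by cutting T2 edges
    comp <- integer(t2$N)
    for (v in order(t2$depth)) {
      comp[[v]] <- if (t2$parent[[v]] == 0L) 1L
                   else if (v %in% cuts) max(comp) + 1L
                   else comp[[t2$parent[[v]]]]
    }
    tipc <- comp[prr$tip2]
    P <- lapply(unique(tipc), function(g) which(tipc == g))
    expect_false(partition_overlaps_in(prr, agreeforest:::canonical_partition(P), "V2"))
  }
})

test_that("K-compatibility follows the intersection definition", {
  pr <- rbw()
  P <- as_partition(pr, list(pr$labels))
  expect_true(is_K_compatible(pr, P, character(0)))
  expect_equal(is_K_compatible(pr, P, pr$labels),
               all(vapply(P, function(A) is_compatible(pr, A), logical(1))))
  # the first refinement of the worked example is (RuB)-compatible
  P1 <- as_partition(pr, list(c("B1", "R1"), c("B2", "W1", "R2", "W2", "W3")))
  expect_true(is_K_compatible(pr, P1, c("R1", "R2", "B1", "B2")))
  # preserved under refinement
  P2 <- as_partition(pr, list(c("B1", "R1"), c("B2", "W1"), c("R2", "W2", "W3")))
  expect_true(is_K_compatible(pr, P2, c("R1", "R2", "B1", "B2")))
})

test_that("splittability checks color-class overlap in the second tree", {
  pr <- rbw()
  col <- make_coloring(pr, lca_node(pr$t1, c("R1", "B1")))
  expect_true(is_splittable(pr, c("W1", "W2", "W3"), col))       # unicolored
  expect_true(is_splittable(pr, c("B1", "R1"), col))
  expect_true(is_splittable(pr, c("B2", "W1", "R2", "W2", "W3"), col))
  expect_false(is_splittable(pr, c("B1", "B2", "W1", "R2", "W2"), col))
})

test_that("feasibility and K-feasibility match their definitions", {
  pr <- pair3()
  expect_true(is_feasible(pr, as_partition(pr, as.list(pr$labels))))
  expect_true(is_feasible(pair_id(), as_partition(pair_id(), list(pair_id()$labels))))
  expect_false(is_feasible(pr, as_partition(pr, list(pr$labels))))

  # full-label K-feasibility coincides with feasibility
  for (rep in 1:4) {
    prr <- random_pair(5, seed = 260 + rep, rho = FALSE)
    for (k in 1:6) {
      # random partition
      g <- sample(1:3, prr$n, replace = TRUE)
      P <- lapply(unique(g), function(x) which(g == x))
      P <- agreeforest:::canonical_partition(P)
      expect_equal(is_feasible(prr, P), is_K_feasible(prr, P, seq_len(prr$n)))
    }
  }

  ex <- worked_examples()
  pr5 <- ex$not_rb_feasible
  P5 <- as_partition(pr5, list(pr5$labels))
  RB5 <- c("R1", "B1", "B2")
  expect_true(is_K_compatible(pr5, P5, RB5))
  expect_false(partition_overlaps_in(pr5, P5, "all"))
  expect_false(is_K_feasible(pr5, P5, RB5))

  pr6 <- ex$subtle_root
  P6 <- as_partition(pr6, list(pr6$labels))
  expect_true(is_compatible(pr6, c("x1", "x2", "x3")))
  expect_false(is_compatible(pr6, c("x1", "x2", "x3", "w1")))
  expect_true(is_compatible(pr6, c("x1", "x2", "x3", "w2")))
  expect_false(is_K_feasible(pr6, P6, c("x1", "x2", "x3")))
  # yet the subtree node is not a root of infeasibility: the scan picks a
  # different (higher) node
  roi <- lowest_root_of_infeasibility(pr6, P6)
  expect_false(identical(roi$u, lca_node(pr6$t1, c("x1", "x2", "x3"))))
})
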