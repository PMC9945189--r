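# Shared fixtures and independent oracles for the test suite.

# the smallest conflicting pair (one bad triple), raw and rho-augmented
pair3 <- function() tree_pair("((a,b),c);", "((a,c),b);")
pair3_rho <- function() augment_rho(pair3())
pair_id <- function(nwk = "((a,b),(c,d));") tree_pair(nwk, nwk)

rbw <- function() worked_examples()$rbw

# independent path oracle: nodes on the path between two tips via the
# parent chains (union over all tip pairs gives the spanned node set)
path_nodes_oracle <- function(tree, tips) {
  if (length(tips) == 0L) return(integer(0))
  if (length(tips) == 1L) return(as.integer(tips))
  anc_chain <- function(v) {
    out <- v
    while (tree$parent[[v]] != 0L) { v <- tree$parent[[v]]; out <- c(out, v) }
    out
  }
  out <- integer(0)
  cmb <- utils::combn(tips, 2L)
  for (j in seq_len(ncol(cmb))) {
    ca <- anc_chain(cmb[1L, j]); cb <- anc_chain(cmb[2L, j])
    l <- intersect(ca, cb)[[1L]]
    out <- c(out, ca[seq_len(match(l, ca))], cb[seq_len(match(l, cb))])
  }
  sort(unique(out))
}

# all nonempty label subsets of a (small) pair
all_subsets <- function(n) {
  unlist(lapply(seq_len(2L^n - 1L), function(m) {
    list(which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0L))
  }), recursive = FALSE)
}

# deterministic small random instances reused across files
random_small_pairs <- function(k, seed0 = 400L, nmin = 4L, nmax = 8L, rho = TRUE) {
  lapply(seq_len(k), function(i) {
    n <- nmin + ((seed0 + i) %% (nmax - nmin + 1L))
    random_pair(n, seed = seed0 + i, rho = rho)
  })
}

expect_partition_equal <- function(pair, P, expected_labels) {
  exp_part <- as_partition(pair, expected_labels)
  expect_identical(agreeforest:::partition_key(agreeforest:::canonical_partition(P)),
                   agreeforest:::partition_key(exp_part))
}
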