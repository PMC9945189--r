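# Exact solver (ground truth on small instances) and exhaustive
# instance enumeration.

#' Exact maximum agreement forest by brute force
#'
#' Enumerates k-subsets of the first tree's edges for k = 0, 1, 2, ... and
#' returns the first edge set whose induced leaf-set partition is a
#' feasible agreement forest.  Feasibility of each candidate checks
#' component compatibility and pairwise non-overlap in the second tree
#' (first-tree non-overlap is automatic for edge-deletion forests).
#' Enumerating deletions in one tree suffices: any feasible partition has
#' pairwise-disjoint first-tree spans and hence arises from some edge
#' deletion set of the first tree.
#'
#' @param pair a `maf_pair`.
#' @param cap maximum number of cuts to try (also guards the search
#'   space).
#' @param max_labels refuse larger instances (enumeration is
#'   exponential).
#' @return list with `opt_cuts`, `opt_forest` (a partition) and `method`.
#' @examples
#' pr <- augment_rho(tree_pair("((a,b),c);", "((a,c),b);"))
#' exact_maf(pr)$opt_cuts
#' @export
exact_maf <- function(pair, cap = 12L, max_labels = 14L) {
  stopifnot(inherits(pair, "maf_pair"))
  if (pair$n > max_labels) {
    stop("instance too large for the brute-force oracle (", pair$n,
         " > ", max_labels, " labels)")
  }
  res <- .exact_maf_cpp(pair$t1$parent - 1L, pair$tip1 - 1L,
                        pair$t2$parent - 1L, pair$tip2 - 1L,
                        pair$n, as.integer(cap))
  if (res$k < 0L) stop("no feasible forest within cap = ", cap, " cuts")
  forest <- canonical_partition(res$components)
  if (length(forest) - 1L != res$k) {
    stop("oracle inconsistency: ", res$k, " cuts produced ",
         length(forest), " components")
  }
  list(opt_cuts = res$k, opt_forest = forest, method = "edge_enum")
}

#' All labelled rooted binary topologies on given labels
#'
#' Generated by sequential insertion (each tree on i leaves arises from
#' exactly one tree on i-1 leaves and one insertion position), giving the
#' (2n-3)!! distinct topologies in a deterministic order.
#'
#' @param labels character vector of leaf labels (2 to 7 of them).
#' @return character vector of Newick strings.
#' @export
all_topologies <- function(labels) {
  n <- length(labels)
  if (n < 2L || n > 7L) stop("supported for 2..7 labels")
  trees <- list(paste0("(", labels[[1L]], ",", labels[[2L]], ")"))
  if (n > 2L) {
    for (i in 3:n) {
      lab <- labels[[i]]
      out <- list()
      for (s in trees) {
        # insertion points: every subtree occurrence (non-root edges and
        # the two root children) plus above the root
        out <- c(out, insert_everywhere(s, lab))
      }
      trees <- out
    }
  }
  vapply(trees, function(s) paste0(s, ";"), character(1))
}

# all ways to replace one subtree X of `s` by (X,lab), plus (s,lab)
insert_everywhere <- function(s, lab) {
  # parse into token spans of subtrees
  out <- list(paste0("(", s, ",", lab, ")"))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  nch <- length(chars)
  i <- 1L
  while (i <= nch) {
    ch <- chars[[i]]
    if (ch == "(") {
      # find matching ) to get a subtree span (skip the full string span,
      # already handled as "above root")
      depthc <- 0L
      j <- i
      repeat {
        if (chars[[j]] == "(") depthc <- depthc + 1L
        if (chars[[j]] == ")") depthc <- depthc - 1L
        if (depthc == 0L) break
        j <- j + 1L
      }
      if (!(i == 1L && j == nch)) {
        sub <- paste(chars[i:j], collapse = "")
        out[[length(out) + 1L]] <-
          paste0(substr(s, 1L, i - 1L), "(", sub, ",", lab, ")",
                 substr(s, j + 1L, nch))
      }
      i <- i + 1L
    } else if (ch %in% c(",", ")")) {
      i <- i + 1L
    } else {
      # a leaf name: read it fully
      j <- i
      while (j <= nch && !(chars[[j]] %in% c("(", ")", ","))) j <- j + 1L
      leaf <- paste(chars[i:(j - 1L)], collapse = "")
      out[[length(out) + 1L]] <-
        paste0(substr(s, 1L, i - 1L), "(", leaf, ",", lab, ")",
               substr(s, j, nch))
      i <- j
    }
  }
  out
}

#' Enumerate all ordered tree pairs on n labels
#'
#' All ordered pairs (equal pairs included) of labelled rooted binary
#' topologies on `n` fixed labels, in deterministic order.  Counts per
#' tree: 1, 3, 15, 105 for n = 2..5.
#'
#' @param n leaf count, at most 5.
#' @param labels optional label vector (default `a`, `b`, ...).
#' @return list of `maf_pair` objects.
#' @export
enumerate_all_tree_pairs <- function(n, labels = letters[seq_len(n)]) {
  if (n > 5L) stop("exhaustive enumeration supported for n <= 5")
  tops <- all_topologies(labels)
  out <- vector("list", length(tops)^2)
  k <- 0L
  for (s1 in tops) for (s2 in tops) {
    k <- k + 1L
    out[[k]] <- tree_pair(s1, s2)
  }
  out
}
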