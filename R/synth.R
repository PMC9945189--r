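# Instance generation: uniformly random labelled rooted binary trees,
# pairs related by a bounded number of rooted SPR moves, and the encoded
# worked-example fixtures.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# mutable flat tree used by the generators: parent/children arrays over
# node slots, leaf slots carry labels
gen_tree_new <- function(lab1, lab2) {
  list(parent = c(3L, 3L, 0L), children = list(integer(0), integer(0), c(1L, 2L)),
       label = c(lab1, lab2, NA), root = 3L)
}

gen_tree_newick <- function(g) {
  rec <- function(v) {
    ch <- g$children[[v]]
    if (!length(ch)) return(g$label[[v]])
    paste0("(", rec(ch[[1L]]), ",", rec(ch[[2L]]), ")")
  }
  paste0(rec(g$root), ";")
}

# attach a new labelled leaf onto the parent edge of `at` (or above the
# root when at == 0)
gen_attach <- function(g, at, lab) {
  nv <- length(g$parent)
  leaf <- nv + 1L; joint <- nv + 2L
  g$parent <- c(g$parent, 0L, 0L)
  g$children <- c(g$children, list(integer(0), integer(0)))
  g$label <- c(g$label, lab, NA)
  if (at == 0L) {
    g$children[[joint]] <- c(g$root, leaf)
    g$parent[[g$root]] <- joint
    g$parent[[leaf]] <- joint
    g$parent[[joint]] <- 0L
    g$root <- joint
  } else {
    p <- g$parent[[at]]
    g$children[[p]][g$children[[p]] == at] <- joint
    g$children[[joint]] <- c(at, leaf)
    g$parent[[at]] <- joint
    g$parent[[leaf]] <- joint
    g$parent[[joint]] <- p
  }
  g
}

#' Uniformly random labelled rooted binary tree
#'
#' Sequential random insertion: leaf i is attached to an edge (or above
#' the root) of the tree on the first i-1 leaves, chosen uniformly among
#' the 2i-3 positions.  This yields the uniform distribution over the
#' (2n-3)!! labelled rooted binary topologies.  Identical seeds give
#' identical trees.
#'
#' @param n number of leaves (>= 2).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param labels leaf labels, default `t1..tn`.
#' @return a `maf_tree`.
#' @export
random_tree <- function(n, seed = NULL, labels = paste0("t", seq_len(n))) {
  if (n < 2L) stop("need at least 2 leaves")
  stopifnot(length(labels) == n)
  with_seed(seed, {
    g <- gen_tree_new(labels[[1L]], labels[[2L]])
    if (n > 2L) {
      for (i in 3:n) {
        non_root <- which(g$parent != 0L)
        at <- sample(c(0L, non_root), 1L)
        g <- gen_attach(g, at, labels[[i]])
      }
    }
    parse_newick(gen_tree_newick(g))
  })
}

# one random rooted SPR move on the flat representation; returns NULL
# when no legal move exists
gen_spr_move <- function(g) {
  non_root <- which(g$parent != 0L)
  prunable <- sample(non_root, length(non_root))
  for (v in prunable) {
    p <- g$parent[[v]]
    sib <- setdiff(g$children[[p]], v)
    # detach v: suppress p
    g2 <- g
    if (g2$parent[[p]] == 0L) {
      g2$root <- sib
      g2$parent[[sib]] <- 0L
    } else {
      gp <- g2$parent[[p]]
      g2$children[[gp]][g2$children[[gp]] == p] <- sib
      g2$parent[[sib]] <- gp
    }
    g2$children[[p]] <- integer(0)
    g2$parent[[p]] <- -1L   # orphaned slot
    # nodes inside the pruned subtree
    in_sub <- logical(length(g2$parent))
    stack <- v
    while (length(stack)) {
      x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      in_sub[[x]] <- TRUE
      stack <- c(stack, g2$children[[x]])
    }
    # regraft candidates: parent edges in the remaining tree, except the
    # old sibling position (a no-op)
    cand <- which(g2$parent > 0L & !in_sub)
    cand <- setdiff(cand, sib)
    cand <- setdiff(cand, p)
    if (!length(cand)) next
    at <- if (length(cand) == 1L) cand else sample(cand, 1L)
    # reuse slot p as the new joint
    q <- g2$parent[[at]]
    g2$children[[q]][g2$children[[q]] == at] <- p
    g2$children[[p]] <- c(at, v)
    g2$parent[[at]] <- p
    g2$parent[[v]] <- p
    g2$parent[[p]] <- q
    return(g2)
  }
  NULL
}

gen_from_tree <- function(tree) {
  list(parent = tree$parent, children = tree$children,
       label = c(tree$tip_label, rep(NA, tree$N - tree$ntip)),
       root = tree$root)
}

#' Random pair related by k rooted SPR moves
#'
#' The second tree is obtained from the first by `k_spr` random
#' prune-and-regraft moves (prune a non-root subtree, regraft onto an
#' edge outside it other than its original position), so the rSPR
#' distance -- and hence the rho-augmented MAF optimum -- is at most the
#' number of moves actually performed.
#'
#' @param n number of leaves.
#' @param k_spr number of SPR moves to attempt.
#' @param seed optional integer seed.
#' @param labels leaf labels.
#' @param rho augment the returned pair with the root label (default
#'   TRUE, matching rSPR semantics).
#' @return list with `pair` (a `maf_pair`), `k_used` and the two trees.
#' @export
random_spr_pair <- function(n, k_spr, seed = NULL,
                            labels = paste0("t", seq_len(n)), rho = TRUE) {
  with_seed(seed, {
    t1 <- random_tree(n, seed = NULL, labels = labels)
    g <- gen_from_tree(t1)
    k_used <- 0L
    if (k_spr > 0L) {
      for (i in seq_len(k_spr)) {
        g2 <- gen_spr_move(g)
        if (is.null(g2)) break
        g <- g2
        k_used <- k_used + 1L
      }
    }
    t2 <- parse_newick(gen_tree_newick(g))
    pr <- tree_pair(t1, t2)
    if (rho) pr <- augment_rho(pr)
    list(pair = pr, k_used = k_used, t1 = t1, t2 = t2)
  })
}

#' Uniformly random tree pair
#'
#' Two independent uniformly random topologies on the same labels.
#'
#' @inheritParams random_spr_pair
#' @return a `maf_pair` (rho-augmented when `rho` is TRUE).
#' @export
random_pair <- function(n, seed = NULL, labels = paste0("t", seq_len(n)),
                        rho = TRUE) {
  with_seed(seed, {
    t1 <- random_tree(n, labels = labels)
    t2 <- random_tree(n, labels = labels)
    pr <- tree_pair(t1, t2)
    if (rho) pr <- augment_rho(pr)
    pr
  })
}

#' Bundled worked-example instances
#'
#' Small instances stored with the package: the recurring red/blue/white
#' example on seven leaf groups that exercises all three
#' root-of-infeasibility conditions and every refinement procedure
#' (`rbw`), an instance whose trivial partition is (R u B)-compatible and
#' non-overlapping yet not (R u B)-feasible (`not_rb_feasible`), an
#' instance whose subtree is compatible but not extendably so
#' (`subtle_root`), and a synthetic instance achieving the 5/4
#' integrality gap of the set-partition relaxation (`gap54`,
#' computationally constructed).
#'
#' @return named list of `maf_pair` objects.
#' @export
worked_examples <- function() {
  read_fix <- function(stem) {
    d <- system.file("extdata", package = "agreeforest")
    t1 <- readLines(file.path(d, paste0(stem, "_t1.nwk")), warn = FALSE)
    t2 <- readLines(file.path(d, paste0(stem, "_t2.nwk")), warn = FALSE)
    tree_pair(paste(t1, collapse = ""), paste(t2, collapse = ""))
  }
  out <- list(rbw = read_fix("rbw_example"),
              not_rb_feasible = read_fix("not_rb_feasible"),
              subtle_root = read_fix("subtle_root"))
  gp <- system.file("extdata", "gap54_synthetic_t1.nwk", package = "agreeforest")
  if (nzchar(gp)) out$gap54 <- read_fix("gap54_synthetic")
  out
}
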