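#' @useDynLib agreeforest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal rooted-binary-tree representation
# --------------------------------------------------------------------------
# Nodes are integers 1..N with tips 1..ntip (ape numbering).  On top of the
# parent/children maps we precompute, once per tree:
#   depth      root has depth 0
#   postorder  children always precede their parent
#   porank     position of each node in `postorder` (deterministic tie-break
#              order for "lowest node" choices)
#   desc       N x ntip logical; desc[v, i] iff tip i is a descendant of v
#              (every node is a descendant of itself)
# Leaf labels are unique non-empty strings; internal-node labels and branch
# lengths in the input are discarded.

new_maf_tree <- function(parent, children, root, tip_label) {
  ntip <- length(tip_label)
  N <- length(parent)
  depth <- integer(N)
  # breadth-first from root
  queue <- root
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    ch <- children[[v]]
    if (length(ch)) {
      depth[ch] <- depth[v] + 1L
      queue <- c(queue, ch)
    }
  }
  postorder <- integer(N)
  k <- 0L
  # iterative post-order DFS following stored child order
  stack <- list(list(v = root, i = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    ch <- children[[top$v]]
    if (top$i < length(ch)) {
      stack[[length(stack)]]$i <- top$i + 1L
      stack[[length(stack) + 1L]] <- list(v = ch[[top$i + 1L]], i = 0L)
    } else {
      k <- k + 1L
      postorder[k] <- top$v
      stack[[length(stack)]] <- NULL
    }
  }
  porank <- integer(N)
  porank[postorder] <- seq_len(N)
  desc <- matrix(FALSE, nrow = N, ncol = ntip)
  for (v in postorder) {
    ch <- children[[v]]
    if (!length(ch)) {
      desc[v, v] <- TRUE
    } else {
      desc[v, ] <- desc[ch[[1L]], ] | desc[ch[[2L]], ]
    }
  }
  structure(
    list(parent = parent, children = children, root = root,
         tip_label = tip_label, ntip = ntip, N = N, depth = depth,
         postorder = postorder, porank = porank, desc = desc),
    class = "maf_tree")
}

#' @export
print.maf_tree <- function(x, ...) {
  cat("Rooted binary tree:", x$ntip, "leaves,", x$N, "nodes\n")
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

#' Parse a rooted binary tree from a Newick string
#'
#' Reads a single rooted tree in Newick format.  All leaves must carry
#' distinct non-empty names; internal-node labels and branch lengths are
#' accepted and discarded.  Strict binarity is enforced: any internal node
#' with a number of children different from two is rejected (no automatic
#' resolution of polytomies).  The order in which children are written is
#' preserved and used for deterministic iteration (the first-written child
#' is the "left" child); it carries no semantics.
#'
#' @param text a Newick string (trailing semicolon optional).
#' @return an object of class `maf_tree`.
#' @examples
#' tr <- parse_newick("((a,b),c);")
#' leaves_below(tr, tr$root)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  ph <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)),
                 warning = function(w) stop("malformed Newick: ", conditionMessage(w)))
  if (is.null(ph)) stop("malformed Newick: could not parse")
  as_maf_tree(ph)
}

#' Convert an ape "phylo" tree to the internal representation
#'
#' @param ph an [ape::read.tree()] style `phylo` object.
#' @return a `maf_tree`.
#' @export
as_maf_tree <- function(ph) {
  if (!inherits(ph, "phylo")) stop("expected a 'phylo' object")
  ntip <- length(ph$tip.label)
  if (ntip == 1L) stop("tree must have at least 2 leaves")
  if (anyDuplicated(ph$tip.label)) {
    dup <- unique(ph$tip.label[duplicated(ph$tip.label)])
    stop("duplicate leaf name(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(ph$tip.label))) stop("all leaves must be named")
  N <- ntip + ph$Nnode
  parent <- integer(N)
  children <- vector("list", N)
  for (i in seq_len(N)) children[[i]] <- integer(0)
  for (r in seq_len(nrow(ph$edge))) {
    p <- ph$edge[r, 1L]; v <- ph$edge[r, 2L]
    parent[v] <- p
    children[[p]] <- c(children[[p]], v)
  }
  root <- ntip + 1L
  nch <- lengths(children)
  bad <- which(nch != 2L & seq_len(N) > ntip)
  if (length(bad)) {
    stop("tree is not binary: internal node ", bad[[1L]], " has ",
         nch[bad[[1L]]], " children")
  }
  new_maf_tree(parent, children, root, ph$tip.label)
}

#' Serialize a tree to Newick
#'
#' Round-trip stable: `parse_newick(write_newick(t))` reproduces `t` with
#' identical leaf labels and child order.
#'
#' @param tree a `maf_tree`.
#' @return a Newick string ending in `";"`.
#' @export
write_newick <- function(tree) {
  rec <- function(v) {
    ch <- tree$children[[v]]
    if (!length(ch)) return(tree$tip_label[[v]])
    paste0("(", rec(ch[[1L]]), ",", rec(ch[[2L]]), ")")
  }
  paste0(rec(tree$root), ";")
}

#' Pair two trees over the same leaf-label set
#'
#' A MAF instance is a pair of rooted binary trees with a common label set.
#' The common label universe is stored sorted; throughout the package a
#' leaf subset is represented by integer indices into this sorted universe
#' (`pair$labels`), and partitions as lists of such index vectors.
#'
#' @param t1,t2 `maf_tree` objects (or Newick strings) on identical label
#'   sets.
#' @return an object of class `maf_pair` with elements `t1`, `t2`,
#'   `labels` (sorted common label universe), `n` and, per tree, the map
#'   from label index to tip number.
#' @export
tree_pair <- function(t1, t2) {
  if (is.character(t1)) t1 <- parse_newick(t1)
  if (is.character(t2)) t2 <- parse_newick(t2)
  l1 <- sort(t1$tip_label); l2 <- sort(t2$tip_label)
  if (!identical(l1, l2)) {
    stop("label sets differ: {", paste(setdiff(l1, l2), collapse = ","),
         "} vs {", paste(setdiff(l2, l1), collapse = ","), "}")
  }
  labels <- l1
  structure(
    list(t1 = t1, t2 = t2, labels = labels, n = length(labels),
         tip1 = match(labels, t1$tip_label),
         tip2 = match(labels, t2$tip_label),
         rho_present = "rho" %in% labels),
    class = "maf_pair")
}

#' @export
print.maf_pair <- function(x, ...) {
  cat("MAF instance on", x$n, "labels",
      if (x$rho_present) "(rho-augmented)" else "", "\n")
  cat(" T1:", write_newick(x$t1), "\n T2:", write_newick(x$t2), "\n")
  invisible(x)
}

#' Augment a tree pair with the root label rho
#'
#' The agreement-forest optimum coincides with the rSPR distance only after
#' both trees receive a new root whose children are the former root and a
#' new leaf carrying a reserved label (here the string `"rho"`).  This
#' forces the two root components of any agreement forest to be matched
#' with each other.
#'
#' @param pair a `maf_pair`.
#' @param rho_label the reserved label, default `"rho"`.
#' @return the augmented `maf_pair` (one extra leaf in each tree).
#' @export
augment_rho <- function(pair, rho_label = "rho") {
  stopifnot(inherits(pair, "maf_pair"))
  if (rho_label %in% pair$labels) {
    stop("label '", rho_label, "' already present; pair appears to be augmented")
  }
  add_root_leaf <- function(tree) {
    # re-parse: simplest way to renumber consistently with ape conventions
    parse_newick(paste0("(", sub(";$", "", write_newick(tree)), ",",
                        rho_label, ");"))
  }
  tree_pair(add_root_leaf(pair$t1), add_root_leaf(pair$t2))
}

# ---- label-subset helpers -------------------------------------------------

# convert user input (character labels or indices) to sorted integer indices
as_label_idx <- function(pair, x) {
  if (is.character(x)) {
    i <- match(x, pair$labels)
    if (anyNA(i)) stop("unknown label(s): ", paste(x[is.na(i)], collapse = ", "))
    x <- i
  }
  x <- as.integer(x)
  if (length(x) && (min(x) < 1L || max(x) > pair$n)) stop("label index out of range")
  if (anyDuplicated(x)) stop("duplicate labels in set")
  sort(x)
}

# tips of tree t (1 or 2) for label indices A
tips_of <- function(pair, A, t) {
  if (t == 1L) pair$tip1[A] else pair$tip2[A]
}

tree_of <- function(pair, t) if (t == 1L) pair$t1 else pair$t2

#' Lowest common ancestor of a leaf set
#'
#' @param tree a `maf_tree`.
#' @param tips integer tip numbers (use [tree_pair()] maps to go from
#'   labels to tips) or character leaf names.
#' @return the node id of the lowest node ancestral to all of `tips`.
#' @export
lca_node <- function(tree, tips) {
  if (is.character(tips)) {
    i <- match(tips, tree$tip_label)
    if (anyNA(i)) stop("unknown label(s): ", paste(tips[is.na(i)], collapse = ", "))
    tips <- i
  }
  if (!length(tips)) stop("lca of an empty set is undefined")
  if (length(tips) == 1L) return(as.integer(tips))
  v <- tips[[1L]]
  target <- rep(FALSE, tree$ntip); target[tips] <- TRUE
  while (!all(tree$desc[v, target])) v <- tree$parent[[v]]
  v
}

#' Leaves below a node
#'
#' Returns the leaf set of the subtree rooted at `v` (a node is its own
#' descendant, so for a leaf this is its own label).
#'
#' @param tree a `maf_tree`.
#' @param v a node id.
#' @return character vector of leaf labels, sorted.
#' @export
leaves_below <- function(tree, v) {
  v <- as.integer(v)
  if (length(v) != 1L || is.na(v) || v < 1L || v > tree$N) {
    stop("unknown node: ", v)
  }
  sort(tree$tip_label[which(tree$desc[v, ])])
}

# Node set spanned by a tip set: all nodes lying on a path between two
# members (a singleton spans just its leaf; the empty set spans nothing).
# With c(v) = #tips of A below v this is {v : 1 <= c(v) < |A|} + {lca(A)}.
span_nodes <- function(tree, tips) {
  k <- length(tips)
  if (k == 0L) return(integer(0))
  if (k == 1L) return(as.integer(tips))
  cnt <- as.integer(tree$desc[, tips, drop = FALSE] %*% rep(1L, k))
  below <- which(cnt >= 1L & cnt < k)
  full <- which(cnt == k)
  lca <- full[which.max(tree$depth[full])]
  sort(c(below, lca))
}

#' Nodes spanned by a label subset
#'
#' The set of nodes of one tree of the pair that lie on a path between two
#' leaves of `A` (for a singleton, the leaf itself; empty for empty `A`).
#'
#' @param pair a `maf_pair`.
#' @param A label subset (character labels or indices into `pair$labels`).
#' @param t which tree, 1 or 2.
#' @return sorted integer node ids of tree `t`.
#' @export
spanned_nodes <- function(pair, A, t = 1L) {
  A <- as_label_idx(pair, A)
  span_nodes(tree_of(pair, t), tips_of(pair, A, t))
}

# lca (node id in tree t) of a label-index set
lca_of <- function(pair, A, t) {
  lca_node(tree_of(pair, t), tips_of(pair, A, t))
}

# label indices below node v of tree t
labels_below <- function(pair, v, t) {
  tr <- tree_of(pair, t)
  tipsel <- if (t == 1L) pair$tip1 else pair$tip2
  which(tr$desc[v, tipsel])
}
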