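# --- state encoding and site-pattern compression -----------------------------
#
# Nucleotides are bitmasks (A=1, C=2, G=4, T=8); gap, N and ? are fully
# ambiguous (15), i.e. missing data never costs a step. Identical columns are
# collapsed to patterns with multiplicity weights; Fitch passes are vectorised
# over patterns.

BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L, "-" = 15L, "?" = 15L)

encode_alignment <- function(aln) {
  m <- aln_matrix(aln)                       # taxa x sites
  codes <- matrix(BASE_BITS[m], nrow = nrow(m))
  codes[is.na(codes)] <- 15L
  rownames(codes) <- rownames(m)
  codes
}

# collapse identical columns; returns list(pat = taxa x P matrix,
# weights, pattern_of = per-column pattern index)
compress_patterns <- function(codes, weights = NULL) {
  if (is.null(weights)) weights <- rep(1L, ncol(codes))
  key <- apply(codes, 2L, paste, collapse = ".")
  idx <- match(key, unique(key))
  pat <- codes[, !duplicated(key), drop = FALSE]
  w <- as.numeric(tapply(weights, idx, sum))
  list(pat = pat, weights = w, pattern_of = idx)
}

# per-pattern minimum possible steps (#distinct unambiguous states - 1, or 0
# if ambiguity can bridge) and a flag for parsimony-informative patterns
pattern_min_steps <- function(pat) {
  apply(pat, 2L, function(col) {
    res <- col[col != 15L]
    if (!length(res)) return(0L)
    length(unique(res)) - 1L
  })
}

pattern_has_missing <- function(pat) apply(pat, 2L, function(col) any(col == 15L))

pattern_is_informative <- function(pat) {
  apply(pat, 2L, function(col) {
    res <- col[col != 15L]
    if (!length(res)) return(FALSE)
    sum(table(res) >= 2L) >= 2L
  })
}

# --- Fitch scoring on an edge-matrix tree -------------------------------------
#
# Trees during search are plain integer edge matrices; tips are 1..ntip,
# internal nodes ntip+1, ... . Scoring roots the tree at an arbitrary
# internal node and folds children into parents in postorder; at a
# multifurcation children are folded sequentially (equivalent to rooting the
# unrooted binary tree along one of its edges).

# postorder node list via iterative DFS; returns list(order, parent)
postorder_nodes <- function(edges, root) {
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (r in seq_len(nrow(edges))) {
    u <- edges[r, 1]; v <- edges[r, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  parent <- integer(nodes)
  order <- integer(0)
  stack <- root; parent[root] <- 0L
  seen <- logical(nodes); seen[root] <- TRUE
  # first pass: preorder via stack
  pre <- integer(0)
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    pre <- c(pre, u)
    for (v in adj[[u]]) if (!seen[v]) { seen[v] <- TRUE; parent[v] <- u; stack <- c(stack, v) }
  }
  list(order = rev(pre), parent = parent, adj = adj)
}

# per-pattern Fitch step counts for a tree over a subset of tips.
# tipstate: list indexed by tip id -> integer vector (length P) of bitmasks.
fitch_steps_per_pattern <- function(edges, tipstate, P) {
  root <- max(edges)
  po <- postorder_nodes(edges, root)
  nodes <- max(edges)
  state <- vector("list", nodes)
  steps <- numeric(P)
  for (u in po$order) {
    if (u <= length(tipstate) && !is.null(tipstate[[u]])) {
      state[[u]] <- tipstate[[u]]
    } else {
      kids <- po$adj[[u]][po$adj[[u]] != po$parent[u]]
      acc <- NULL
      for (v in kids) {
        if (is.null(acc)) { acc <- state[[v]]; next }
        inter <- bitwAnd(acc, state[[v]])
        zero <- inter == 0L
        if (any(zero)) {
          steps[zero] <- steps[zero] + 1
          inter[zero] <- bitwOr(acc[zero], state[[v]][zero])
        }
        acc <- inter
      }
      state[[u]] <- acc
    }
  }
  steps
}

fitch_score_edges <- function(edges, tipstate, weights) {
  sum(weights * fitch_steps_per_pattern(edges, tipstate, length(weights)))
}

#' Fitch parsimony length of a tree
#'
#' Number of state changes required by the alignment on the tree under
#' unordered, unweighted (Fitch) parsimony. Gaps and N are treated as
#' missing data (fully ambiguous), so they never contribute steps.
#'
#' @param tree A `phylo` tree whose tip labels match the alignment ids.
#' @param alignment A [dna_alignment].
#' @return Tree length in steps.
#' @export
fitch_length <- function(tree, alignment) {
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, alignment$ids))
    abort("tree tip labels do not match alignment ids")
  codes <- encode_alignment(alignment)
  cp <- compress_patterns(codes)
  tipstate <- tipstate_for(tree$tip.label, cp$pat, alignment$ids)
  fitch_score_edges(tree$edge, tipstate, cp$weights)
}

# build the per-tip pattern-state list for tips numbered 1..n in `labels`
# order, pulling rows of `pat` by matching `ids`
tipstate_for <- function(labels, pat, ids) {
  rows <- match(labels, ids)
  ts <- vector("list", length(labels))
  for (i in seq_along(labels)) ts[[i]] <- pat[rows[i], ]
  ts
}

# --- tree representation helpers ---------------------------------------------

# star tree on tips 1..3 with internal node `ntip + 1`
start_tree <- function(ntip) {
  c0 <- ntip + 1L
  cbind(c(c0, c0, c0), c(1L, 2L, 3L))
}

# insert tip `leaf` into edge row `r`, creating internal node `newint`
insert_leaf <- function(edges, r, leaf, newint) {
  u <- edges[r, 1]; v <- edges[r, 2]
  edges[r, ] <- c(u, newint)
  rbind(edges, c(newint, v), c(newint, leaf))
}

# canonical Newick of an unrooted edge-matrix tree (sorted subtrees), used to
# deduplicate topologies
canon_newick <- function(edges, labels) {
  root <- 1L   # hang from tip 1
  po <- postorder_nodes(edges, root)
  build <- function(u, parent) {
    kids <- po$adj[[u]][po$adj[[u]] != parent]
    if (!length(kids)) return(labels[u])
    sub <- sort(vapply(kids, function(v) build(v, u), ""))
    paste0("(", paste(sub, collapse = ","), ")")
  }
  paste0("(", labels[root], ",", build(po$adj[[root]][1], root), ");")
}

# edge matrix -> phylo (via Newick round-trip through ape)
edges_to_phylo <- function(edges, labels) {
  ape::read.tree(text = newick_of(edges, labels))
}

newick_of <- function(edges, labels) {
  root <- 1L
  po <- postorder_nodes(edges, root)
  build <- function(u, parent) {
    kids <- po$adj[[u]][po$adj[[u]] != parent]
    if (!length(kids)) return(labels[u])
    paste0("(", paste(vapply(kids, function(v) build(v, u), ""), collapse = ","), ")")
  }
  inner <- po$adj[[root]][1]
  kids_of_inner <- po$adj[[inner]][po$adj[[inner]] != root]
  paste0("(", labels[root], ",",
         paste(vapply(kids_of_inner, function(v) build(v, inner), ""), collapse = ","),
         ");")
}

# splits (as sorted character vectors of tip labels, side not containing the
# alphabetically first label) of the nontrivial bipartitions of a phylo tree
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  labels <- tree$tip.label
  anchor <- sort(labels)[1]
  ntip <- length(labels)
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) desc[[i]] <- labels[i]
  edges <- tree$edge
  for (e in ape::postorder(tree)) {
    u <- edges[e, 1]; v <- edges[e, 2]
    desc[[u]] <- c(desc[[u]], desc[[v]])
  }
  out <- character(0)
  for (e in seq_len(nrow(edges))) {
    v <- edges[e, 2]
    if (v <= ntip) next
    side <- sort(desc[[v]])
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (anchor %in% side) side <- sort(setdiff(labels, side))
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the nontrivial bipartitions of two unrooted trees
#' on the same leaf set.
#'
#' @param a,b `phylo` trees with identical tip label sets.
#' @return Integer count of splits present in exactly one tree.
#' @export
rf_distance <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    abort("trees have different leaf sets")
  sa <- tree_splits(a); sb <- tree_splits(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}
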