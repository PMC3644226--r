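#' Maximum-parsimony tree search
#'
#' Finds all equally most-parsimonious unrooted binary trees for an
#' alignment under Fitch parsimony.
#'
#' Strategies:
#' \describe{
#'   \item{`exhaustive`}{scores every unrooted binary topology (at most 9
#'     taxa).}
#'   \item{`branch_and_bound`}{exact: depth-first stepwise addition, pruning
#'     any partial tree whose length already exceeds the incumbent (at most
#'     15 taxa). The incumbent is initialised by a greedy stepwise-addition
#'     tree.}
#'   \item{`heuristic`}{`n_starts` random-addition starts (seeded), each
#'     followed by nearest-neighbour-interchange to convergence and one
#'     sweep of subtree regrafting; repeats the NNI pass if regrafting
#'     improved the tree. Not guaranteed optimal; length is always an upper
#'     bound on the exact length.}
#' }
#'
#' @param alignment A [dna_alignment] with at least 4 rows.
#' @param strategy One of `"branch_and_bound"`, `"exhaustive"`, `"heuristic"`.
#' @param n_starts Random-addition starts for the heuristic (default 10).
#' @param seed Integer seed for the heuristic's random addition orders.
#' @return An object of class `mp_fit`: list with `best_trees` (list of
#'   `phylo`), `length` (steps), `strategy`, `n_taxa`, and `seed`.
#' @export
mp_search <- function(alignment,
                      strategy = c("branch_and_bound", "exhaustive", "heuristic"),
                      n_starts = 10L, seed = 1L) {
  strategy <- match.arg(strategy)
  labels <- alignment$ids
  n <- length(labels)
  if (n < 4L) abort("need at least 4 taxa for tree search")
  if (strategy == "exhaustive" && n > 9L)
    abort("exhaustive search allowed only for <= 9 taxa")
  if (strategy == "branch_and_bound" && n > 15L)
    abort("branch-and-bound search allowed only for <= 15 taxa")
  codes <- encode_alignment(alignment)
  cp <- compress_patterns(codes)
  fit <- mp_search_impl(cp$pat, cp$weights, labels, strategy, n_starts, seed)
  structure(list(best_trees = lapply(fit$newicks, function(s) ape::read.tree(text = s)),
                 length = fit$L, strategy = strategy, n_taxa = n,
                 seed = seed, n_trees = length(fit$newicks)),
            class = "mp_fit")
}

#' @export
print.mp_fit <- function(x, ...) {
  cat(sprintf("<mp_fit> %s search: %d most-parsimonious tree(s), length %g steps, %d taxa\n",
              x$strategy, x$n_trees, x$length, x$n_taxa))
  invisible(x)
}

# search over compressed patterns; `pat` rows are taxa in `labels` order.
# Splits patterns into parsimony-informative ones (searched) and a constant
# per-tree contribution from the rest (valid when the rest carry no missing
# data mixed with >1 state; patterns where that cannot be asserted stay in
# the searched set).
mp_search_impl <- function(pat, weights, labels, strategy, n_starts, seed) {
  ntip <- length(labels)
  info <- pattern_is_informative(pat)
  minsteps <- pattern_min_steps(pat)
  miss <- pattern_has_missing(pat)
  # uninformative complete-data patterns cost (states-1) on every topology;
  # all-missing / single-state patterns cost 0
  const_ok <- !info & (!miss | minsteps == 0L)
  base <- sum(weights[const_ok] * minsteps[const_ok])
  keep <- !const_ok
  spat <- pat[, keep, drop = FALSE]
  sw <- weights[keep]
  tipstate <- lapply(seq_len(ntip), function(i) spat[i, ])
  score <- function(edges) {
    if (!ncol(spat)) return(base)
    base + fitch_score_edges(edges, tipstate, sw)
  }
  if (strategy == "exhaustive") {
    best <- enumerate_and_score(ntip, score, prune = Inf, labels = labels)
  } else if (strategy == "branch_and_bound") {
    greedy <- greedy_addition(seq_len(ntip), score, ntip)
    best <- enumerate_and_score(ntip, score, prune = score(greedy), labels = labels)
  } else {
    best <- heuristic_search(ntip, score, labels, n_starts, seed)
  }
  best
}

# DFS stepwise addition over all topologies; prunes partial trees whose score
# exceeds the current best (prune = Inf gives exhaustive enumeration).
enumerate_and_score <- function(ntip, score, prune, labels) {
  bestL <- prune
  bestset <- character(0)
  recurse <- function(edges, next_tip) {
    L <- score(edges)
    if (L > bestL) return(invisible())
    if (next_tip > ntip) {
      if (L < bestL) { bestL <<- L; bestset <<- canon_newick(edges, labels) }
      else bestset <<- union(bestset, canon_newick(edges, labels))
      return(invisible())
    }
    newint <- ntip + next_tip - 2L
    for (r in seq_len(nrow(edges))) {
      recurse(insert_leaf(edges, r, next_tip, newint), next_tip + 1L)
    }
  }
  recurse(start_tree(ntip), 4L)
  # a greedy incumbent used for pruning may not itself have been re-found if
  # it was the unique optimum reached only at prune == L; ensure non-empty
  if (!length(bestset)) {
    # re-run accepting equality at the incumbent
    bestL2 <- bestL
    recurse2 <- function(edges, next_tip) {
      L <- score(edges)
      if (L > bestL2) return(invisible())
      if (next_tip > ntip) {
        bestset <<- union(bestset, canon_newick(edges, labels))
        return(invisible())
      }
      newint <- ntip + next_tip - 2L
      for (r in seq_len(nrow(edges)))
        recurse2(insert_leaf(edges, r, next_tip, newint), next_tip + 1L)
    }
    recurse2(start_tree(ntip), 4L)
  }
  list(L = bestL, newicks = bestset)
}

# greedy stepwise addition in the given taxon order; returns an edge matrix
greedy_addition <- function(order, score, ntip) {
  edges <- cbind(rep(ntip + 1L, 3L), order[1:3])
  for (i in 4:ntip) {
    newint <- ntip + i - 2L
    bestE <- NULL; bestL <- Inf
    for (r in seq_len(nrow(edges))) {
      cand <- insert_leaf(edges, r, order[i], newint)
      L <- score(cand)
      if (L < bestL) { bestL <- L; bestE <- cand }
    }
    edges <- bestE
  }
  edges
}

adj_list <- function(edges) {
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (r in seq_len(nrow(edges))) {
    u <- edges[r, 1]; v <- edges[r, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

# the (at most) 2 NNI rearrangements of each internal edge
nni_neighbors <- function(edges, ntip) {
  adj <- adj_list(edges)
  out <- list()
  for (r in seq_len(nrow(edges))) {
    u <- edges[r, 1]; v <- edges[r, 2]
    if (u <= ntip || v <= ntip) next
    bu <- setdiff(adj[[u]], v)
    bv <- setdiff(adj[[v]], u)
    b <- bu[2]
    for (cc in bv) {
      e2 <- edges
      # swap subtree b (on u) with subtree cc (on v)
      iu <- which((e2[, 1] == u & e2[, 2] == b) | (e2[, 1] == b & e2[, 2] == u))
      iv <- which((e2[, 1] == v & e2[, 2] == cc) | (e2[, 1] == cc & e2[, 2] == v))
      e2[iu, ] <- c(u, cc)
      e2[iv, ] <- c(v, b)
      out[[length(out) + 1L]] <- e2
    }
  }
  out
}

# one sweep of subtree prune + regraft moves
spr_moves <- function(edges, ntip) {
  adj <- adj_list(edges)
  out <- list()
  for (r in seq_len(nrow(edges))) {
    for (dir in 1:2) {
      u <- edges[r, dir]; v <- edges[r, 3L - dir]   # prune component of v
      if (u <= ntip) next                           # u must be suppressible
      # component containing v after cutting (u,v)
      comp <- v; frontier <- v
      while (length(frontier)) {
        nxt <- setdiff(unlist(adj[frontier]), c(comp, u))
        comp <- c(comp, nxt); frontier <- nxt
      }
      if (length(comp) >= 2L * ntip - 2L - 2L) next
      p <- setdiff(adj[[u]], v)                     # u's two other neighbours
      keep <- !((edges[, 1] == u | edges[, 2] == u))
      base_edges <- rbind(edges[keep, , drop = FALSE], p)   # suppress u
      # drop edges inside the pruned component from regraft targets
      in_comp <- (base_edges[, 1] %in% comp) | (base_edges[, 2] %in% comp)
      targets <- which(!in_comp)
      new_edge_row <- nrow(base_edges)              # the (p1,p2) edge
      for (tr in targets) {
        if (tr == new_edge_row) next                # recreates the original
        x <- base_edges[tr, 1]; y <- base_edges[tr, 2]
        e2 <- base_edges
        e2[tr, ] <- c(x, u)
        e2 <- rbind(e2, c(u, y), c(u, v))
        out[[length(out) + 1L]] <- e2
      }
    }
  }
  out
}

heuristic_search <- function(ntip, score, labels, n_starts, seed) {
  set.seed(seed)
  bestL <- Inf
  bestset <- character(0)
  for (s in seq_len(n_starts)) {
    ord <- sample(ntip)
    edges <- greedy_addition(ord, score, ntip)
    L <- score(edges)
    repeat {
      improved <- FALSE
      # NNI to convergence
      repeat {
        cands <- nni_neighbors(edges, ntip)
        if (!length(cands)) break
        Ls <- vapply(cands, score, 0)
        if (min(Ls) < L) {
          pick <- which.min(Ls)
          edges <- cands[[pick]]; L <- Ls[pick]; improved <- TRUE
        } else break
      }
      # one regrafting sweep
      cands <- spr_moves(edges, ntip)
      if (length(cands)) {
        Ls <- vapply(cands, score, 0)
        if (min(Ls) < L) {
          pick <- which.min(Ls)
          edges <- cands[[pick]]; L <- Ls[pick]
          next   # regrafting improved: rerun NNI
        }
      }
      if (!improved) break
    }
    nwk <- canon_newick(edges, labels)
    if (L < bestL) { bestL <- L; bestset <- nwk }
    else if (L == bestL) bestset <- union(bestset, nwk)
  }
  list(L = bestL, newicks = bestset)
}

#' Nonparametric bootstrap with majority-rule consensus
#'
#' Resamples alignment columns with replacement to the original length,
#' reruns the MP search per replicate, and reports each bipartition's
#' support as the percentage of replicates whose strict consensus of best
#' trees contains it. Returns the >=50% majority-rule consensus with
#' supports as node labels.
#'
#' @param alignment A [dna_alignment].
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param strategy Search strategy per replicate (see [mp_search()]).
#' @param seed Integer seed; results are bit-reproducible given
#'   `(seed, replicates, strategy)`.
#' @param n_starts Random-addition starts when `strategy = "heuristic"`.
#' @return A list of class `bootstrap_result`: `consensus` (`phylo` with
#'   node labels = support percentages), `split_support` (tibble of splits
#'   and percentages), `replicates`, `seed`.
#' @export
bootstrap_support <- function(alignment, replicates = 100L,
                              strategy = "branch_and_bound", seed = 1L,
                              n_starts = 2L) {
  if (replicates < 1L) abort("at least 1 bootstrap replicate required")
  labels <- alignment$ids
  codes <- encode_alignment(alignment)
  L <- ncol(codes)
  cp <- compress_patterns(codes)
  set.seed(seed)
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    w <- tapply(rep(1L, L), factor(cp$pattern_of[cols], levels = seq_along(cp$weights)), sum)
    w <- as.numeric(ifelse(is.na(w), 0, w))
    fit <- mp_search_impl(cp$pat, w, labels, strategy, n_starts,
                          seed = seed + b)
    trees <- lapply(fit$newicks, function(s) ape::read.tree(text = s))
    splits <- Reduce(intersect, lapply(trees, tree_splits))   # strict consensus
    for (sp in splits) {
      counts[[sp]] <- (counts[[sp]] %||% 0L) + 1L
    }
  }
  splits <- ls(counts)
  support <- vapply(splits, function(s) 100 * counts[[s]] / replicates, 0)
  tab <- tibble::tibble(split = splits, support = unname(support))
  tab <- tab[order(-tab$support, tab$split), ]
  maj <- tab[tab$support > 50, , drop = FALSE]
  cons <- consensus_from_splits(maj$split, labels, maj$support)
  structure(list(consensus = cons, split_support = tab,
                 replicates = replicates, seed = seed, strategy = strategy),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d replicates; %d majority-rule split(s)\n",
              x$replicates, sum(x$split_support$support > 50)))
  invisible(x)
}

# build a (possibly multifurcating) unrooted tree from a laminar family of
# splits given as "a|b|c" strings (side not containing the first label);
# supports become internal node labels
consensus_from_splits <- function(splits, labels, supports = NULL) {
  sets <- lapply(splits, function(s) strsplit(s, "|", fixed = TRUE)[[1]])
  if (!is.null(supports)) names(supports) <- splits
  build <- function(members, available) {
    # available: indices of splits whose set is a subset of members
    sizes <- lengths(sets[available])
    kids <- character(0)
    used <- character(0)
    # maximal sets first
    for (i in available[order(-sizes)]) {
      s <- sets[[i]]
      if (all(s %in% members) && !any(s %in% used)) {
        sub <- build(s, setdiff(available, i))
        lab <- if (!is.null(supports)) format(round(supports[[splits[i]]])) else ""
        kids <- c(kids, paste0(sub, lab))
        used <- c(used, s)
      }
    }
    singles <- setdiff(members, used)
    paste0("(", paste(c(kids, singles), collapse = ","), ")")
  }
  anchor_side <- build(setdiff(labels, character(0)), seq_along(sets))
  # top level: all labels
  ape::read.tree(text = paste0(anchor_side, ";"))
}

# strict consensus of a list of phylo trees (shared splits only)
strict_consensus <- function(trees) {
  if (length(trees) == 1L) return(trees[[1]])
  splits <- Reduce(intersect, lapply(trees, tree_splits))
  consensus_from_splits(splits, trees[[1]]$tip.label)
}

#' Parsimony tree statistics (L, CI, RI, RC)
#'
#' Computes the tree length and the consistency (CI), retention (RI) and
#' rescaled consistency (RC) indices over variable columns. Per column,
#' `m` is the minimum possible steps (distinct states - 1) and `g` the
#' maximum on a star tree (occurrences minus the largest state frequency);
#' columns with `m = 0` are excluded. `CI = sum(m)/L`, `RI = (G-L)/(G-M)`,
#' `RC = CI * RI`; a zero-length tree takes CI = RI = 1 by convention.
#'
#' @param tree A `phylo` scored on `alignment`.
#' @param alignment A [dna_alignment].
#' @return A one-row tibble with `L`, `CI`, `RI`, `RC`.
#' @export
tree_statistics <- function(tree, alignment) {
  codes <- encode_alignment(alignment)
  cp <- compress_patterns(codes)
  minsteps <- pattern_min_steps(cp$pat)
  maxsteps <- apply(cp$pat, 2L, function(col) {
    res <- col[col != 15L]
    if (!length(res)) return(0L)
    length(res) - max(table(res))
  })
  keep <- minsteps > 0L
  tipstate <- tipstate_for(tree$tip.label, cp$pat, alignment$ids)
  per_pat <- fitch_steps_per_pattern(reindex_tree(tree), tipstate, length(cp$weights))
  L <- sum(cp$weights[keep] * per_pat[keep])
  M <- sum(cp$weights[keep] * minsteps[keep])
  G <- sum(cp$weights[keep] * maxsteps[keep])
  if (L == 0) {
    ci <- 1; ri <- 1
  } else {
    ci <- M / L
    ri <- if (G > M) (G - L) / (G - M) else 1
  }
  tibble::tibble(L = L, CI = ci, RI = ri, RC = ci * ri)
}

# phylo edge matrix already uses tips 1..ntip and internals above; reuse as-is
reindex_tree <- function(tree) tree$edge
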