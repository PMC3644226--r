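# Independent oracles and small simulation helpers used across the suite.

# --- uniform-cost Sankoff dynamic programme (oracle for Fitch length) --------
# Scores one alignment on one tree by per-column DP over explicit state costs;
# shares no code with the Fitch implementation.
sankoff_length <- function(tree, alignment) {
  m <- do.call(rbind, strsplit(unname(alignment$seqs), "", fixed = TRUE))
  rownames(m) <- alignment$ids
  bases <- c("A", "C", "G", "T")
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  kids <- split(edges[, 2], edges[, 1])
  root <- setdiff(unique(edges[, 1]), edges[, 2])[1]
  total <- 0
  for (col in seq_len(ncol(m))) {
    cost_of <- function(node) {
      if (node <= ntip) {
        ch <- m[tree$tip.label[node], col]
        if (ch %in% bases) {
          v <- rep(Inf, 4); v[match(ch, bases)] <- 0
          return(v)
        }
        return(rep(0, 4))
      }
      acc <- rep(0, 4)
      for (child in kids[[as.character(node)]]) {
        cc <- cost_of(child)
        acc <- acc + vapply(1:4, function(s) min(cc + (1:4 != s)), 0)
      }
      acc
    }
    total <- total + min(cost_of(root))
  }
  total
}

# --- independent brute-force repeat finder -----------------------------------
# Re-derives the hit definition (exact 15-mer seed runs chained over match
# runs of >= confirm_run with running identity >= min_identity) by direct
# per-diagonal scanning with plain loops; shares no code with
# find_repeat_pairs().
brute_force_repeats <- function(seq, min_len = 30L, min_identity = 0.90,
                                k = 15L, confirm_run = 8L) {
  n <- nchar(seq)
  sv <- strsplit(seq, "")[[1]]
  rv <- strsplit(chartr("ACGT", "TGCA", paste(rev(sv), collapse = "")), "")[[1]]
  hits <- list()
  chain_hits <- function(m, emit) {
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    tr <- which(r$values)
    seeds <- tr[r$lengths[tr] >= k]
    done <- rep(FALSE, length(r$lengths))
    for (s in seeds) {
      if (done[s]) next
      lo <- s; hi <- s
      matches <- r$lengths[s]
      a <- starts[s]; b <- ends[s]
      repeat {
        moved <- FALSE
        nxt <- tr[tr > hi]
        if (length(nxt)) {
          nxt <- nxt[1]
          if (r$lengths[nxt] >= confirm_run &&
              (matches + r$lengths[nxt]) / (ends[nxt] - a + 1L) >= min_identity) {
            matches <- matches + r$lengths[nxt]; b <- ends[nxt]; hi <- nxt
            moved <- TRUE
          }
        }
        prv <- tr[tr < lo]
        if (length(prv)) {
          prv <- prv[length(prv)]
          if (r$lengths[prv] >= confirm_run &&
              (matches + r$lengths[prv]) / (b - starts[prv] + 1L) >= min_identity) {
            matches <- matches + r$lengths[prv]; a <- starts[prv]; lo <- prv
            moved <- TRUE
          }
        }
        if (!moved) break
      }
      for (ss in seeds) if (ss >= lo && ss <= hi) done[ss] <- TRUE
      len <- b - a + 1L
      ident <- matches / len
      if (len >= min_len && ident >= min_identity) emit(a, b, ident)
    }
  }
  # direct: diagonals d = offset between the two copies
  for (d in seq_len(n - min_len)) {
    hi <- n - d
    if (hi < k) next
    m <- sv[1:hi] == sv[(1:hi) + d]
    chain_hits(m, function(a, b, ident) {
      hits[[length(hits) + 1L]] <<- data.frame(
        copy1_start = a - 1L, copy1_end = b,
        copy2_start = a + d - 1L, copy2_end = b + d,
        length = b - a + 1L, identity = ident, orientation = "direct")
    })
  }
  # inverted: genome vs reverse complement
  for (d in (1L - n):(n - 1L)) {
    p_lo <- max(1L, 1L - d); p_hi <- min(n, n - d)
    if (p_hi - p_lo + 1L < k) next
    m <- sv[p_lo:p_hi] == rv[(p_lo:p_hi) + d]
    chain_hits(m, function(a, b, ident) {
      a1 <- a + p_lo - 1L; b1 <- b + p_lo - 1L
      c2s <- n + 1L - (b1 + d); c2e <- n + 1L - (a1 + d)
      if (c2s <= b1) return(invisible())
      hits[[length(hits) + 1L]] <<- data.frame(
        copy1_start = a1 - 1L, copy1_end = b1,
        copy2_start = c2s - 1L, copy2_end = c2e,
        length = b1 - a1 + 1L, identity = ident, orientation = "inverted")
    })
  }
  if (!length(hits)) {
    return(data.frame(copy1_start = integer(), copy1_end = integer(),
                      copy2_start = integer(), copy2_end = integer(),
                      length = integer(), identity = numeric(),
                      orientation = character()))
  }
  out <- unique(do.call(rbind, hits))
  # drop contained duplicates, mirroring the documented rule
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) for (j in seq_len(nrow(out))) {
    if (i != j && keep[i] &&
        out$orientation[i] == out$orientation[j] &&
        out$copy1_start[i] >= out$copy1_start[j] &&
        out$copy1_end[i] <= out$copy1_end[j] &&
        out$copy2_start[i] >= out$copy2_start[j] &&
        out$copy2_end[i] <= out$copy2_end[j] &&
        out$length[i] < out$length[j]) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$copy1_start, out$copy2_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- tiny alignment simulator (no indels) ------------------------------------
sim_alignment_on_tree <- function(tree, n_sites, multiplier = 1, seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- random_dna(n_sites)
  for (e in rev(ape::postorder(tree))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    seqs[[v]] <- evolve_sequence(seqs[[u]], tree$edge.length[e], multiplier)$child
  }
  dna_alignment(setNames(unlist(seqs[seq_len(ntip)]), tree$tip.label))
}

# random alignment over ACGT (optionally with gaps/N)
random_alignment <- function(ntaxa, nsites, gap_frac = 0) {
  m <- matrix(sample(c("A", "C", "G", "T"), ntaxa * nsites, replace = TRUE),
              nrow = ntaxa)
  if (gap_frac > 0) {
    idx <- sample(length(m), round(gap_frac * length(m)))
    m[idx] <- sample(c("-", "N"), length(idx), replace = TRUE)
  }
  rows <- apply(m, 1, paste, collapse = "")
  names(rows) <- paste0("t", seq_len(ntaxa))
  dna_alignment(rows)
}

# plant an exact or degraded copy of `motif` at 0-based position `at`
overwrite_at <- function(seq, at, motif) {
  substr(seq, at + 1L, at + nchar(motif)) <- motif
  seq
}
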