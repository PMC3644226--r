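#' Find repeat pairs in a genome
#'
#' Enumerates maximal local ungapped matches of the genome against itself
#' (direct repeats) and against its reverse complement (inverted repeats)
#' via exact k-mer seeding (k = 15) and greedy extension that keeps the
#' running identity at or above `min_identity`. The trivial self-match is
#' excluded, as is the whole IR-vs-IR duplication and, more generally, any
#' hit with a copy lying entirely inside IRa (by the genome's structural
#' duplication every such hit has an IRb image that is reported instead).
#' Symmetric duplicates are collapsed (copy 1 starts before copy 2);
#' inverted hits with overlapping copies (self-palindromes) are dropped.
#'
#' @param genome A [plastome].
#' @param min_len Minimum copy length (default 30, must be >= 8).
#' @param min_identity Minimum identity over the extended span (default 0.90).
#' @param partition Optional `quadripartite` used for the IR exclusion;
#'   when `NULL` it is computed with [detect_quadripartite()] defaults.
#' @param k Seed length (default 15).
#' @return A tibble sorted by (`copy1_start`, `copy2_start`) with 0-based
#'   half-open columns `copy1_start`, `copy1_end`, `copy2_start`,
#'   `copy2_end`, plus `length`, `identity`, `orientation`.
#' @export
find_repeat_pairs <- function(genome, min_len = 30L, min_identity = 0.90,
                              partition = NULL, k = 15L) {
  stopifnot(inherits(genome, "plastome"))
  if (min_len < 8L) abort("min_len must be >= 8")
  S <- genome$sequence
  n <- genome$length
  if (is.null(partition)) partition <- detect_quadripartite(genome)
  Sv <- chars(S)
  hits <- rbind(
    scan_direct(S, Sv, n, k, min_len, min_identity),
    scan_inverted(S, Sv, n, k, min_len, min_identity)
  )
  if (nrow(hits)) {
    hits <- dplyr::distinct(hits)
    hits <- drop_contained(hits)
    if (!partition$no_ir) {
      ira <- partition$ira[1, ]
      in_ira <- function(s, e) s >= ira["start"] & e <= ira["end"]
      hits <- hits[!(in_ira(hits$copy1_start, hits$copy1_end) |
                       in_ira(hits$copy2_start, hits$copy2_end)), , drop = FALSE]
    }
    hits <- hits[order(hits$copy1_start, hits$copy2_start), , drop = FALSE]
  }
  tibble::as_tibble(hits)
}

empty_hits <- function() {
  data.frame(copy1_start = integer(), copy1_end = integer(),
             copy2_start = integer(), copy2_end = integer(),
             length = integer(), identity = numeric(),
             orientation = character())
}

# direct repeats: self-comparison, diagonals d = i2 - i1 > 0
scan_direct <- function(S, Sv, n, k, min_len, min_identity) {
  starts <- seq_len(n - k + 1L)
  ks <- substring(S, starts, starts + k - 1L)
  tab <- split(starts, ks)
  tab <- tab[lengths(tab) > 1L]
  if (!length(tab)) return(empty_hits())
  pairs <- do.call(rbind, lapply(tab, function(p) {
    idx <- t(utils::combn(sort(p), 2L))
    idx
  }))
  out <- list()
  for (d in unique(pairs[, 2] - pairs[, 1])) {
    ii <- sort(pairs[pairs[, 2] - pairs[, 1] == d, 1])
    hi <- n - d                       # last valid p with partner p + d
    m <- Sv[seq_len(hi)] == Sv[seq_len(hi) + d]
    out[[length(out) + 1L]] <-
      diagonal_hits(m, ii, k, min_len, min_identity,
                    to_hit = function(a, b) {
                      data.frame(copy1_start = a - 1L, copy1_end = b,
                                 copy2_start = a + d - 1L, copy2_end = b + d,
                                 length = b - a + 1L, identity = NA_real_,
                                 orientation = "direct")
                    })
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty_hits() else res
}

# inverted repeats: genome vs reverse complement; R position j maps back to
# genome interval [n+1-(j+L-1), n+1-j] (1-based)
scan_inverted <- function(S, Sv, n, k, min_len, min_identity) {
  R <- revcomp(S)
  hits <- seed_hits(S, R, k)
  if (!nrow(hits)) return(empty_hits())
  Rv <- chars(R)
  out <- list()
  for (d in unique(hits$j - hits$i)) {
    ii <- sort(unique(hits$i[hits$j - hits$i == d]))
    p_lo <- max(1L, 1L - d); p_hi <- min(n, n - d)
    m <- Sv[p_lo:p_hi] == Rv[(p_lo:p_hi) + d]
    out[[length(out) + 1L]] <-
      diagonal_hits(m, ii - p_lo + 1L, k, min_len, min_identity,
                    to_hit = function(a, b) {
                      a1 <- a + p_lo - 1L; b1 <- b + p_lo - 1L
                      c2s <- n + 1L - (b1 + d); c2e <- n + 1L - (a1 + d)
                      if (c2s <= b1) return(NULL)     # overlapping copies
                      data.frame(copy1_start = a1 - 1L, copy1_end = b1,
                                 copy2_start = c2s - 1L, copy2_end = c2e,
                                 length = b1 - a1 + 1L, identity = NA_real_,
                                 orientation = "inverted")
                    })
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty_hits() else res
}

# shared per-diagonal machinery: merge seeds into runs, extend greedily,
# filter by length/identity, emit via to_hit (which works in local 1-based
# match-vector coordinates)
diagonal_hits <- function(m, seed_starts, k, min_len, min_identity, to_hit) {
  if (!length(seed_starts)) return(NULL)
  seed_starts <- seed_starts[seed_starts >= 1L & seed_starts + k - 1L <= length(m)]
  seed_starts <- seed_starts[vapply(seed_starts, function(s) all(m[s:(s + k - 1L)]), TRUE)]
  if (!length(seed_starts)) return(NULL)
  runs <- seed_runs(seed_starts, k)
  res <- list()
  for (r in seq_len(nrow(runs))) {
    span <- extend_run(m, runs[r, 1], runs[r, 2], min_identity)
    len <- span[2] - span[1] + 1L
    if (len < min_len) next
    ident <- mean(m[span[1]:span[2]])
    if (ident < min_identity) next
    h <- to_hit(span[1], span[2])
    if (is.null(h)) next
    h$identity <- ident
    res[[length(res) + 1L]] <- h
  }
  if (!length(res)) return(NULL)
  unique(do.call(rbind, res))
}

# drop hits strictly contained (both copies) in another hit of the same
# orientation
drop_contained <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    for (j in seq_len(nrow(hits))) {
      if (i == j || !keep[i]) next
      if (hits$orientation[i] == hits$orientation[j] &&
          hits$copy1_start[i] >= hits$copy1_start[j] &&
          hits$copy1_end[i] <= hits$copy1_end[j] &&
          hits$copy2_start[i] >= hits$copy2_start[j] &&
          hits$copy2_end[i] <= hits$copy2_end[j] &&
          hits$length[i] < hits$length[j]) {
        keep[i] <- FALSE
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Classify repeat hits into the four categories
#'
#' Merges hits whose copy footprints overlap into one motif (so a genome
#' region belongs to at most one reported repeat) and assigns exactly one
#' category per motif with precedence
#' tandem > palindromic > gene-similarity > dispersed:
#' tandem = direct orientation with copies closer than `tandem_gap`;
#' palindromic = inverted orientation with a gap of at most
#' `palindrome_gap` (3 kb) between the copies; gene-similarity = the two
#' copies overlap two distinct annotated genes; dispersed otherwise.
#'
#' @param hits A hit table from [find_repeat_pairs()] on the same genome.
#' @param genome The annotated [plastome].
#' @param tandem_gap Maximum gap in bases for adjacency (default 10).
#' @param palindrome_gap Maximum gap for the palindromic class (default 3000).
#' @return A tibble with one row per motif: category, representative copy
#'   coordinates, `length`, `identity` (minimum over merged hits),
#'   `orientation`, `genes_hit`, `n_merged`.
#' @export
classify_repeats <- function(hits, genome, tandem_gap = 10L, palindrome_gap = 3000L) {
  if (!nrow(hits)) {
    return(tibble::tibble(category = character(), copy1_start = integer(),
                          copy1_end = integer(), copy2_start = integer(),
                          copy2_end = integer(), length = integer(),
                          identity = numeric(), orientation = character(),
                          genes_hit = character(), n_merged = integer()))
  }
  nh <- nrow(hits)
  # connected components over footprint overlap
  overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  comp <- seq_len(nh)
  repeat {
    changed <- FALSE
    for (i in seq_len(nh - 1L)) for (j in (i + 1L):nh) {
      if (comp[i] != comp[j] &&
          (overlaps(hits$copy1_start[i], hits$copy1_end[i], hits$copy1_start[j], hits$copy1_end[j]) ||
           overlaps(hits$copy1_start[i], hits$copy1_end[i], hits$copy2_start[j], hits$copy2_end[j]) ||
           overlaps(hits$copy2_start[i], hits$copy2_end[i], hits$copy1_start[j], hits$copy1_end[j]) ||
           overlaps(hits$copy2_start[i], hits$copy2_end[i], hits$copy2_start[j], hits$copy2_end[j]))) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  genes <- genome$features[genome$features$kind %in%
                             c("gene", "CDS", "tRNA", "rRNA"), , drop = FALSE]
  purrr::map_dfr(unique(comp), function(cc) {
    grp <- hits[comp == cc, , drop = FALSE]
    rep_hit <- grp[order(-grp$length, grp$copy1_start), ][1, ]
    gap <- rep_hit$copy2_start - rep_hit$copy1_end
    g1 <- unique(genes$name[overlaps(genes$start, genes$end,
                                     rep_hit$copy1_start, rep_hit$copy1_end)])
    g2 <- unique(genes$name[overlaps(genes$start, genes$end,
                                     rep_hit$copy2_start, rep_hit$copy2_end)])
    category <- if (rep_hit$orientation == "direct" && gap <= tandem_gap) {
      "tandem"
    } else if (rep_hit$orientation == "inverted" && gap <= palindrome_gap) {
      "palindromic"
    } else if (length(g1) && length(g2) && length(union(g1, g2)) >= 2L &&
               !setequal(g1, g2)) {
      "gene_similarity"
    } else "dispersed"
    tibble::tibble(category = category,
                   copy1_start = rep_hit$copy1_start, copy1_end = rep_hit$copy1_end,
                   copy2_start = rep_hit$copy2_start, copy2_end = rep_hit$copy2_end,
                   length = rep_hit$length,
                   identity = min(grp$identity),
                   orientation = rep_hit$orientation,
                   genes_hit = paste(sort(union(g1, g2)), collapse = ","),
                   n_merged = nrow(grp))
  })
}

#' Summarise classified repeats
#'
#' @param repeats A tibble from [classify_repeats()].
#' @return A list: `total`, `by_category` (tibble of counts, fractions and
#'   copy-length statistics), `length_range`.
#' @export
repeat_summary <- function(repeats) {
  cats <- c("dispersed", "tandem", "palindromic", "gene_similarity")
  if (!nrow(repeats)) {
    return(list(total = 0L,
                by_category = tibble::tibble(category = cats, n = 0L,
                                             fraction = 0, min_len = NA_integer_,
                                             mean_len = NA_real_, max_len = NA_integer_),
                length_range = c(NA_integer_, NA_integer_)))
  }
  by_cat <- purrr::map_dfr(cats, function(cc) {
    sel <- repeats[repeats$category == cc, , drop = FALSE]
    tibble::tibble(category = cc, n = nrow(sel),
                   fraction = nrow(sel) / nrow(repeats),
                   min_len = if (nrow(sel)) min(sel$length) else NA_integer_,
                   mean_len = if (nrow(sel)) mean(sel$length) else NA_real_,
                   max_len = if (nrow(sel)) max(sel$length) else NA_integer_)
  })
  list(total = nrow(repeats), by_category = by_cat,
       length_range = range(repeats$length))
}
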