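#' Detect the quadripartite LSC/IRb/SSC/IRa architecture
#'
#' Finds the longest pair of inverted, near-identical segments of the genome
#' (the inverted repeat) by exact k-mer seeding (k = 25) of the genome
#' against its reverse complement, followed by greedy extension that keeps
#' the running identity of the extended span at or above `min_identity`.
#' The longer intervening single-copy stretch is labelled LSC, the shorter
#' SSC; IRb is the IR copy that follows the LSC in coordinate direction.
#' When the two IR copies differ in length, `ir_length` is the length of IRb.
#'
#' @param genome A [plastome].
#' @param min_ir Minimum IR length in bases (default 1000).
#' @param min_identity Minimum running identity for seed extension
#'   (default 0.99).
#' @return A list of class `quadripartite` with elements `lsc`, `irb`,
#'   `ssc`, `ira` (each an interval matrix with 0-based half-open rows;
#'   a region that wraps the origin has two rows), `ir_length`, and
#'   `no_ir` (`TRUE` when no inverted duplication of at least `min_ir`
#'   bases exists, in which case the partition degenerates to one region).
#' @export
detect_quadripartite <- function(genome, min_ir = 1000L, min_identity = 0.99) {
  stopifnot(inherits(genome, "plastome"))
  n <- genome$length
  S <- genome$sequence
  R <- revcomp(S)
  k <- 25L
  no_ir <- structure(list(lsc = cbind(start = 0L, end = n), irb = NULL,
                          ssc = NULL, ira = NULL, ir_length = 0L,
                          no_ir = TRUE, genome_length = n),
                     class = "quadripartite")
  if (n < 2L * min_ir + 2L || n < k) return(no_ir)

  Sv <- chars(S); Rv <- chars(R)
  hits <- seed_hits(S, R, k)
  if (!nrow(hits)) return(no_ir)

  # extend candidate segments per diagonal d = j - i (i on S, j on R; both
  # 1-based); the candidate with the longest extended span wins
  best <- NULL
  for (d in unique(hits$j - hits$i)) {
    ii <- sort(hits$i[hits$j - hits$i == d])
    p_lo <- max(1L, 1L - d); p_hi <- min(n, n - d) - k + 1L
    m <- Sv[p_lo:(p_hi + k - 1L)] == Rv[(p_lo:(p_hi + k - 1L)) + d]
    runs <- seed_runs(ii, k)
    for (r in seq_len(nrow(runs))) {
      span <- extend_run(m, runs[r, 1] - p_lo + 1L, runs[r, 2] - p_lo + 1L, min_identity)
      a <- span[1] + p_lo - 1L; b <- span[2] + p_lo - 1L   # 1-based on S
      len <- b - a + 1L
      # copy2 in genome coordinates (1-based inclusive)
      c2s <- n + 1L - (b + d); c2e <- n + 1L - (a + d)
      if (c2s <= b) next                                   # overlapping copies
      if (is.null(best) || len > best$len ||
          (len == best$len && a < best$a)) {
        best <- list(a = a, b = b, c2s = c2s, c2e = c2e, len = len)
      }
    }
  }
  if (is.null(best) || best$len < min_ir) return(no_ir)

  # 0-based half-open copies
  ir1 <- c(best$a - 1L, best$b); ir2 <- c(best$c2s - 1L, best$c2e)
  inner <- c(ir1[2], ir2[1])                    # between the two copies
  inner_len <- inner[2] - inner[1]
  outer_len <- n - (ir1[2] - ir1[1]) - (ir2[2] - ir2[1]) - inner_len
  outer <- if (ir2[2] < n || ir1[1] > 0L) {
    rbind(c(ir2[2], n), c(0L, ir1[1]))
  } else cbind(integer(), integer())
  outer <- outer[outer[, 1] < outer[, 2], , drop = FALSE]
  iv <- function(x) {
    x <- rbind(x); colnames(x) <- c("start", "end"); x
  }
  if (outer_len >= inner_len) {
    # LSC wraps (or precedes copy1): order around circle LSC, copy1=IRb,
    # inner=SSC, copy2=IRa
    part <- list(lsc = iv(outer), irb = iv(ir1), ssc = iv(inner), ira = iv(ir2))
  } else {
    part <- list(lsc = iv(inner), irb = iv(ir2), ssc = iv(outer), ira = iv(ir1))
  }
  structure(c(part, list(ir_length = part$irb[1, 2] - part$irb[1, 1],
                         no_ir = FALSE, genome_length = n)),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  if (x$no_ir) {
    cat("<quadripartite> no IR detected; single region of", x$genome_length, "bp\n")
    return(invisible(x))
  }
  fmt <- function(m) paste(sprintf("[%d,%d)", m[, 1], m[, 2]), collapse = " + ")
  cat(sprintf("<quadripartite> LSC %s | IRb %s | SSC %s | IRa %s (IR %d bp)\n",
              fmt(x$lsc), fmt(x$irb), fmt(x$ssc), fmt(x$ira), x$ir_length))
  invisible(x)
}

# exact k-mer seed pairs between S and R (both 1-based start positions)
seed_hits <- function(S, R, k) {
  n <- nchar(S)
  starts <- seq_len(n - k + 1L)
  ks <- substring(S, starts, starts + k - 1L)
  kr <- substring(R, starts, starts + k - 1L)
  tab <- split(starts, ks)
  idx <- tab[kr]
  found <- !vapply(idx, is.null, TRUE)
  if (!any(found)) return(data.frame(i = integer(), j = integer()))
  j <- rep.int(starts[found], lengths(idx[found]))
  i <- unlist(idx[found], use.names = FALSE)
  data.frame(i = i, j = j)
}

# collapse sorted seed start positions into runs of overlapping seeds;
# returns matrix of (first, last) where last is the end of the covered span
seed_runs <- function(ii, k) {
  breaks <- which(diff(ii) > k)
  s <- ii[c(1L, breaks + 1L)]
  e <- ii[c(breaks, length(ii))] + k - 1L
  cbind(s, e)
}

# extension of an exact seed run [a,b] over the diagonal match vector m:
# the hit grows by whole match-runs; a mismatch stretch is crossed only onto
# a further exact run of >= confirm_run matches, and only while the overall
# identity of the extended span stays >= min_identity. Iterated to a fixed
# point (left growth can re-enable right growth). Exact duplications are
# therefore recovered with 0 bp of boundary creep.
extend_run <- function(m, a, b, min_identity, confirm_run = 8L) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  # run index containing the seed (seed is all-match, so one TRUE run)
  cur <- which(r$values & starts <= a & ends >= b)
  if (!length(cur)) return(c(a, b))
  lo <- cur; hi <- cur
  a <- starts[cur]; b <- ends[cur]            # grow to the full seed run
  matches <- b - a + 1L
  repeat {
    moved <- FALSE
    nxt <- true_runs[true_runs > hi]
    if (length(nxt)) {
      nxt <- nxt[1]
      if (r$lengths[nxt] >= confirm_run &&
          (matches + r$lengths[nxt]) / (ends[nxt] - a + 1L) >= min_identity) {
        matches <- matches + r$lengths[nxt]
        b <- ends[nxt]; hi <- nxt; moved <- TRUE
      }
    }
    prv <- true_runs[true_runs < lo]
    if (length(prv)) {
      prv <- prv[length(prv)]
      if (r$lengths[prv] >= confirm_run &&
          (matches + r$lengths[prv]) / (b - starts[prv] + 1L) >= min_identity) {
        matches <- matches + r$lengths[prv]
        a <- starts[prv]; lo <- prv; moved <- TRUE
      }
    }
    if (!moved) break
  }
  c(a, b)
}

#' Report the gene context of the four quadripartite junctions
#'
#' For each junction (LSC/IRb, IRb/SSC, SSC/IRa, IRa/LSC) reports the feature
#' spanning it, or otherwise the nearest feature, with the signed offset from
#' that feature's closest boundary to the junction. When two or more features
#' overlap the junction (e.g. a pseudogene/gene overlap) they are all listed
#' in `overlapping`.
#'
#' @param genome A [plastome].
#' @param part A `quadripartite` from [detect_quadripartite()].
#' @return A tibble with columns `junction`, `position`, `gene`, `offset`,
#'   `spans`, `overlapping`.
#' @export
junction_report <- function(genome, part) {
  stopifnot(inherits(part, "quadripartite"))
  if (part$no_ir) abort("no IR detected; no junctions to report")
  jpos <- c("LSC/IRb" = unname(part$irb[1, 1]), "IRb/SSC" = unname(part$ssc[1, 1]),
            "SSC/IRa" = unname(part$ira[1, 1]), "IRa/LSC" = unname(part$lsc[1, 1]))
  f <- genome$features
  f <- f[f$kind != "misc", , drop = FALSE]
  n <- genome$length
  purrr::map_dfr(names(jpos), function(j) {
    p <- jpos[[j]]
    if (!nrow(f)) {
      return(tibble::tibble(junction = j, position = p, gene = NA_character_,
                            offset = NA_integer_, spans = FALSE,
                            overlapping = NA_character_))
    }
    spanning <- f$start < p & f$end > p
    if (any(spanning)) {
      sp <- f[spanning, ]
      tibble::tibble(junction = j, position = p, gene = sp$name[1],
                     offset = p - sp$start[1], spans = TRUE,
                     overlapping = if (nrow(sp) > 1L)
                       paste(unique(sp$name), collapse = ",") else NA_character_)
    } else {
      # circular distance from junction to the nearest feature boundary
      dist_end <- (p - f$end) %% n      # feature upstream of junction
      dist_start <- (f$start - p) %% n  # feature downstream
      best_up <- which.min(dist_end); best_dn <- which.min(dist_start)
      if (dist_end[best_up] <= dist_start[best_dn]) {
        tibble::tibble(junction = j, position = p, gene = f$name[best_up],
                       offset = as.integer(dist_end[best_up]), spans = FALSE,
                       overlapping = NA_character_)
      } else {
        tibble::tibble(junction = j, position = p, gene = f$name[best_dn],
                       offset = -as.integer(dist_start[best_dn]), spans = FALSE,
                       overlapping = NA_character_)
      }
    }
  })
}

#' Genome composition statistics
#'
#' AT content, coding fraction (union of CDS, tRNA and rRNA intervals;
#' pseudogenes and introns count as noncoding), per-class coding fractions,
#' and functional gene counts: `unique_genes` is the number of distinct
#' functional gene names and `duplicated_genes` the number of those present
#' as two or more copies (the IR duplicates). Pseudogenes are excluded from
#' both gene counts.
#'
#' @param genome A [plastome].
#' @return A one-row tibble.
#' @export
composition_stats <- function(genome) {
  n <- genome$length
  base_counts <- table(factor(chars(genome$sequence), levels = c("A", "C", "G", "T", "N")))
  at <- unname(base_counts["A"] + base_counts["T"]) / n
  f <- genome$features
  union_len <- function(kinds) {
    sel <- f[f$kind %in% kinds, , drop = FALSE]
    m <- merge_intervals(sel$start, sel$end)
    sum(m[, "end"] - m[, "start"])
  }
  coding <- union_len(c("CDS", "tRNA", "rRNA")) / n
  genes <- f[f$kind == "gene", , drop = FALSE]
  copies <- table(unique(genes[, c("name", "feature_id")])$name)
  tibble::tibble(
    id = genome$id,
    genome_length = n,
    at_fraction = at,
    coding_fraction = coding,
    protein_fraction = union_len("CDS") / n,
    trna_fraction = union_len("tRNA") / n,
    rrna_fraction = union_len("rRNA") / n,
    unique_genes = length(copies),
    duplicated_genes = sum(copies >= 2L)
  )
}

#' Inverted syntenic blocks between two gene orders
#'
#' Represents each genome as a signed permutation of its single-copy shared
#' genes (sign = strand, order = start coordinate) and returns the maximal
#' blocks whose gene order is reversed with flipped strands in `b` relative
#' to `a`.
#'
#' @param a,b Annotated [plastome]s sharing a gene-name vocabulary.
#' @return A tibble with one row per inverted block: `genes` (comma-joined,
#'   in `a` order), `a_start`, `b_start` (1-based indices into the shared
#'   gene orders) and `length`. Empty when fewer than two genes are shared.
#' @export
gene_order_inversions <- function(a, b) {
  order_of <- function(g) {
    genes <- g$features[g$features$kind == "gene", , drop = FALSE]
    first <- genes[!duplicated(genes$feature_id), , drop = FALSE]
    single <- names(which(table(first$name) == 1L))
    first <- first[first$name %in% single, , drop = FALSE]
    first[order(first$start), c("name", "strand")]
  }
  oa <- order_of(a); ob <- order_of(b)
  shared <- intersect(oa$name, ob$name)
  if (length(shared) < 2L) return(tibble::tibble(genes = character(),
                                                 a_start = integer(),
                                                 b_start = integer(),
                                                 length = integer()))
  oa <- oa[oa$name %in% shared, ]; ob <- ob[ob$name %in% shared, ]
  sig <- function(o) ifelse(o$strand == "+", 1L, -1L)
  pa <- setNames(seq_len(nrow(oa)) * sig(oa), oa$name)
  vb <- unname(pa[ob$name]) * sig(ob)          # b as signed a-indices
  # maximal descending, sign-flipped runs in vb
  out <- list()
  i <- 1L
  while (i <= length(vb)) {
    if (vb[i] < 0) {
      j <- i
      while (j < length(vb) && vb[j + 1L] == vb[j] + 1L && vb[j + 1L] < 0) j <- j + 1L
      a_idx <- sort(-vb[i:j])
      out[[length(out) + 1L]] <- tibble::tibble(
        genes = paste(oa$name[a_idx], collapse = ","),
        a_start = a_idx[1], b_start = i, length = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(out)) return(tibble::tibble(genes = character(),
                                          a_start = integer(),
                                          b_start = integer(),
                                          length = integer()))
  dplyr::bind_rows(out)
}
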