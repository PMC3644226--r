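#' Incongruence length difference (partition homogeneity) test
#'
#' Compares the summed maximum-parsimony tree lengths of two character
#' partitions with the sums obtained after randomly reassigning columns to
#' two pseudo-partitions of the original sizes (sampling without
#' replacement). Incongruence is signalled when the observed within-
#' partition sum is *smaller* than the permuted sums (separate trees fit
#' incongruent partitions better), so
#' `p = (1 + #\{replicate sum <= observed sum\}) / (replicates + 1)`.
#' Constant columns are retained in the permutation.
#'
#' For seven or fewer taxa the MP lengths are obtained exactly by scoring
#' every topology once per site pattern and minimising a matrix product;
#' otherwise [mp_search()] runs per replicate with the given strategy.
#'
#' @param alignment A [dna_alignment].
#' @param partition_labels Vector of length `ncol(alignment)` with two
#'   levels assigning each column to partition 1 or 2.
#' @param replicates Number of permutation replicates (>= 1; default 99).
#' @param strategy Search strategy for > 7 taxa (default branch and bound).
#' @param seed Integer seed.
#' @return An object of class `ild_result`: `observed_sum`, `observed_D`
#'   (combined length minus the sum), `partition_lengths`,
#'   `replicate_sums`, `p_value`, `replicates`, `seed`, `low_power`
#'   (`TRUE` when a partition has no variable column).
#' @export
ild_test <- function(alignment, partition_labels, replicates = 99L,
                     strategy = "branch_and_bound", seed = 1L) {
  if (replicates < 1L) abort("at least 1 replicate required")
  L <- nchar(alignment$seqs[[1]])
  if (length(partition_labels) != L)
    abort("partition_labels must label every alignment column")
  lev <- unique(partition_labels)
  if (length(lev) != 2L) abort("exactly two partitions required")
  cols1 <- which(partition_labels == lev[1])
  cols2 <- which(partition_labels == lev[2])
  codes <- encode_alignment(alignment)
  cp <- compress_patterns(codes)
  P <- length(cp$weights)
  ntip <- length(alignment$ids)
  wt_of <- function(cols) tabulate(cp$pattern_of[cols], nbins = P)
  if (ntip <= 7L) {
    S <- all_tree_steps(cp$pat, alignment$ids)
    mp_len <- function(cols) min(S %*% wt_of(cols))
  } else {
    mp_len <- function(cols) {
      fit <- mp_search_impl(cp$pat, wt_of(cols), alignment$ids,
                            strategy, n_starts = 5L, seed = seed)
      fit$L
    }
  }
  L1 <- mp_len(cols1); L2 <- mp_len(cols2)
  observed_sum <- L1 + L2
  L_comb <- mp_len(seq_len(L))
  set.seed(seed)
  n1 <- length(cols1)
  replicate_sums <- vapply(seq_len(replicates), function(b) {
    perm <- sample.int(L)
    mp_len(perm[seq_len(n1)]) + mp_len(perm[(n1 + 1L):L])
  }, 0)
  p <- (1 + sum(replicate_sums <= observed_sum)) / (replicates + 1)
  varcols <- pattern_min_steps(cp$pat) > 0L
  low_power <- !any(varcols[cp$pattern_of[cols1]]) || !any(varcols[cp$pattern_of[cols2]])
  structure(list(observed_sum = observed_sum,
                 observed_D = L_comb - observed_sum,
                 partition_lengths = c(L1, L2), combined_length = L_comb,
                 replicate_sums = replicate_sums, p_value = p,
                 replicates = replicates, seed = seed,
                 low_power = low_power),
            class = "ild_result")
}

#' @export
print.ild_result <- function(x, ...) {
  cat(sprintf("<ild_result> observed sum %g (D = %g), p = %.4g (%d replicates)%s\n",
              x$observed_sum, x$observed_D, x$p_value, x$replicates,
              if (x$low_power) " [low power: a partition has no variable site]" else ""))
  invisible(x)
}

# steps matrix: one row per unrooted topology on the taxa, one column per
# site pattern (exact MP machinery for small taxon counts)
all_tree_steps <- function(pat, labels) {
  ntip <- length(labels)
  tipstate <- lapply(seq_len(ntip), function(i) pat[i, ])
  P <- ncol(pat)
  rows <- list()
  recurse <- function(edges, next_tip) {
    if (next_tip > ntip) {
      rows[[length(rows) + 1L]] <<- fitch_steps_per_pattern(edges, tipstate, P)
      return(invisible())
    }
    newint <- ntip + next_tip - 2L
    for (r in seq_len(nrow(edges)))
      recurse(insert_leaf(edges, r, next_tip, newint), next_tip + 1L)
  }
  recurse(start_tree(ntip), 4L)
  do.call(rbind, rows)
}

#' Per-region congruence against a reference tree
#'
#' For each region alignment: infers its MP tree (strict consensus over
#' ties), computes the Robinson-Foulds distance to the reference tree, and
#' runs the ILD test of the region against the concatenation of all other
#' regions. A region is flagged congruent when the consensus has RF = 0.
#' Regions missing any reference taxon are dropped with a message.
#'
#' @param region_alignments Named list of [dna_alignment]s over the
#'   reference leaf set.
#' @param reference_tree A `phylo` tree.
#' @param strategy Search strategy (see [mp_search()]).
#' @param seed Integer seed.
#' @param ild_replicates Permutation replicates for the per-region ILD test;
#'   0 skips the test (column `ild_p` becomes NA).
#' @return A tibble: `region`, `aligned_length`, `pic_percent`, `L`,
#'   `rf_to_reference`, `ild_p`, `congruent`.
#' @export
per_region_congruence <- function(region_alignments, reference_tree,
                                  strategy = "branch_and_bound", seed = 1L,
                                  ild_replicates = 99L) {
  leaves <- reference_tree$tip.label
  keep <- vapply(region_alignments, function(a) all(leaves %in% a$ids), TRUE)
  if (any(!keep))
    message("dropping region(s) missing reference taxa: ",
            paste(names(region_alignments)[!keep], collapse = ", "))
  region_alignments <- region_alignments[keep]
  nm <- names(region_alignments)
  purrr::map_dfr(seq_along(region_alignments), function(i) {
    aln <- region_alignments[[i]]
    aln <- dna_alignment(aln$seqs[leaves], region_name = aln$region_name)
    fit <- mp_search(aln, strategy = strategy, seed = seed)
    cons <- strict_consensus(fit$best_trees)
    rf <- rf_distance(cons, reference_tree)
    pic <- pic_fraction(aln)
    ild_p <- NA_real_
    if (ild_replicates > 0L && length(region_alignments) > 1L) {
      rest <- concat_alignments(region_alignments[-i], ids = leaves)
      comb <- concat_alignments(list(aln, rest), ids = leaves)
      labs <- c(rep(1L, nchar(aln$seqs[[1]])), rep(2L, nchar(rest$seqs[[1]])))
      ild_p <- ild_test(comb, labs, replicates = ild_replicates,
                        strategy = strategy, seed = seed)$p_value
    }
    tibble::tibble(region = nm[i],
                   aligned_length = pic$aligned_length,
                   pic_percent = 100 * pic$pic_fraction,
                   L = fit$length,
                   rf_to_reference = rf,
                   ild_p = ild_p,
                   congruent = rf == 0L)
  })
}

#' Concatenate alignments over a shared id set
#'
#' @param alignments List of [dna_alignment]s each containing every id.
#' @param ids Ids (and row order) of the result; defaults to the ids of the
#'   first alignment.
#' @return A [dna_alignment].
#' @export
concat_alignments <- function(alignments, ids = NULL) {
  if (!length(alignments)) abort("no alignments to concatenate")
  ids <- ids %||% alignments[[1]]$ids
  rows <- vapply(ids, function(id) {
    paste(vapply(alignments, function(a) {
      if (!id %in% a$ids) abort(sprintf("id '%s' missing from an alignment", id))
      unname(a$seqs[id])
    }, ""), collapse = "")
  }, "")
  dna_alignment(rows)
}
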