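#' Classify alignment columns
#'
#' Per column, residues are gathered excluding gaps (`-`) and `N`; the column
#' is `constant` when at most one distinct state remains,
#' `parsimony_informative` when at least two states each occur at least
#' twice, otherwise `variable_singleton`; columns with no residues at all
#' are `gap_or_missing_only`. A gap never makes a site informative.
#'
#' @param alignment A [dna_alignment] with >= 2 rows.
#' @return A list of class `site_classification`: `labels` (per-column
#'   factor), `counts` (named totals), `aligned_length`, and
#'   `analysed_length` (columns with at least one residue).
#' @export
classify_sites <- function(alignment) {
  m <- aln_matrix(alignment)
  if (nrow(m) < 2L) abort("need >= 2 alignment rows")
  L <- ncol(m)
  lv <- c("constant", "variable_singleton", "parsimony_informative", "gap_or_missing_only")
  cnt <- sapply(c("A", "C", "G", "T"), function(b) colSums(m == b))
  cnt <- matrix(cnt, ncol = 4L)                       # L x 4
  n_states <- rowSums(cnt > 0L)
  n_ge2 <- rowSums(cnt >= 2L)
  lab <- rep("constant", L)
  lab[n_states == 0L] <- "gap_or_missing_only"
  lab[n_states >= 2L] <- "variable_singleton"
  lab[n_states >= 2L & n_ge2 >= 2L] <- "parsimony_informative"
  labels <- factor(lab, levels = lv)
  structure(list(labels = labels,
                 counts = table(labels),
                 aligned_length = L,
                 analysed_length = sum(n_states > 0L)),
            class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat("<site_classification>", x$aligned_length, "columns:\n")
  print(x$counts)
  invisible(x)
}

#' Parsimony-informative character fraction (PIC)
#'
#' Fraction of alignment columns that are parsimony-informative, with the
#' full aligned length (gapped columns included) as denominator; an
#' alternative with only the analysed (not wholly gap/missing) columns as
#' denominator is reported alongside for transparency.
#'
#' @param alignment A [dna_alignment].
#' @return A one-row tibble: `pic_fraction`, `pi_sites`, `variable_sites`,
#'   `aligned_length`, `analysed_length`, `pic_fraction_analysed`.
#' @export
pic_fraction <- function(alignment) {
  sc <- classify_sites(alignment)
  pi <- unname(sc$counts["parsimony_informative"])
  var <- pi + unname(sc$counts["variable_singleton"])
  tibble::tibble(pic_fraction = pi / sc$aligned_length,
                 pi_sites = as.integer(pi),
                 variable_sites = as.integer(var),
                 aligned_length = sc$aligned_length,
                 analysed_length = sc$analysed_length,
                 pic_fraction_analysed =
                   if (sc$analysed_length > 0) pi / sc$analysed_length else 0)
}

#' Uncorrected p-distance matrix
#'
#' Proportion of differing sites between every pair of rows. Under complete
#' deletion (default) every column containing a gap or N in any row is
#' dropped before comparison; pairwise deletion drops such columns per pair.
#'
#' @param alignment A [dna_alignment] with >= 2 rows.
#' @param deletion `"complete"` or `"pairwise"`.
#' @return A list of class `p_distance_matrix`: `ids`, `values` (symmetric
#'   matrix of proportions), `sites_used` (scalar for complete deletion, a
#'   matrix for pairwise), `deletion`.
#' @export
p_distance_matrix <- function(alignment, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- aln_matrix(alignment)
  if (nrow(m) < 2L) abort("need >= 2 alignment rows")
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  if (deletion == "complete") {
    keep <- colSums(ok) == n
    if (!any(keep)) abort("no comparable sites after complete deletion")
    mm <- m[, keep, drop = FALSE]
    sites <- ncol(mm)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(mm[i, ] != mm[j, ]) / sites
    }
    sites_used <- sites
  } else {
    sites_used <- matrix(0L, n, n, dimnames = dimnames(d))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      keep <- ok[i, ] & ok[j, ]
      s <- sum(keep)
      if (s == 0L) abort(sprintf("no comparable sites between %s and %s",
                                 alignment$ids[i], alignment$ids[j]))
      d[i, j] <- d[j, i] <- sum(m[i, keep] != m[j, keep]) / s
      sites_used[i, j] <- sites_used[j, i] <- s
    }
  }
  structure(list(ids = alignment$ids, values = d, sites_used = sites_used,
                 deletion = deletion),
            class = "p_distance_matrix")
}

#' @export
print.p_distance_matrix <- function(x, ...) {
  cat(sprintf("<p_distance_matrix> %d taxa, %s deletion\n",
              length(x$ids), x$deletion))
  print(round(x$values, 4))
  invisible(x)
}

#' Species-level divergence summary
#'
#' Mean p-distance over all unordered pairs, over pairs from different
#' species, and over pairs sharing a species (absent when no such pair
#' exists). When the source alignment is supplied, also reports the overall
#' divergent fraction: variable columns / analysed columns.
#'
#' @param dmat A [p_distance_matrix].
#' @param species_of Named character vector mapping every id to a species.
#' @param alignment Optional [dna_alignment] the matrix came from.
#' @return A one-row tibble: `mean_all`, `mean_between_species`,
#'   `mean_within_species`, `overall_divergent_fraction`.
#' @export
divergence_summary <- function(dmat, species_of, alignment = NULL) {
  ids <- dmat$ids
  if (!all(ids %in% names(species_of)))
    abort("species_of must label every id in the distance matrix")
  sp <- species_of[ids]
  n <- length(ids)
  pairs <- which(upper.tri(dmat$values), arr.ind = TRUE)
  vals <- dmat$values[pairs]
  same <- sp[pairs[, 1]] == sp[pairs[, 2]]
  odf <- NA_real_
  if (!is.null(alignment)) {
    sc <- classify_sites(alignment)
    v <- unname(sc$counts["parsimony_informative"] + sc$counts["variable_singleton"])
    odf <- if (sc$analysed_length > 0) v / sc$analysed_length else 0
  }
  tibble::tibble(
    mean_all = mean(vals),
    mean_between_species = if (any(!same)) mean(vals[!same]) else NA_real_,
    mean_within_species = if (any(same)) mean(vals[same]) else NA_real_,
    overall_divergent_fraction = odf
  )
}
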