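#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MP search result
#'
#' One row per equally most-parsimonious tree, with its Newick string.
#'
#' @param x An `mp_fit` from [mp_search()].
#' @param ... Unused.
#' @return A tibble: `tree`, `length`, `newick`.
#' @export
tidy.mp_fit <- function(x, ...) {
  tibble::tibble(tree = seq_along(x$best_trees),
                 length = x$length,
                 newick = vapply(x$best_trees, function(t)
                   ape::write.tree(t), ""))
}

#' One-row summary of an MP search
#'
#' @param x An `mp_fit`.
#' @param ... Unused.
#' @return A tibble: `length`, `n_trees`, `n_taxa`, `strategy`, `seed`.
#' @export
glance.mp_fit <- function(x, ...) {
  tibble::tibble(length = x$length, n_trees = x$n_trees,
                 n_taxa = x$n_taxa, strategy = x$strategy, seed = x$seed)
}

#' Tidy an ILD test result
#'
#' One row per permutation replicate.
#'
#' @param x An `ild_result` from [ild_test()].
#' @param ... Unused.
#' @return A tibble: `replicate`, `sum_length`.
#' @export
tidy.ild_result <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$replicate_sums),
                 sum_length = x$replicate_sums)
}

#' One-row summary of an ILD test
#'
#' @param x An `ild_result`.
#' @param ... Unused.
#' @return A tibble with the observed sum, D, p-value and metadata.
#' @export
glance.ild_result <- function(x, ...) {
  tibble::tibble(observed_sum = x$observed_sum, observed_D = x$observed_D,
                 p_value = x$p_value, replicates = x$replicates,
                 seed = x$seed, low_power = x$low_power)
}

#' Tidy a hotspot scan
#'
#' @param x A `hotspot_scan` from [run_scan()].
#' @param ... Unused.
#' @return The ranked region-report tibble.
#' @export
tidy.hotspot_scan <- function(x, ...) x$region_reports

#' One-row summary of a hotspot scan
#'
#' @param x A `hotspot_scan`.
#' @param ... Unused.
#' @return A tibble of totals and the combined tree length.
#' @export
glance.hotspot_scan <- function(x, ...) {
  r <- x$region_reports
  tibble::tibble(n_regions = nrow(r),
                 n_passing = sum(r$passes_length),
                 n_informative = sum(r$informative_flag),
                 n_hotspot = sum(r$hotspot_flag),
                 combined_length = if (is.null(x$combined_fit)) NA_real_
                                   else x$combined_fit$length,
                 seed = x$config$seed)
}
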