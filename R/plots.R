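#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a hotspot scan as a ranked PIC% profile
#'
#' Bar chart of PIC% per passing region, coloured by kind, with the
#' informative and hotspot thresholds drawn as horizontal lines.
#'
#' @param object A `hotspot_scan` from [run_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hotspot_scan <- function(object, ...) {
  r <- object$region_reports
  r <- r[r$passes_length, , drop = FALSE]
  r$region <- factor(r$region, levels = r$region[order(-r$pic_percent)])
  ggplot2::ggplot(r, ggplot2::aes(x = .data$region, y = .data$pic_percent,
                                  fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$config$informative_pic,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$config$hotspot_pic,
                        linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "parsimony-informative characters (%)",
                  fill = "region kind") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot an ILD permutation distribution
#'
#' Histogram of replicate within-partition length sums with the observed
#' sum marked; small observed sums (left tail) signal incongruence.
#'
#' @param object An `ild_result` from [ild_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ild_result <- function(object, ...) {
  df <- tibble::tibble(sum_length = object$replicate_sums)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sum_length)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$observed_sum, colour = "red") +
    ggplot2::labs(x = "permuted partition length sum (steps)", y = "replicates",
                  subtitle = sprintf("observed sum %g, p = %.3g",
                                     object$observed_sum, object$p_value)) +
    ggplot2::theme_minimal()
}
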