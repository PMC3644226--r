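#' Annotated plastome container
#'
#' An annotated circular plastid genome: a DNA string over `{A,C,G,T,N}` plus
#' an ordered feature table. All coordinates are 0-based half-open
#' (`start` inclusive, `end` exclusive); features that wrap the origin are
#' stored as two intervals sharing one `feature_id`.
#'
#' @param id Accession or label.
#' @param sequence DNA string; ambiguity codes other than N are mapped to N
#'   with a warning.
#' @param features A data frame with columns `feature_id`, `name`, `kind`
#'   (one of gene, CDS, tRNA, rRNA, intron, pseudogene, misc), `start`,
#'   `end`, `strand` (`"+"` or `"-"`); one row per interval (exon).
#'   Optional; defaults to no features.
#' @param species,individual Taxon and sample labels.
#' @return An object of class `plastome`.
#' @export
plastome <- function(id, sequence, features = NULL, species = id, individual = id) {
  sequence <- sanitize_dna(sequence, context = id)
  len <- nchar(sequence)
  if (len == 0L) abort("empty genome sequence")
  if (is.null(features)) {
    features <- tibble::tibble(feature_id = integer(), name = character(),
                               kind = character(), start = integer(),
                               end = integer(), strand = character())
  }
  features <- tibble::as_tibble(features)
  need <- c("feature_id", "name", "kind", "start", "end", "strand")
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols)) abort(paste("features lacks columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(features)) {
    if (any(features$start < 0L) || any(features$end > len))
      abort("feature interval outside [0, genome length)")
    if (any(features$start >= features$end))
      abort("feature interval with start >= end (wrap-around must be split)")
  }
  structure(list(id = id, species = species, individual = individual,
                 sequence = sequence, length = len, features = features),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s (%s / %s): %s bp, %d feature intervals\n",
              x$id, x$species, x$individual,
              format(x$length, big.mark = ","),
              nrow(x$features)))
  invisible(x)
}

#' @export
length.plastome <- function(x) x$length

#' Extract a subsequence from a circular genome
#'
#' Coordinates are 0-based half-open. A region that wraps the origin is given
#' as two intervals (vectors `start`, `end` of length 2) and is concatenated
#' across the origin. `strand = "-"` returns the reverse complement of the
#' concatenated plus-strand sequence.
#'
#' @param genome A [plastome].
#' @param start,end Integer vectors (parallel) of 0-based half-open intervals.
#' @param strand `"+"` or `"-"`.
#' @return A DNA string.
#' @export
extract_subsequence <- function(genome, start, end, strand = "+") {
  stopifnot(inherits(genome, "plastome"), length(start) == length(end))
  if (any(start < 0L) || any(end > genome$length) || any(start > end))
    abort("interval out of range for genome")
  s <- paste(substring(genome$sequence, start + 1L, end), collapse = "")
  if (strand == "-") revcomp(s) else s
}

# Total feature footprint as a merged interval set (matrix with cols start,end).
merge_intervals <- function(start, end) {
  if (!length(start)) return(cbind(start = integer(), end = integer()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- end[i] }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}
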