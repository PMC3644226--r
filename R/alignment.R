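#' Gapped DNA alignment container
#'
#' Equal-length gapped rows over `{A,C,G,T,N,-}` with unique ids, stored as a
#' named character vector. Most results that summarise an alignment
#' (site classification, PIC fraction, p-distances) take this class.
#'
#' @param seqs Named character vector of equal-length gapped sequences.
#' @param region_name Optional label for the region the alignment covers.
#' @return An object of class `dna_alignment`.
#' @export
dna_alignment <- function(seqs, region_name = NULL) {
  if (!length(seqs)) abort("empty alignment")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    abort("alignment rows must be named")
  if (anyDuplicated(names(seqs)))
    abort(sprintf("duplicate alignment ids: %s",
                  paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", ")))
  seqs <- vapply(seqs, sanitize_dna, "", USE.NAMES = TRUE)
  if (length(unique(nchar(seqs))) != 1L)
    abort("alignment rows differ in length")
  structure(list(ids = names(seqs), seqs = seqs,
                 region_name = region_name),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment>%s %d rows x %d columns\n",
              if (is.null(x$region_name)) "" else paste0(" ", x$region_name),
              length(x$ids), nchar(x$seqs[[1]])))
  invisible(x)
}

#' @export
dim.dna_alignment <- function(x) c(length(x$ids), nchar(x$seqs[[1]]))

# rows x columns character matrix view
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

aln_from_matrix <- function(m, region_name = NULL) {
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- rownames(m)
  dna_alignment(seqs, region_name = region_name)
}

#' Read a multi-FASTA alignment
#'
#' Rows are uppercased; `-` gaps and `N` are accepted; other ambiguity codes
#' map to `N` with a warning. Input order is preserved.
#'
#' @param path Path to a multi-FASTA file of equal-length gapped rows.
#' @return A [dna_alignment].
#' @export
read_fasta_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) abort(sprintf("%s: no FASTA records", path))
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (length(unique(nchar(seqs))) != 1L)
    abort(sprintf("%s: rows have unequal lengths", path))
  dna_alignment(seqs)
}

#' Write sequences or an alignment as FASTA (70-column wrap)
#'
#' @param x A [dna_alignment] or a named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "dna_alignment")) as.list(x$seqs) else as.list(x)
  write_fasta_file(seqs, path)
}
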