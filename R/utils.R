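#' @importFrom rlang %||% abort warn
#' @importFrom stats setNames
NULL

# Reverse complement of a plain character DNA string (A,C,G,T,N,-).
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN-", "TGCAN-", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Random DNA string
#'
#' I.i.d. sequence over A/C/G/T with a configurable AT fraction (uniform by
#' default), used by the simulator and by tests. Draws from the current RNG
#' stream; seed it for reproducibility.
#'
#' @param n Length in bases.
#' @param at Expected A+T fraction (default 0.5).
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, at = 0.5) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Replace IUPAC ambiguity codes other than N by N (downstream statistics are
# defined over {A,C,G,T,N,-} only); warns when it does so.
sanitize_dna <- function(x, context = "sequence") {
  x <- toupper(x)
  bad <- gsub("[ACGTN-]", "", x)
  if (nzchar(bad)) {
    warn(sprintf("%s: %d ambiguity character(s) (%s) mapped to N",
                 context, nchar(bad),
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ",")))
    x <- gsub("[^ACGTN-]", "N", x)
  }
  x
}

# Split a string into a character vector of single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# 70-column FASTA wrap.
wrap70 <- function(x) {
  n <- nchar(x)
  starts <- seq(1L, n, by = 70L)
  substring(x, starts, pmin(starts + 69L, n))
}

write_fasta_file <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    writeLines(wrap70(seqs[[id]]), con)
  }
  invisible(path)
}
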