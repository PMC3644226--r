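#' Decompose an annotated genome into exon, intron and spacer regions
#'
#' Gene and pseudogene footprints (merged where they overlap) partition the
#' circle; the gaps between consecutive footprints are intergenic spacers
#' named `geneA-geneB` in genome orientation (the spacer between the last
#' and first footprint wraps the origin). Within each functional gene,
#' consecutive exon intervals yield `gene-exonN` / `gene-intronN` regions;
#' single-exon genes yield one region named by the gene. Pseudogenes break
#' spacers like genes do but contribute no exon regions.
#'
#' @param genome A [plastome].
#' @return A tibble: `name`, `kind` (exon/intron/spacer), `start`, `end`,
#'   `start2`, `end2` (second interval for the wrap-around spacer, else NA),
#'   `strand`.
#' @export
genome_regions <- function(genome) {
  f <- genome$features
  fp <- f[f$kind %in% c("gene", "pseudogene"), , drop = FALSE]
  if (!nrow(fp)) abort(sprintf("%s: no gene annotation", genome$id))
  foot <- dplyr::summarise(dplyr::group_by(fp, .data$feature_id),
                           name = .data$name[1], kind = .data$kind[1],
                           strand = .data$strand[1],
                           fs = min(.data$start), fe = max(.data$end),
                           .groups = "drop")
  foot <- foot[order(foot$fs), ]
  n <- genome$length
  rows <- list()
  add <- function(name, kind, s, e, strand = "+", s2 = NA_integer_, e2 = NA_integer_) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = name, kind = kind, start = s, end = e,
      start2 = s2, end2 = e2, strand = strand)
  }
  # gene internals; pseudogene interiors are carried as noncoding regions
  # (they are landmarks, not protein-coding exons) so the regions tile the
  # genome exactly
  for (i in seq_len(nrow(foot))) {
    if (foot$kind[i] == "pseudogene") {
      add(foot$name[i], "spacer", foot$fs[i], foot$fe[i], foot$strand[i])
      next
    }
    iv <- fp[fp$feature_id == foot$feature_id[i], , drop = FALSE]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) == 1L) {
      add(foot$name[i], "exon", iv$start, iv$end, foot$strand[i])
    } else {
      for (e in seq_len(nrow(iv))) {
        add(paste0(foot$name[i], "-exon", e), "exon", iv$start[e], iv$end[e], foot$strand[i])
        if (e < nrow(iv))
          add(paste0(foot$name[i], "-intron", e), "intron", iv$end[e], iv$start[e + 1L], foot$strand[i])
      }
    }
  }
  # spacers between merged footprint blocks
  blocks <- merge_intervals(foot$fs, foot$fe)
  last_gene <- vapply(seq_len(nrow(blocks)), function(b) {
    inb <- foot[foot$fs >= blocks[b, 1] & foot$fe <= blocks[b, 2], ]
    inb$name[which.max(inb$fe)]
  }, "")
  first_gene <- vapply(seq_len(nrow(blocks)), function(b) {
    inb <- foot[foot$fs >= blocks[b, 1] & foot$fe <= blocks[b, 2], ]
    inb$name[which.min(inb$fs)]
  }, "")
  nb <- nrow(blocks)
  for (b in seq_len(nb)) {
    nxt <- if (b == nb) 1L else b + 1L
    s <- blocks[b, 2]
    e <- if (b == nb) blocks[1, 1] else blocks[nxt, 1]
    nm <- paste0(last_gene[b], "-", first_gene[nxt])
    if (b == nb) {
      if (s < n || e > 0L)
        add(nm, "spacer", s, n, "+", s2 = 0L, e2 = e)
    } else if (e > s) {
      add(nm, "spacer", s, e, "+")
    }
  }
  dplyr::bind_rows(rows)
}

# strip a tRNA anticodon suffix for tolerant spacer-name matching
strip_anticodon <- function(x) gsub("-[ACGTU]{3}(?=-|$)", "", x, perl = TRUE)

region_sequence <- function(genome, r) {
  s <- r$start; e <- r$end
  if (!is.na(r$start2)) { s <- c(s, r$start2); e <- c(e, r$end2) }
  extract_subsequence(genome, s, e, r$strand)
}

#' Extract homologous regions across genomes
#'
#' Regions (exons, introns, intergenic spacers) are defined on the reference
#' genome with [genome_regions()]; the homologous sequence in every other
#' genome is located through that genome's own annotation (same gene names
#' for exons/introns, same flanking-gene pair for spacers — anticodon
#' suffixes may differ, and a spacer found with reversed flanking order is
#' taken reverse-complemented). Regions missing from a genome are recorded
#' absent. No length filter is applied here.
#'
#' @param genomes A named list of annotated [plastome]s (names = ids), or an
#'   unnamed list (ids are taken from the genomes).
#' @param reference_id Id of the reference genome (must be present).
#' @param partition Optional `quadripartite` of the reference; when given,
#'   regions lying entirely inside IRa are dropped so IR content is
#'   represented once (the IRb instance).
#' @return A list of class `region_set_list`; each element is a list with
#'   `name`, `kind`, `reference_start`, `reference_end`, `strand`,
#'   `sequences` (named character), `absent` (ids lacking the region).
#' @export
extract_homologous_regions <- function(genomes, reference_id, partition = NULL) {
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, function(g) g$id, "")
  if (!reference_id %in% names(genomes))
    abort(sprintf("reference genome '%s' not in genome set", reference_id))
  decomp <- lapply(genomes, genome_regions)
  ref <- decomp[[reference_id]]
  if (!is.null(partition) && !partition$no_ir) {
    ira <- partition$ira[1, ]
    inside <- ref$start >= ira["start"] & ref$end <= ira["end"] & is.na(ref$start2)
    ref <- ref[!inside, , drop = FALSE]
  }
  others <- setdiff(names(genomes), reference_id)
  # per-genome lookup tables
  lookups <- lapply(decomp, function(d) {
    d$stripped <- strip_anticodon(d$name)
    d$rev_name <- vapply(strsplit(d$name, "-"), function(p) {
      if (length(p) == 2L) paste(rev(p), collapse = "-") else NA_character_
    }, "")
    d
  })
  out <- vector("list", nrow(ref))
  for (i in seq_len(nrow(ref))) {
    r <- ref[i, ]
    seqs <- c(setNames(region_sequence(genomes[[reference_id]], r), reference_id))
    absent <- character(0)
    for (id in others) {
      d <- lookups[[id]]
      hit <- which(d$name == r$name & d$kind == r$kind)
      revc <- FALSE
      if (!length(hit) && r$kind == "spacer") {
        hit <- which(d$stripped == strip_anticodon(r$name) & d$kind == "spacer")
        if (!length(hit)) {
          rn <- strsplit(r$name, "-")[[1]]
          if (length(rn) == 2L) {
            rev_nm <- paste(rev(rn), collapse = "-")
            hit <- which(d$name == rev_nm & d$kind == "spacer")
            if (!length(hit))
              hit <- which(d$stripped == strip_anticodon(rev_nm) & d$kind == "spacer")
            revc <- length(hit) > 0L
          }
        }
      }
      if (!length(hit)) { absent <- c(absent, id); next }
      s <- region_sequence(genomes[[id]], d[hit[1], ])
      if (revc) s <- revcomp(s)
      seqs[id] <- s
    }
    out[[i]] <- list(name = r$name, kind = r$kind,
                     reference_start = r$start, reference_end = r$end,
                     strand = r$strand, sequences = seqs, absent = absent)
  }
  structure(out, class = "region_set_list")
}

#' @export
print.region_set_list <- function(x, ...) {
  cat(sprintf("<region_set_list> %d regions (%d exon, %d intron, %d spacer)\n",
              length(x),
              sum(vapply(x, function(r) r$kind, "") == "exon"),
              sum(vapply(x, function(r) r$kind, "") == "intron"),
              sum(vapply(x, function(r) r$kind, "") == "spacer")))
  invisible(x)
}

#' Index table for an extracted region set
#'
#' @param regions A `region_set_list`.
#' @return A tibble: region, kind, reference_start, reference_end,
#'   n_sequences.
#' @export
regions_index <- function(regions) {
  purrr::map_dfr(regions, function(r) {
    tibble::tibble(region = r$name, kind = r$kind,
                   reference_start = r$reference_start,
                   reference_end = r$reference_end,
                   n_sequences = length(r$sequences))
  })
}

#' Center-star progressive multiple alignment
#'
#' Picks the center sequence maximising the summed pairwise global-alignment
#' score, aligns every other sequence to the center with affine-gap global
#' alignment (a gap of length L costs `gap_open + L * gap_extend`), and
#' merges the pairwise alignments under "once a gap, always a gap".
#' Deterministic; ties in the center choice go to input order.
#'
#' @param sequences Named character vector (or list) of >= 2 DNA sequences.
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (defaults +2, -1, -5, -2).
#' @param region_name Optional label carried into the result.
#' @return A [dna_alignment] in input row order.
#' @export
align_center_star <- function(sequences,
                              scoring = list(match = 2, mismatch = -1,
                                             gap_open = -5, gap_extend = -2),
                              region_name = NULL) {
  sequences <- unlist(sequences)
  if (length(sequences) < 2L) abort("need >= 2 sequences to align")
  if (any(!nzchar(sequences))) abort("cannot align an empty sequence")
  sequences <- vapply(sequences, sanitize_dna, "", USE.NAMES = TRUE)
  ids <- names(sequences)
  n <- length(sequences)
  band_of <- function(i, j) {
    if (max(nchar(sequences[[i]]), nchar(sequences[[j]])) > 400L) 50L else NULL
  }
  if (n == 2L) {
    center <- 1L
  } else {
    # summed pairwise global-alignment score per candidate center
    totals <- numeric(n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      sc <- nw_align(sequences[[i]], sequences[[j]], scoring,
                     band = band_of(i, j), score_only = TRUE)$score
      totals[i] <- totals[i] + sc
      totals[j] <- totals[j] + sc
    }
    center <- which.max(totals)
  }
  cseq <- sequences[[center]]
  lc <- nchar(cseq)
  others <- setdiff(seq_len(n), center)
  # pairwise alignments to the center: per slot (0..lc) the insertion of the
  # other sequence before center residue slot, and per residue the aligned char
  ins <- matrix("", nrow = n, ncol = lc + 1L)
  alc <- matrix("-", nrow = n, ncol = lc)
  alc[center, ] <- chars(cseq)
  for (i in others) {
    # long sequences get a banded DP: homologous plastome regions drift by
    # at most a few indels, far less than the 50-column half-width
    nw <- nw_align(cseq, sequences[[i]], scoring, band = band_of(center, i))
    ac <- nw$a_aln
    as_ <- nw$b_aln
    is_res <- ac != "-"
    cpos <- cumsum(is_res)                     # center position per column
    alc[i, cpos[is_res]] <- as_[is_res]
    gap_cols <- which(!is_res)
    if (length(gap_cols)) {
      slot <- cpos[gap_cols] + 1L              # insertion before this residue
      pieces <- vapply(split(as_[gap_cols], slot), paste, "", collapse = "")
      ins[i, as.integer(names(pieces))] <- pieces
    }
  }
  widths <- apply(nchar(ins), 2L, max)
  pads <- matrix(strrep("-", pmax(0L, rep(widths, each = n) - nchar(ins))),
                 nrow = n)
  padded <- matrix(paste0(ins, pads), nrow = n)
  blocks <- matrix("", nrow = n, ncol = 2L * lc + 1L)
  blocks[, seq(1L, 2L * lc + 1L, by = 2L)] <- padded
  blocks[, seq(2L, 2L * lc, by = 2L)] <- alc
  rows <- apply(blocks, 1L, paste, collapse = "")
  names(rows) <- ids
  dna_alignment(rows, region_name = region_name)
}

align_submat <- function(scoring) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

#' Align every region of a region set
#'
#' Runs [align_center_star()] on each region with at least two present
#' sequences; regions with fewer are skipped.
#'
#' @param regions A `region_set_list`.
#' @param scoring Passed to [align_center_star()].
#' @return Named list of [dna_alignment]s.
#' @export
align_regions <- function(regions, scoring = list(match = 2, mismatch = -1,
                                                  gap_open = -5, gap_extend = -2)) {
  out <- list()
  for (r in regions) {
    if (length(r$sequences) < 2L) next
    out[[r$name]] <- align_center_star(r$sequences, scoring, region_name = r$name)
  }
  out
}

# Affine-gap global pairwise alignment (Gotoh), maximising; a gap of length
# L costs gap_open + L * gap_extend (both negative). Computed in C (see
# src/align.cpp), optionally restricted to a diagonal band of half-width
# `band` for near-homologous sequences. Deterministic traceback with tie
# order match > gap-in-b > gap-in-a. Returns the two aligned rows as
# character vectors plus the optimal score.
nw_align <- function(a, b, scoring, band = NULL, score_only = FALSE) {
  if (is.null(band)) band <- max(nchar(a), nchar(b))
  res <- nw_align_cpp(a, b, scoring$match, scoring$mismatch,
                      -scoring$gap_open, -scoring$gap_extend,
                      as.integer(band), score_only)
  if (score_only) return(res)
  list(a_aln = chars(res$a_aln), b_aln = chars(res$b_aln), score = res$score)
}
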