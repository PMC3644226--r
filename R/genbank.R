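#' Read an annotated genome from a GenBank flat file
#'
#' Parses LOCUS, FEATURES and ORIGIN blocks. GenBank 1-based inclusive
#' locations become 0-based half-open intervals; `join()` becomes one feature
#' with several intervals (exon order preserved); `complement()` sets the
#' minus strand. Gene names are normalised to a lower-case three-letter stem
#' with the case-sensitive suffix kept (`RPS19 -> rps19`, `trnK-UUU` kept).
#' A `source` feature's `/organism` and `/isolate` qualifiers populate the
#' species and individual labels.
#'
#' @param path Path to a GenBank flat file containing one record.
#' @return A [plastome].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) abort(sprintf("%s: no LOCUS line", path))
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- locus[2]
  stated_len <- suppressWarnings(as.integer(locus[3]))

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) abort(sprintf("%s: no ORIGIN block", path))
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1L

  # -- sequence ---------------------------------------------------------------
  seq_lines <- lines[(orig_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!is.na(stated_len) && nchar(sequence) != stated_len)
    abort(sprintf("%s: LOCUS says %d bp but ORIGIN has %d",
                  path, stated_len, nchar(sequence)))

  # -- features ---------------------------------------------------------------
  species <- id; individual <- id
  features <- tibble::tibble(feature_id = integer(), name = character(),
                             kind = character(), start = integer(),
                             end = integer(), strand = character())
  if (length(feat_i)) {
    flines <- lines[(feat_i[1] + 1L):(orig_i[1] - 1L)]
    # group physical lines into feature entries: a new entry starts when a
    # feature key appears in columns 6-20
    is_key <- grepl("^ {5}\\S", flines)
    if (any(!is_key & !grepl("^ {21}", flines) & nzchar(trimws(flines)))) {
      bad <- which(!is_key & !grepl("^ {21}", flines) & nzchar(trimws(flines)))[1]
      abort(sprintf("%s: malformed FEATURES line %d: %s", path,
                    feat_i[1] + bad, trimws(flines[bad])))
    }
    grp <- cumsum(is_key)
    rows <- list(); fid <- 0L
    for (g in unique(grp[grp > 0])) {
      entry <- flines[grp == g]
      key <- sub("^\\s*(\\S+).*", "\\1", entry[1])
      rest <- c(sub("^ {5}\\S+\\s*", "", entry[1]), trimws(entry[-1]))
      # location = leading lines up to the first qualifier
      qual_start <- which(startsWith(rest, "/"))
      loc_str <- paste(rest[seq_len(if (length(qual_start)) qual_start[1] - 1L else length(rest))],
                       collapse = "")
      quals <- if (length(qual_start)) rest[qual_start[1]:length(rest)] else character()
      q <- parse_qualifiers(quals)
      if (key == "source") {
        if (!is.null(q$organism)) species <- q$organism
        if (!is.null(q$isolate)) individual <- q$isolate
        next
      }
      loc <- parse_gb_location(loc_str, path)
      kind <- switch(key, gene = "gene", CDS = "CDS", tRNA = "tRNA",
                     rRNA = "rRNA", intron = "intron", "misc")
      if (!is.null(q$pseudo) || isTRUE(q$pseudo)) kind <- "pseudogene"
      name <- q$gene %||% q$standard_name %||% q$label %||% key
      fid <- fid + 1L
      rows[[fid]] <- tibble::tibble(feature_id = fid,
                                    name = normalize_gene_name(name),
                                    kind = kind,
                                    start = loc$start, end = loc$end,
                                    strand = loc$strand)
    }
    if (length(rows)) features <- dplyr::bind_rows(rows)
  }
  if (nrow(features) && any(features$end > nchar(sequence)))
    abort(sprintf("%s: feature interval beyond sequence end", path))
  plastome(id, sequence, features, species = species, individual = individual)
}

parse_qualifiers <- function(quals) {
  if (!length(quals)) return(list())
  # re-join continuation lines (a qualifier runs until the next "/")
  idx <- cumsum(startsWith(quals, "/"))
  joined <- vapply(split(quals, idx), paste, "", collapse = " ")
  out <- list()
  for (qq in joined) {
    m <- regmatches(qq, regexec('^/([A-Za-z_]+)(=("?)(.*?)\\3)?\\s*$', qq, perl = TRUE))[[1]]
    if (length(m)) out[[m[2]]] <- if (nzchar(m[3])) m[5] else TRUE
  }
  out
}

# "complement(join(5..10,20..25))" -> intervals + strand, 0-based half-open.
parse_gb_location <- function(loc, path = "") {
  loc <- gsub("\\s+", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  parts <- gsub("[<>]", "", parts)
  if (!length(parts) || any(!grepl("^\\d+(\\.\\.\\d+)?$", parts)))
    abort(sprintf("%s: cannot parse location '%s'", path, loc))
  a <- as.integer(sub("\\.\\..*$", "", parts))
  b <- as.integer(sub("^\\d+(\\.\\.)?", "", sub("^(\\d+)$", "\\1..\\1", parts)))
  b <- ifelse(is.na(b), a, b)
  list(start = a - 1L, end = b, strand = strand)
}

# lower-case the three-letter stem of a plastid gene symbol; keep the
# case-sensitive suffix (number, subunit letter, anticodon).
normalize_gene_name <- function(name) {
  vapply(name, function(n) {
    if (grepl("^[A-Za-z]{3}", n))
      paste0(tolower(substr(n, 1, 3)), substring(n, 4))
    else n
  }, "", USE.NAMES = FALSE)
}

#' Write a plastome as a GenBank flat file
#'
#' Inverse of [read_genbank()] for plastomes built in R (notably simulator
#' output): emits LOCUS, a `source` feature carrying the species and
#' individual labels, every feature with its GenBank-style location, and the
#' ORIGIN sequence block.
#'
#' @param genome A [plastome].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular PLN %s",
                     genome$id, genome$length, format(Sys.Date(), "%d-%b-%Y")),
             con)
  writeLines(sprintf("DEFINITION  %s chloroplast, complete genome.", genome$species), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", genome$length), con)
  writeLines(sprintf('                     /organism="%s"', genome$species), con)
  writeLines(sprintf('                     /isolate="%s"', genome$individual), con)
  f <- genome$features
  if (nrow(f)) {
    for (fid in unique(f$feature_id)) {
      fr <- f[f$feature_id == fid, ]
      key <- switch(fr$kind[1], gene = "gene", CDS = "CDS", tRNA = "tRNA",
                    rRNA = "rRNA", intron = "intron",
                    pseudogene = "gene", "misc_feature")
      spans <- sprintf("%d..%d", fr$start + 1L, fr$end)
      loc <- if (length(spans) > 1L) sprintf("join(%s)", paste(spans, collapse = ",")) else spans
      if (fr$strand[1] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-15s %s", key, loc), con)
      writeLines(sprintf('                     /gene="%s"', fr$name[1]), con)
      if (fr$kind[1] == "pseudogene")
        writeLines("                     /pseudo", con)
    }
  }
  writeLines("ORIGIN", con)
  s <- genome$sequence
  for (pos in seq(1L, genome$length, by = 60L)) {
    chunk <- substring(s, pos, min(pos + 59L, genome$length))
    tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", pos, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}
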