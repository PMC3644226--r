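#' Pipeline configuration for the divergence-hotspot scan
#'
#' @param reference_id Reference genome id; defaults to the first genome.
#' @param min_region_len Minimum aligned region length in bp for a region to
#'   pass (strictly greater than; default 200).
#' @param informative_pic PIC percentage at or above which a passing region
#'   is flagged informative (default 2).
#' @param hotspot_pic PIC percentage strictly above which a passing region
#'   is flagged a hotspot (default 3).
#' @param strategy MP search strategy (see [mp_search()]).
#' @param bootstrap_replicates Bootstrap replicates for the combined tree;
#'   0 skips bootstrapping (default 100).
#' @param ild_replicates Permutation replicates for per-region ILD tests;
#'   0 skips them (default 99).
#' @param seed Integer seed recorded in all outputs.
#' @param exclude_regions Region names dropped before analysis (stand-in
#'   for manual curation of ambiguously aligned loci).
#' @param deletion p-distance deletion mode, `"complete"` or `"pairwise"`.
#' @param scoring Alignment scoring for [align_center_star()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_id = NULL, min_region_len = 200L,
                            informative_pic = 2.0, hotspot_pic = 3.0,
                            strategy = "branch_and_bound",
                            bootstrap_replicates = 100L,
                            ild_replicates = 99L, seed = 1L,
                            exclude_regions = character(),
                            deletion = "complete",
                            scoring = list(match = 2, mismatch = -1,
                                           gap_open = -5, gap_extend = -2)) {
  if (min_region_len <= 0 || informative_pic <= 0 || hotspot_pic <= 0)
    abort("thresholds must be positive")
  structure(list(reference_id = reference_id, min_region_len = min_region_len,
                 informative_pic = informative_pic, hotspot_pic = hotspot_pic,
                 strategy = strategy,
                 bootstrap_replicates = bootstrap_replicates,
                 ild_replicates = ild_replicates, seed = as.integer(seed),
                 exclude_regions = exclude_regions, deletion = deletion,
                 scoring = scoring),
            class = "pipeline_config")
}

#' Run the end-to-end divergence-hotspot scan
#'
#' Extracts homologous regions on the reference, aligns each region
#' (built-in center-star aligner, or pre-aligned inputs), classifies sites
#' and computes PIC%, applies the length and PIC thresholds, infers the
#' combined-alignment MP tree (with bootstrap when configured), assesses
#' per-region congruence of hotspot-flagged regions against the combined
#' tree, and returns the ranked region report. Deterministic given
#' (inputs, config, seed).
#'
#' @param genomes Named list of annotated [plastome]s (>= 3 for tree
#'   steps; with 2 genomes a statistics-only report is produced).
#' @param config A [pipeline_config()].
#' @param alignments Optional named list of pre-built region
#'   [dna_alignment]s (e.g. from external aligner output read with
#'   [read_fasta_alignment()]); skips extraction and alignment.
#' @return A list of class `hotspot_scan`: `region_reports` (tibble),
#'   `combined_tree` (`phylo` or NULL), `combined_fit` (`mp_fit`),
#'   `bootstrap`, `alignments`, `partition`, `config`, `summary`.
#' @export
run_scan <- function(genomes, config = pipeline_config(), alignments = NULL) {
  if (is.null(alignments)) {
    if (is.null(names(genomes)))
      names(genomes) <- vapply(genomes, function(g) g$id, "")
    ref_id <- config$reference_id %||% names(genomes)[1]
    if (!ref_id %in% names(genomes)) abort("reference genome missing")
    part <- detect_quadripartite(genomes[[ref_id]])
    regions <- extract_homologous_regions(genomes, ref_id, partition = part)
    alignments <- align_regions(regions, config$scoring)
    kinds <- setNames(vapply(regions, function(r) r$kind, ""),
                      vapply(regions, function(r) r$name, ""))
  } else {
    part <- NULL
    kinds <- setNames(rep("spacer", length(alignments)), names(alignments))
  }
  alignments <- alignments[setdiff(names(alignments), config$exclude_regions)]
  if (!length(alignments)) {
    warn("all regions filtered out")
    return(structure(list(region_reports = empty_region_report(),
                          combined_tree = NULL, combined_fit = NULL,
                          bootstrap = NULL, alignments = list(),
                          partition = part, config = config),
                     class = "hotspot_scan"))
  }
  reports <- purrr::map_dfr(names(alignments), function(nm) {
    p <- pic_fraction(alignments[[nm]])
    tibble::tibble(region = nm,
                   kind = unname(kinds[nm]) %||% NA_character_,
                   aligned_length = p$aligned_length,
                   variable_sites = p$variable_sites,
                   pi_sites = p$pi_sites,
                   pic_percent = 100 * p$pic_fraction)
  })
  reports$passes_length <- reports$aligned_length > config$min_region_len
  reports$informative_flag <- reports$passes_length &
    reports$pic_percent >= config$informative_pic
  reports$hotspot_flag <- reports$passes_length &
    reports$pic_percent > config$hotspot_pic
  reports$rank <- NA_integer_
  passing <- which(reports$passes_length)
  reports$rank[passing[order(-reports$pic_percent[passing],
                             reports$region[passing])]] <-
    seq_along(passing)

  all_ids <- unique(unlist(lapply(alignments, function(a) a$ids)))
  complete <- purrr::keep(alignments, function(a) setequal(a$ids, all_ids))
  combined_fit <- NULL; combined_tree <- NULL; boot <- NULL
  reports$congruent <- NA
  reports$ild_p <- NA_real_
  if (length(all_ids) >= 4L && length(complete)) {   # 3 taxa: single topology, statistics only
    combined <- concat_alignments(complete, ids = all_ids)
    combined_fit <- mp_search(combined, strategy = config$strategy,
                              seed = config$seed)
    combined_tree <- strict_consensus(combined_fit$best_trees)
    if (config$bootstrap_replicates > 0L) {
      boot <- bootstrap_support(combined, config$bootstrap_replicates,
                                strategy = config$strategy,
                                seed = config$seed)
    }
    hot <- reports$region[reports$hotspot_flag]
    hot <- intersect(hot, names(complete))
    if (length(hot)) {
      cong <- per_region_congruence(complete[hot], combined_tree,
                                    strategy = config$strategy,
                                    seed = config$seed,
                                    ild_replicates = config$ild_replicates)
      reports$congruent[match(cong$region, reports$region)] <- cong$congruent
      reports$ild_p[match(cong$region, reports$region)] <- cong$ild_p
    }
  }
  reports <- reports[order(is.na(reports$rank), reports$rank), ]
  structure(list(region_reports = reports, combined_tree = combined_tree,
                 combined_fit = combined_fit, bootstrap = boot,
                 alignments = alignments, partition = part, config = config),
            class = "hotspot_scan")
}

empty_region_report <- function() {
  tibble::tibble(region = character(), kind = character(),
                 aligned_length = integer(), variable_sites = integer(),
                 pi_sites = integer(), pic_percent = numeric(),
                 passes_length = logical(), informative_flag = logical(),
                 hotspot_flag = logical(), rank = integer(),
                 congruent = logical(), ild_p = numeric())
}

#' @export
print.hotspot_scan <- function(x, ...) {
  r <- x$region_reports
  cat(sprintf("<hotspot_scan> %d regions (%d passing, %d informative, %d hotspot); seed %d\n",
              nrow(r), sum(r$passes_length), sum(r$informative_flag),
              sum(r$hotspot_flag), x$config$seed))
  invisible(x)
}

#' Split a whole-genome alignment into the six standard datasets
#'
#' Columns inherit the structural (LSC / SSC / IR) and functional (protein
#' coding exon vs intron/spacer) class of their reference residue;
#' gap-in-reference columns inherit the class of the preceding reference
#' residue. Returns the six datasets: complete sequence, protein coding
#' exons, LSC, SSC, IR, and introns + spacers.
#'
#' @param whole_alignment A [dna_alignment] containing the reference row.
#' @param annotation The reference [plastome].
#' @param partition A `quadripartite` for the reference (computed when
#'   NULL).
#' @return Named list of [dna_alignment]s: `complete`, `coding_exons`,
#'   `lsc`, `ssc`, `ir`, `introns_spacers`.
#' @export
partition_datasets <- function(whole_alignment, annotation, partition = NULL) {
  if (!annotation$id %in% whole_alignment$ids)
    abort("reference row missing from alignment")
  if (is.null(partition)) partition <- detect_quadripartite(annotation)
  refrow <- chars(whole_alignment$seqs[[annotation$id]])
  L <- length(refrow)
  # reference 0-based coordinate per column (gap columns inherit previous)
  ref_pos <- cumsum(refrow != "-") - 1L
  ref_pos[ref_pos < 0L] <- 0L
  n <- annotation$length
  struct_of <- rep("lsc", n)
  lab <- function(m, what) {
    if (is.null(m)) return(invisible())
    for (r in seq_len(nrow(m)))
      if (m[r, 2] > m[r, 1]) struct_of[(m[r, 1] + 1L):m[r, 2]] <<- what
  }
  if (!partition$no_ir) {
    lab(partition$lsc, "lsc"); lab(partition$irb, "ir")
    lab(partition$ssc, "ssc"); lab(partition$ira, "ir")
  }
  f <- annotation$features
  coding <- rep(FALSE, n)
  cf <- f[f$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  for (r in seq_len(nrow(cf))) coding[(cf$start[r] + 1L):cf$end[r]] <- TRUE
  col_struct <- struct_of[ref_pos + 1L]
  col_coding <- coding[ref_pos + 1L]
  subaln <- function(keep) {
    rows <- vapply(whole_alignment$seqs, function(s)
      paste(chars(s)[keep], collapse = ""), "")
    names(rows) <- whole_alignment$ids
    dna_alignment(rows)
  }
  list(complete = whole_alignment,
       coding_exons = subaln(col_coding),
       lsc = subaln(col_struct == "lsc"),
       ssc = subaln(col_struct == "ssc"),
       ir = subaln(col_struct == "ir"),
       introns_spacers = subaln(!col_coding))
}

#' Write the ranked marker report to disk
#'
#' Writes `region_report.tsv` (ranked), one Newick file per hotspot region's
#' MP tree, the combined tree, and a run-metadata block (package version,
#' configuration, seed). Output is byte-identical across reruns with the
#' same inputs and seed.
#'
#' @param scan A `hotspot_scan` from [run_scan()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible character vector of files written.
#' @export
marker_report <- function(scan, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create '%s'", out_dir))
  files <- character(0)
  tsv <- file.path(out_dir, "region_report.tsv")
  df <- as.data.frame(scan$region_reports)
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (cc in names(df)[num]) df[[cc]] <- sprintf("%.6f", df[[cc]])
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  files <- c(files, tsv)
  if (!is.null(scan$combined_tree)) {
    f <- file.path(out_dir, "combined_tree.nwk")
    ape::write.tree(scan$combined_tree, f)
    files <- c(files, f)
  }
  if (!is.null(scan$bootstrap)) {
    f <- file.path(out_dir, "combined_tree_bootstrap.nwk")
    ape::write.tree(scan$bootstrap$consensus, f)
    files <- c(files, f)
  }
  hot <- scan$region_reports$region[scan$region_reports$hotspot_flag %in% TRUE]
  for (nm in intersect(hot, names(scan$alignments))) {
    fit <- mp_search(scan$alignments[[nm]], strategy = scan$config$strategy,
                     seed = scan$config$seed)
    f <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", nm), ".nwk"))
    ape::write.tree(strict_consensus(fit$best_trees), f)
    files <- c(files, f)
  }
  meta <- file.path(out_dir, "run_metadata.txt")
  cfg <- scan$config
  writeLines(c(
    paste0("package_version\t", as.character(utils::packageVersion("plastomics"))),
    paste0("seed\t", cfg$seed),
    paste0("min_region_len\t", cfg$min_region_len),
    paste0("informative_pic\t", cfg$informative_pic),
    paste0("hotspot_pic\t", cfg$hotspot_pic),
    paste0("strategy\t", cfg$strategy),
    paste0("bootstrap_replicates\t", cfg$bootstrap_replicates),
    paste0("ild_replicates\t", cfg$ild_replicates),
    paste0("deletion\t", cfg$deletion),
    paste0("exclude_regions\t", paste(cfg$exclude_regions, collapse = ","))
  ), meta)
  files <- c(files, meta)
  invisible(files)
}
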