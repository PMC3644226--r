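#' Simulation configuration for a quadripartite plastome set
#'
#' Describes the study design the simulator emulates: a known tree with
#' branch lengths (expected substitutions/site), an ordered genome plan of
#' regions (genes, introns, spacers) grouped into the LSC, IRb and SSC
#' structural parts (IRa is the exact reverse complement of the IRb block),
#' per-class rate multipliers, indels confined to noncoding DNA, and
#' planted repeats of the four categories.
#'
#' @param tree Newick string or `phylo` with branch lengths; >= 4 leaves.
#' @param genome_plan Tibble with columns `name`, `kind` (exon, intron,
#'   spacer), `length`, `rate_class`, `part` (LSC, IRb, SSC), `gene` (gene
#'   name for exon/intron rows, NA for spacers), `gkind` (CDS, tRNA, rRNA,
#'   pseudogene for gene rows), `strand`.
#' @param rate_classes Named multipliers (defaults: coding 0.3, intron 1.0,
#'   spacer 1.5, hotspot 10).
#' @param indel_rate Indel events per substitution in noncoding DNA
#'   (default 0.1).
#' @param indel_mean_len Mean of the geometric indel length (default 4).
#' @param planted_repeats Tibble with columns `length`, `identity`,
#'   `category` (dispersed, tandem, palindromic, gene_similarity) and
#'   `host` (region name, or "regionA|regionB" for the two-host
#'   categories).
#' @param at_content Expected A+T fraction of the root genome (default
#'   0.63, the AT-richness typical of plastomes).
#' @param species_of Named character vector mapping each leaf to a species.
#' @param ir_copy_correction Keep IRa identical to IRb after every branch
#'   (plastome copy-correction mimic; default TRUE). Disable to test
#'   tolerant IR detection.
#' @param seed Integer seed governing every random draw.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(tree, genome_plan,
                              rate_classes = c(coding = 0.3, intron = 1.0,
                                               spacer = 1.5, hotspot = 10.0),
                              indel_rate = 0.1, indel_mean_len = 4,
                              planted_repeats = NULL,
                              at_content = 0.63,
                              species_of = NULL,
                              ir_copy_correction = TRUE,
                              seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) abort("tree must carry branch lengths")
  if (length(tree$tip.label) < 4L) abort("tree must have >= 4 leaves")
  genome_plan <- tibble::as_tibble(genome_plan)
  need <- c("name", "kind", "length", "rate_class", "part", "gene", "gkind", "strand")
  if (!all(need %in% names(genome_plan)))
    abort(paste("genome_plan lacks columns:",
                paste(setdiff(need, names(genome_plan)), collapse = ", ")))
  if (any(genome_plan$length <= 0L)) abort("plan region lengths must be > 0")
  if (any(!genome_plan$rate_class %in% names(rate_classes)))
    abort("plan uses an undefined rate class")
  if (any(rate_classes <= 0)) abort("rate multipliers must be > 0")
  hot <- names(which(rate_classes == max(rate_classes)))
  if (any(genome_plan$rate_class %in% hot & genome_plan$part == "IRb"))
    abort("inconsistent plan: IR block may not contain a hotspot region")
  if (is.null(species_of))
    species_of <- setNames(tree$tip.label, tree$tip.label)
  structure(list(tree = tree, genome_plan = genome_plan,
                 rate_classes = rate_classes, indel_rate = indel_rate,
                 indel_mean_len = indel_mean_len,
                 planted_repeats = planted_repeats,
                 at_content = at_content,
                 species_of = species_of,
                 ir_copy_correction = ir_copy_correction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Evolve a DNA sequence along one branch
#'
#' Jukes-Cantor substitution: each site substitutes with probability
#' `p = 3/4 (1 - exp(-4/3 b m))` for branch length `b` and rate multiplier
#' `m`, drawing uniformly among the three other bases. When `noncoding`,
#' indel events are drawn at `indel_rate` events per expected substitution
#' with geometric lengths (mean `indel_mean_len`); insertions and deletions
#' are equally likely. Draws from the current RNG stream.
#'
#' @param parent DNA string.
#' @param branch_length Expected substitutions/site (>= 0).
#' @param multiplier Rate multiplier (> 0).
#' @param noncoding Allow indels?
#' @param indel_rate,indel_mean_len Indel process parameters.
#' @return List: `child` (DNA string), `map` (for each child position, the
#'   1-based parent position it descends from, NA for insertions),
#'   `n_subs`, `n_indels`.
#' @export
evolve_sequence <- function(parent, branch_length, multiplier,
                            noncoding = FALSE, indel_rate = 0.1,
                            indel_mean_len = 4) {
  if (branch_length < 0) abort("branch_length must be >= 0")
  x <- chars(parent)
  n <- length(x)
  map <- seq_len(n)
  p_sub <- 0.75 * (1 - exp(-4 / 3 * branch_length * multiplier))
  n_subs <- 0L
  if (p_sub > 0 && n > 0L) {
    hit <- which(stats::runif(n) < p_sub)
    n_subs <- length(hit)
    if (n_subs) {
      bases <- c("A", "C", "G", "T")
      for (i in hit) x[i] <- sample(setdiff(bases, x[i]), 1L)
    }
  }
  n_ind <- 0L
  if (noncoding && indel_rate > 0 && p_sub > 0 && n > 0L) {
    n_ind <- stats::rpois(1L, indel_rate * p_sub * n)
    for (e in seq_len(n_ind)) {
      l <- 1L + stats::rgeom(1L, prob = 1 / indel_mean_len)
      if (stats::runif(1) < 0.5 && length(x) > l + 1L) {       # deletion
        q <- sample.int(length(x) - l, 1L)
        keep <- setdiff(seq_along(x), q:(q + l - 1L))
        x <- x[keep]; map <- map[keep]
      } else {                                                  # insertion
        q <- sample.int(length(x), 1L)
        ins <- sample(c("A", "C", "G", "T"), l, replace = TRUE)
        x <- append(x, ins, after = q)
        map <- append(map, rep(NA_integer_, l), after = q)
      }
    }
  }
  list(child = paste(x, collapse = ""), map = map,
       n_subs = n_subs, n_indels = n_ind)
}

#' Simulate an annotated plastome set on a known tree
#'
#' Builds the root genome from the plan (AT-biased random sequence per region,
#' planted repeats written in, IRa appended as the exact reverse complement
#' of the IRb block), evolves every region independently down the tree with
#' its class multiplier (indels only in introns and spacers), re-mirrors the
#' IR after every branch when copy correction is on, and assembles one
#' annotated genome per leaf together with a ground-truth manifest.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, writes one GenBank file
#'   per leaf, a FASTA of the genomes, the true tree (Newick) and a
#'   plain-text manifest summary.
#' @return List of class `sim_result`: `genomes` (named list of
#'   [plastome]s) and `truth` (list: `true_tree`, `species_of`,
#'   `region_rates`, `hotspot_regions`, `planted_repeats`, `ir_intervals`,
#'   `region_maps` (per leaf, per region map to root coordinates),
#'   `root_genome`, `seed`).
#' @export
simulate_plastome_set <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  plan <- config$genome_plan
  tree <- config$tree
  mult <- config$rate_classes[plan$rate_class]
  noncoding <- plan$kind %in% c("intron", "spacer")

  # --- root ------------------------------------------------------------------
  root_seqs <- lapply(plan$length, random_dna, at = config$at_content)
  names(root_seqs) <- plan$name
  planted <- tibble::tibble(category = character(), copy1_start = integer(),
                            copy1_end = integer(), copy2_start = integer(),
                            copy2_end = integer(), length = integer(),
                            identity = numeric())
  if (!is.null(config$planted_repeats)) {
    pr <- plant_repeats(root_seqs, plan, config$planted_repeats)
    root_seqs <- pr$seqs
    planted <- pr$truth
  }

  # --- evolve down the tree --------------------------------------------------
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  seq_state <- vector("list", nnode)
  map_state <- vector("list", nnode)
  seq_state[[root]] <- root_seqs
  map_state[[root]] <- lapply(plan$length, seq_len)
  edges <- tree$edge
  preorder <- rev(ape::postorder(tree))
  for (e in preorder) {
    u <- edges[e, 1]; v <- edges[e, 2]
    b <- tree$edge.length[e]
    pseqs <- seq_state[[u]]; pmaps <- map_state[[u]]
    cseqs <- pseqs; cmaps <- pmaps
    for (r in seq_along(pseqs)) {
      ev <- evolve_sequence(pseqs[[r]], b, mult[r], noncoding = noncoding[r],
                            indel_rate = config$indel_rate,
                            indel_mean_len = config$indel_mean_len)
      cseqs[[r]] <- ev$child
      cmaps[[r]] <- pmaps[[r]][ev$map]
    }
    seq_state[[v]] <- cseqs
    map_state[[v]] <- cmaps
  }

  # --- assemble leaves -------------------------------------------------------
  genomes <- list()
  ir_intervals <- list()
  region_maps <- list()
  for (i in seq_len(ntip)) {
    leaf <- tree$tip.label[i]
    g <- assemble_genome(leaf, config$species_of[[leaf]], plan,
                         seq_state[[i]], config$ir_copy_correction,
                         config, i)
    genomes[[leaf]] <- g$genome
    ir_intervals[[leaf]] <- g$partition
    region_maps[[leaf]] <- map_state[[i]]
  }
  root_genome <- assemble_genome("root", "root", plan, root_seqs,
                                 config$ir_copy_correction, config, 0L)$genome

  hot <- names(which(config$rate_classes == max(config$rate_classes)))
  truth <- list(true_tree = tree,
                species_of = config$species_of,
                region_rates = setNames(as.numeric(mult), plan$name),
                hotspot_regions = plan$name[plan$rate_class %in% hot],
                planted_repeats = planted,
                ir_intervals = ir_intervals,
                region_maps = region_maps,
                region_names = plan$name,
                root_genome = root_genome,
                seed = config$seed)
  res <- structure(list(genomes = genomes, truth = truth), class = "sim_result")
  if (!is.null(out_dir)) write_sim_result(res, out_dir)
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d genomes of ~%s bp; %d hotspot region(s); seed %d\n",
              length(x$genomes),
              format(x$genomes[[1]]$length, big.mark = ","),
              length(x$truth$hotspot_regions), x$truth$seed))
  invisible(x)
}

# overwrite planted repeat copies into the root region sequences
plant_repeats <- function(seqs, plan, spec) {
  spec <- tibble::as_tibble(spec)
  truth <- list()
  offsets <- cumsum(c(0L, plan$length))[seq_len(nrow(plan))]  # root coords
  names(offsets) <- plan$name
  put <- function(region, at, motif) {
    s <- seqs[[region]]
    substr(s, at + 1L, at + nchar(motif)) <- motif
    seqs[[region]] <<- s
    offsets[[region]] + at                                   # 0-based genome
  }
  for (i in seq_len(nrow(spec))) {
    L <- spec$length[i]
    motif <- random_dna(L)
    copy2 <- degrade_copy(motif, spec$identity[i])
    hosts <- strsplit(spec$host[i], "|", fixed = TRUE)[[1]]
    if (spec$category[i] == "tandem") {
      a <- put(hosts[1], 10L, motif)
      b <- put(hosts[1], 10L + L, copy2)
    } else if (spec$category[i] == "palindromic") {
      a <- put(hosts[1], 10L, motif)
      b <- put(hosts[1], 10L + L + 60L, revcomp(copy2))
    } else if (spec$category[i] == "dispersed") {
      a <- put(hosts[1], 20L, motif)
      b <- put(hosts[2], 20L, copy2)
    } else {  # gene_similarity
      a <- put(hosts[1], 30L, motif)
      b <- put(hosts[2], 30L, copy2)
    }
    truth[[i]] <- tibble::tibble(category = spec$category[i],
                                 copy1_start = a, copy1_end = a + L,
                                 copy2_start = b, copy2_end = b + L,
                                 length = L, identity = spec$identity[i])
  }
  list(seqs = seqs, truth = dplyr::bind_rows(truth))
}

# mutate round((1-identity)*L) positions of a copy: the first 15 bases stay
# exact (a seed for detection) and mismatches fall every 9th base after it,
# leaving 8-base exact runs that extension can chain across
degrade_copy <- function(motif, identity) {
  L <- nchar(motif)
  nmut <- round((1 - identity) * L)
  if (nmut == 0L) return(motif)
  x <- chars(motif)
  pos <- seq(16L, by = 9L, length.out = nmut)
  pos <- pos[pos <= L]
  for (p in pos) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
  paste(x, collapse = "")
}

# build one annotated plastome from evolved region sequences
assemble_genome <- function(id, species, plan, seqs, ir_correct, config, tip_index) {
  parts <- c("LSC", "IRb", "SSC")
  part_seq <- function(p) paste(unlist(seqs[plan$part == p]), collapse = "")
  lsc <- part_seq("LSC"); irb <- part_seq("IRb"); ssc <- part_seq("SSC")
  # boundary identifiability guard: if the first SSC base complements the
  # last SSC base, the maximal inverted duplication would genuinely extend
  # one base past the planted junction; nudge the first SSC base so the
  # planted boundaries remain the maximal ones
  first_ssc <- substr(ssc, 1L, 1L)
  last_ssc <- substr(ssc, nchar(ssc), nchar(ssc))
  if (first_ssc == chartr("ACGT", "TGCA", last_ssc)) {
    repl <- if (chartr("ACGT", "TGCA", last_ssc) == "A") "C" else "A"
    ssc_rows <- which(plan$part == "SSC")
    s1 <- seqs[[ssc_rows[1]]]
    substr(s1, 1L, 1L) <- repl
    seqs[[ssc_rows[1]]] <- s1
    ssc <- part_seq("SSC")
  }
  ira <- revcomp(irb)
  genome_seq <- paste0(lsc, irb, ssc, ira)
  # region coordinates in genome order
  lens <- unname(vapply(seqs, nchar, 0L))
  ord <- order(match(plan$part, parts))           # plan is already in order
  starts <- cumsum(c(0L, lens[ord]))[seq_along(ord)]
  reg_start <- integer(nrow(plan)); reg_start[ord] <- starts
  features <- build_features(plan, reg_start, lens,
                             nchar(lsc), nchar(irb), nchar(ssc))
  g <- plastome(id, genome_seq, features, species = species, individual = id)
  n <- g$length
  iv <- function(s, e) { m <- cbind(start = s, end = e); m }
  part <- structure(list(lsc = iv(0L, nchar(lsc)),
                         irb = iv(nchar(lsc), nchar(lsc) + nchar(irb)),
                         ssc = iv(nchar(lsc) + nchar(irb), n - nchar(ira)),
                         ira = iv(n - nchar(ira), n),
                         ir_length = nchar(irb), no_ir = FALSE,
                         genome_length = n),
                    class = "quadripartite")
  list(genome = g, partition = part)
}

# gene/CDS/tRNA/rRNA/pseudogene features for the plan rows, plus the IRa
# mirror copies of every IRb gene
build_features <- function(plan, reg_start, lens, lsc_len, irb_len, ssc_len) {
  rows <- list(); fid <- 0L
  genes <- unique(plan$gene[!is.na(plan$gene)])
  n <- lsc_len + irb_len + ssc_len + irb_len
  for (gn in genes) {
    sel <- which(plan$gene == gn)
    exons <- sel[plan$kind[sel] == "exon"]
    s <- reg_start[exons]; e <- reg_start[exons] + lens[exons]
    gkind <- plan$gkind[sel[1]]
    strand <- plan$strand[sel[1]]
    fid <- fid + 1L
    if (gkind == "pseudogene") {
      rows[[length(rows) + 1L]] <- tibble::tibble(feature_id = fid, name = gn,
                                                  kind = "pseudogene",
                                                  start = s, end = e, strand = strand)
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(feature_id = fid, name = gn,
                                                  kind = "gene",
                                                  start = s, end = e, strand = strand)
      fid <- fid + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(feature_id = fid, name = gn,
                                                  kind = gkind,
                                                  start = s, end = e, strand = strand)
    }
    # IRa mirror copy: IRb offset o maps to IRa offset irb_len - 1 - o
    if (plan$part[sel[1]] == "IRb") {
      irb_start <- lsc_len
      ira_start <- lsc_len + irb_len + ssc_len
      m_start <- sort(ira_start + irb_len - (e - irb_start))
      m_end <- sort(ira_start + irb_len - (s - irb_start))
      mstrand <- if (strand == "+") "-" else "+"
      fid <- fid + 1L
      if (gkind == "pseudogene") {
        rows[[length(rows) + 1L]] <- tibble::tibble(feature_id = fid, name = gn,
                                                    kind = "pseudogene",
                                                    start = m_start, end = m_end,
                                                    strand = mstrand)
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(feature_id = fid, name = gn,
                                                    kind = "gene",
                                                    start = m_start, end = m_end,
                                                    strand = mstrand)
        fid <- fid + 1L
        rows[[length(rows) + 1L]] <- tibble::tibble(feature_id = fid, name = gn,
                                                    kind = gkind,
                                                    start = m_start, end = m_end,
                                                    strand = mstrand)
      }
    }
  }
  dplyr::bind_rows(rows)
}

write_sim_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(res$genomes))
    write_genbank(res$genomes[[id]], file.path(out_dir, paste0(id, ".gb")))
  write_fasta(setNames(lapply(res$genomes, function(g) g$sequence),
                       names(res$genomes)),
              file.path(out_dir, "genomes.fasta"))
  ape::write.tree(res$truth$true_tree, file.path(out_dir, "true_tree.nwk"))
  manifest <- c(
    sprintf("seed\t%d", res$truth$seed),
    sprintf("n_genomes\t%d", length(res$genomes)),
    sprintf("hotspot_regions\t%s", paste(res$truth$hotspot_regions, collapse = ",")),
    sprintf("species\t%s", paste(sprintf("%s=%s", names(res$truth$species_of),
                                         res$truth$species_of), collapse = ","))
  )
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}

#' Default Cymbidium-like simulation design
#'
#' A desk-scale emulation of the study design behind the package: eight
#' individuals from five species of a slowly evolving orchid genus, each
#' with a quadripartite plastome. The genome is scaled to ~30 kb (scale
#' factor ~0.19 of a typical ~155 kb plastome): LSC ~16 kb, IR ~5 kb (x2),
#' SSC ~4 kb, with ~40 annotated genes (two intron-containing, one
#' pseudogene), three designated hotspot spacers evolving at 10x the coding
#' rate, and five planted repeats covering the four categories. Branch
#' lengths put within-species divergence near 0.004 and between-species
#' divergence near 0.011 in uncorrected p-distance.
#'
#' @param seed Integer seed stored in the config.
#' @return A [simulation_config()].
#' @export
default_cymbidium_like_plan <- function(seed = 1L) {
  tree <- paste0(
    "(((CtorA:0.0019,(CtorB:0.0015,CtorC:0.0015):0.0006):0.0025,",
    "(CmanA:0.0019,CmanB:0.0019):0.0025):0.0012,",
    "(Csin1:0.0034,Cgoe1:0.0034):0.0012,Ctra1:0.0052);")
  species_of <- c(CtorA = "C_tortisepalum", CtorB = "C_tortisepalum",
                  CtorC = "C_tortisepalum", CmanA = "C_mannii",
                  CmanB = "C_mannii", Csin1 = "C_sinense",
                  Cgoe1 = "C_goeringii", Ctra1 = "C_tracyanum")
  gene_row <- function(name, len, gkind = "CDS", strand = "+", part = "LSC") {
    tibble::tibble(name = name, kind = "exon", length = len,
                   rate_class = "coding", part = part, gene = name,
                   gkind = gkind, strand = strand)
  }
  spacer_row <- function(a, b, len, part = "LSC", rate = "spacer") {
    tibble::tibble(name = paste0(a, "-", b), kind = "spacer", length = len,
                   rate_class = rate, part = part, gene = NA_character_,
                   gkind = NA_character_, strand = "+")
  }
  intron_gene <- function(gname, exon_lens, intron_lens, gkind = "CDS",
                          strand = "+", part = "LSC") {
    rows <- list()
    for (e in seq_along(exon_lens)) {
      rows[[length(rows) + 1L]] <-
        tibble::tibble(name = paste0(gname, "-exon", e), kind = "exon",
                       length = exon_lens[e], rate_class = "coding",
                       part = part, gene = gname, gkind = gkind, strand = strand)
      if (e <= length(intron_lens))
        rows[[length(rows) + 1L]] <-
          tibble::tibble(name = paste0(gname, "-intron", e), kind = "intron",
                         length = intron_lens[e], rate_class = "intron",
                         part = part, gene = gname, gkind = gkind, strand = strand)
    }
    dplyr::bind_rows(rows)
  }
  lsc_genes <- c(psbA = 1060, matK = 1520, rps16 = 260, psbK = 190,
                 atpA = 1520, rpoC1 = 2060, rpoB = 3210, petN = 90,
                 psbM = 105, psbD = 1060, psbC = 1420, rps4 = 600,
                 ndhJ = 480, atpB = 1500, rbcL = 1430, accD = 1460,
                 cemA = 690, petA = 960, psbJ = 120, psbE = 250,
                 petL = 95, psbB = 1530, petB = 650, rps19 = 280)
  # scale coding lengths to fit a ~16 kb LSC alongside spacers
  lsc_genes <- round(lsc_genes * 0.5)
  lsc <- list()
  spacer_len <- c(350, 280, 240, 300, 260, 280, 240, 220, 310, 260, 250,
                  280, 240, 300, 260, 280, 420, 380, 240, 260, 280, 240, 260)
  hot_lsc <- c("petA-psbJ", "matK-rps16")
  gnames <- names(lsc_genes)
  for (i in seq_along(gnames)) {
    lsc[[length(lsc) + 1L]] <- gene_row(gnames[i], lsc_genes[[i]],
                                        gkind = if (gnames[i] == "matK") "CDS" else "CDS",
                                        strand = if (i %% 3 == 0) "-" else "+")
    if (i < length(gnames)) {
      nm <- paste0(gnames[i], "-", gnames[i + 1])
      lsc[[length(lsc) + 1L]] <- spacer_row(gnames[i], gnames[i + 1],
                                            spacer_len[i],
                                            rate = if (nm %in% hot_lsc) "hotspot" else "spacer")
    }
  }
  lsc <- dplyr::bind_rows(lsc)
  # two intron-containing genes spliced into the LSC between rbcL and accD
  atpf <- intron_gene("atpF", c(145, 410), 360, strand = "-")
  clpp <- intron_gene("clpP", c(70, 290, 230), c(400, 320))
  pre <- lsc$name == "rbcL-accD"
  at <- which(pre)
  lsc <- dplyr::bind_rows(
    lsc[seq_len(at - 1L), ],
    spacer_row("rbcL", "atpF", 220), atpf,
    spacer_row("atpF", "clpP", 240), clpp,
    spacer_row("clpP", "accD", 230),
    lsc[seq((at + 1L), nrow(lsc)), ])
  irb <- dplyr::bind_rows(
    gene_row("rrn16", 900, gkind = "rRNA", part = "IRb"),
    spacer_row("rrn16", "trnA-UGC", 320, part = "IRb"),
    gene_row("trnA-UGC", 75, gkind = "tRNA", part = "IRb"),
    spacer_row("trnA-UGC", "rrn23", 300, part = "IRb"),
    gene_row("rrn23", 1600, gkind = "rRNA", part = "IRb"),
    spacer_row("rrn23", "ycf15", 350, part = "IRb"),
    gene_row("ycf15", 200, gkind = "pseudogene", part = "IRb"),
    spacer_row("ycf15", "ndhB", 300, part = "IRb"),
    gene_row("ndhB", 740, part = "IRb", strand = "-"))
  ssc <- dplyr::bind_rows(
    gene_row("ndhF", 900, part = "SSC", strand = "-"),
    spacer_row("ndhF", "rpl32", 480, part = "SSC", rate = "hotspot"),
    gene_row("rpl32", 160, part = "SSC"),
    spacer_row("rpl32", "ccsA", 300, part = "SSC"),
    gene_row("ccsA", 580, part = "SSC"),
    spacer_row("ccsA", "ndhD", 260, part = "SSC"),
    gene_row("ndhD", 640, part = "SSC", strand = "-"))
  plan <- dplyr::bind_rows(lsc, irb, ssc)
  planted <- tibble::tibble(
    length = c(32L, 36L, 40L, 40L, 33L),
    identity = c(1.0, 0.94, 1.0, 0.925, 1.0),
    category = c("tandem", "tandem", "palindromic", "dispersed", "gene_similarity"),
    host = c("psbA-matK", "rpoB-petN", "cemA-petA", "rps16-psbK|psbE-petL",
             "rpoC1|rbcL"))
  simulation_config(tree, plan, species_of = species_of,
                    planted_repeats = planted, seed = seed)
}
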