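toy_pair <- function() {
  set.seed(31)
  mk <- function(id) {
    s <- random_dna(400)
    feats <- tibble::tibble(feature_id = 1:2, name = c("g1", "g2"),
                            kind = "gene", start = c(50L, 200L),
                            end = c(150L, 300L), strand = c("+", "-"))
    plastome(id, s, feats)
  }
  list(a = mk("a"), b = mk("b"))
}

test_that("spacers are named by flanking genes and extracted in both genomes", {
  tp <- toy_pair()
  regs <- extract_homologous_regions(tp, "a")
  idx <- regions_index(regs)
  expect_true("g1-g2" %in% idx$region)
  sp <- regs[[which(idx$region == "g1-g2")]]
  expect_equal(sp$kind, "spacer")
  expect_equal(length(sp$sequences), 2L)
  expect_equal(nchar(sp$sequences[["a"]]), 50L)
})

test_that("two-exon genes decompose into exon/intron/exon regions", {
  set.seed(32)
  feats <- tibble::tibble(feature_id = c(1L, 1L), name = "g",
                          kind = "gene", start = c(20L, 120L),
                          end = c(70L, 180L), strand = "+")
  g <- plastome("x", random_dna(300), feats)
  d <- genome_regions(g)
  expect_setequal(d$name[d$kind != "spacer"],
                  c("g-exon1", "g-intron1", "g-exon2"))
  expect_equal(unname(d$start[d$name == "g-intron1"]), 70L)
  expect_equal(unname(d$end[d$name == "g-intron1"]), 120L)
})

test_that("reference regions tile the genome exactly", {
  cfg <- default_cymbidium_like_plan(seed = 6)
  sim <- simulate_plastome_set(cfg)
  g <- sim$genomes[[1]]
  d <- genome_regions(g)
  # order by start, concatenate + strand sequences, compare to the genome
  # rotated so it starts at the first footprint
  d <- d[order(d$start), ]
  pieces <- character(0)
  for (i in seq_len(nrow(d))) {
    r <- d[i, ]
    s <- r$start; e <- r$end
    if (!is.na(r$start2)) { s <- c(s, r$start2); e <- c(e, r$end2) }
    pieces <- c(pieces, extract_subsequence(g, s, e, "+"))
  }
  covered <- sum(nchar(pieces))
  expect_equal(covered, g$length)
  # non-wrapping concatenation reconstructs the sequence from position 0
  no_wrap <- d[is.na(d$start2), ]
  recon <- paste(vapply(seq_len(nrow(no_wrap)), function(i)
    extract_subsequence(g, no_wrap$start[i], no_wrap$end[i], "+"), ""),
    collapse = "")
  wrap <- d[!is.na(d$start2), ]
  if (nrow(wrap)) {
    recon <- paste0(
      substring(g$sequence, 1, wrap$end2),
      recon,
      substring(g$sequence, wrap$start + 1, g$length))
  }
  expect_equal(recon, g$sequence)
})

test_that("the eleven-hotspot-style spacer names appear in the extracted set", {
  cfg <- default_cymbidium_like_plan(seed = 6)
  sim <- simulate_plastome_set(cfg)
  part <- detect_quadripartite(sim$genomes[["CtorA"]])
  regs <- extract_homologous_regions(sim$genomes, "CtorA", partition = part)
  idx <- regions_index(regs)
  expect_true(all(sim$truth$hotspot_regions %in% idx$region))
  expect_true(all(idx$n_sequences[idx$region %in% sim$truth$hotspot_regions] == 8L))
})

test_that("regions inside IRa are dropped so IR content appears once", {
  cfg <- default_cymbidium_like_plan(seed = 6)
  sim <- simulate_plastome_set(cfg)
  g <- sim$genomes[["CtorA"]]
  part <- detect_quadripartite(g)
  regs <- extract_homologous_regions(sim$genomes, "CtorA", partition = part)
  idx <- regions_index(regs)
  expect_equal(sum(idx$region == "rrn16"), 1L)
  ira <- part$ira[1, ]
  expect_true(all(!(idx$reference_start >= ira["start"] &
                      idx$reference_end <= ira["end"])))
})

test_that("center-star picks the documented optimum for the textbook pair", {
  # enumerate the three gap placements of AGT against ACGT at the default
  # scores: -AGT = -13, A-GT = -1, AG-T = -4, AGT- = -13; optimum unique
  a <- align_center_star(c(x = "ACGT", y = "AGT"))
  expect_equal(unname(a$seqs["y"]), "A-GT")
  expect_equal(unname(a$seqs["x"]), "ACGT")
})

test_that("identical sequences align without gaps", {
  a <- align_center_star(c(p = "ACGT", q = "ACGT", r = "ACGT"))
  expect_equal(unname(a$seqs), rep("ACGT", 3))
})

test_that("gaps removed from center-star rows restore the inputs", {
  set.seed(33)
  for (rep in 1:5) {
    base <- random_dna(120)
    seqs <- vapply(1:5, function(i)
      evolve_sequence(base, 0.05, 1, noncoding = TRUE)$child, "")
    names(seqs) <- paste0("s", 1:5)
    a <- align_center_star(seqs)
    expect_equal(gsub("-", "", a$seqs), seqs)
    expect_equal(length(unique(nchar(a$seqs))), 1L)
  }
})

test_that("aligning an empty sequence is an error", {
  expect_error(align_center_star(c(a = "ACGT", b = "")), "empty")
  expect_error(align_center_star(c(a = "ACGT")), ">= 2")
})

test_that("alignment columns recover true homology at low divergence", {
  # simulate sequences with known per-base ancestry down a short star tree
  set.seed(34)
  hits <- 0; tot <- 0
  for (rep in 1:3) {
    root <- random_dna(300)
    leaves <- list(); maps <- list()
    for (i in 1:5) {
      ev <- evolve_sequence(root, 0.03, 1, noncoding = TRUE)
      leaves[[paste0("s", i)]] <- ev$child
      maps[[paste0("s", i)]] <- ev$map
    }
    a <- align_center_star(unlist(leaves))
    m <- do.call(rbind, strsplit(unname(a$seqs), "", fixed = TRUE))
    # per column, the root position each residue descends from
    cum <- apply(m != "-", 1, cumsum)            # columns x rows
    for (col in seq_len(ncol(m))) {
      anc <- integer(0)
      for (row in seq_len(nrow(m))) {
        if (m[row, col] == "-") next
        anc <- c(anc, maps[[row]][cum[col, row]])
      }
      anc <- anc[!is.na(anc)]
      if (length(anc) >= 2) {
        tot <- tot + 1
        if (length(unique(anc)) == 1L) hits <- hits + 1
      }
    }
  }
  expect_gte(hits / tot, 0.95)
})
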