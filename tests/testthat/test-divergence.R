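test_that("site classification follows the parsimony definitions", {
  aln <- dna_alignment(c(a = "AAAA", b = "AAA-", c = "GAGA", d = "GAGN"))
  sc <- classify_sites(aln)
  # col1 A,A,G,G -> PI; col2 all A -> constant; col3 A,A,G,G -> PI;
  # col4 A,-,A,N -> constant (gap/N excluded)
  expect_equal(as.character(sc$labels),
               c("parsimony_informative", "constant", "parsimony_informative",
                 "constant"))
  expect_equal(sc$aligned_length, 4L)
  expect_equal(sc$analysed_length, 4L)
  expect_equal(sum(sc$counts), sc$aligned_length)
  aln2 <- dna_alignment(c(a = "AG", b = "AG", c = "AG", d = "GG"))
  expect_equal(as.character(classify_sites(aln2)$labels)[1], "variable_singleton")
  expect_error(classify_sites(dna_alignment(c(a = "ACGT"))), ">= 2")
})

test_that("gap-only columns are classified as such", {
  aln <- dna_alignment(c(a = "-A", b = "-A", c = "NA"))
  expect_equal(as.character(classify_sites(aln)$labels)[1], "gap_or_missing_only")
  expect_equal(classify_sites(aln)$analysed_length, 1L)
})

test_that("PIC fraction uses the aligned length as denominator", {
  aln <- dna_alignment(c(a = "AAT", b = "AAT", c = "AAG", d = "AAG"))
  p <- pic_fraction(aln)
  expect_equal(p$pic_fraction, 1 / 3)
  expect_equal(p$pi_sites, 1L)
  expect_equal(p$variable_sites, 1L)
  same <- dna_alignment(c(a = "ACGT", b = "ACGT"))
  expect_equal(pic_fraction(same)$pic_fraction, 0)
  # gapped column still counts in the denominator
  gap <- dna_alignment(c(a = "AA-T", b = "AA-T", c = "GA-T", d = "GA-T"))
  expect_equal(pic_fraction(gap)$pic_fraction, 1 / 4)
  expect_equal(pic_fraction(gap)$pic_fraction_analysed, 1 / 3)
})

test_that("p-distance matches hand-computed examples", {
  d <- p_distance_matrix(dna_alignment(c(x = "ACGT", y = "ACGA")))
  expect_equal(unname(d$values["x", "y"]), 0.25)
  d2 <- p_distance_matrix(dna_alignment(c(x = "AC-T", y = "ACGT")))
  expect_equal(unname(d2$values["x", "y"]), 0)
  expect_equal(d2$sites_used, 3L)
  pw <- p_distance_matrix(dna_alignment(c(x = "AC-T", y = "ACGT", z = "GCGT")),
                          deletion = "pairwise")
  expect_equal(unname(pw$sites_used["x", "y"]), 3L)
  expect_equal(unname(pw$sites_used["y", "z"]), 4L)
  expect_error(p_distance_matrix(dna_alignment(c(x = "--", y = "AC"))),
               "no comparable sites")
})

test_that("p-distance is symmetric with zero diagonal and row-order invariant", {
  set.seed(41)
  aln <- random_alignment(5, 60, gap_frac = 0.05)
  d <- p_distance_matrix(aln)
  expect_equal(d$values, t(d$values))
  expect_true(all(diag(d$values) == 0))
  perm <- sample(length(aln$ids))
  aln2 <- dna_alignment(aln$seqs[perm])
  d2 <- p_distance_matrix(aln2)
  expect_equal(d2$values[aln$ids, aln$ids], d$values)
})

test_that("divergence summary splits means by species", {
  d <- p_distance_matrix(dna_alignment(c(x = strrep("A", 10),
                                         y = paste0(strrep("A", 9), "G"))))
  s <- divergence_summary(d, c(x = "sp1", y = "sp2"))
  expect_equal(s$mean_all, 0.1)
  expect_equal(s$mean_between_species, 0.1)
  expect_true(is.na(s$mean_within_species))
  # 4 taxa in 2 species: within pairs identical, between pairs at 0.2
  rows <- c(a1 = strrep("A", 10), a2 = strrep("A", 10),
            b1 = paste0(strrep("G", 2), strrep("A", 8)),
            b2 = paste0(strrep("G", 2), strrep("A", 8)))
  s2 <- divergence_summary(p_distance_matrix(dna_alignment(rows)),
                           c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_equal(s2$mean_within_species, 0)
  expect_equal(s2$mean_between_species, 0.2)
})

test_that("mean p-distance rises monotonically with the rate multiplier", {
  tree <- "((A:0.02,B:0.02):0.01,(C:0.02,D:0.02):0.01,(E:0.02,F:0.02):0.01);"
  means <- vapply(seq_along(c(0.5, 1, 2, 4, 8)), function(i) {
    m <- c(0.5, 1, 2, 4, 8)[i]
    aln <- sim_alignment_on_tree(tree, 2000, multiplier = m, seed = 100 + i)
    mean(p_distance_matrix(aln)$values[upper.tri(diag(6))])
  }, 0)
  expect_equal(cor(means, c(0.5, 1, 2, 4, 8), method = "spearman"), 1)
})

test_that("hotspot spacers outrank background spacers in PIC across replicates", {
  tree <- ape::read.tree(text = paste0(
    "(((A:0.002,B:0.002):0.003,(C:0.002,D:0.002):0.003):0.001,",
    "(E:0.004,F:0.004):0.001,G:0.006);"))
  wins <- 0L
  for (rep in 1:10) {
    hot <- pic_fraction(sim_alignment_on_tree(tree, 400, multiplier = 10,
                                              seed = 500 + rep))$pic_fraction
    bg <- vapply(1:5, function(j)
      pic_fraction(sim_alignment_on_tree(tree, 400, multiplier = 1.5,
                                         seed = 600 + 10 * rep + j))$pic_fraction, 0)
    if (hot > max(bg)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("within-species divergence stays below between-species divergence", {
  for (seed in 7:9) {
    cfg <- default_cymbidium_like_plan(seed = seed)
    sim <- simulate_plastome_set(cfg)
    # exon regions are indel-free: concatenate directly for a quick distance
    part <- detect_quadripartite(sim$genomes[[1]])
    regs <- extract_homologous_regions(sim$genomes, "CtorA", partition = part)
    ex <- purrr::keep(regs, function(r)
      r$kind == "exon" && length(r$sequences) == 8 &&
        length(unique(nchar(r$sequences))) == 1)
    aln <- concat_alignments(lapply(ex, function(r) dna_alignment(r$sequences)),
                             ids = names(sim$genomes))
    s <- divergence_summary(p_distance_matrix(aln), sim$truth$species_of)
    expect_lt(s$mean_within_species, s$mean_between_species)
  }
})
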