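planted_quadripartite <- function(seed, lsc = 5000L, ir = 800L, ssc = 1200L) {
  set.seed(seed)
  l <- random_dna(lsc); b <- random_dna(ir); s <- random_dna(ssc)
  # keep the planted SSC boundaries maximal (first SSC base must not pair
  # with the last SSC base under the IR extension)
  if (substr(s, 1, 1) == chartr("ACGT", "TGCA", substr(s, ssc, ssc)))
    substr(s, 1, 1) <- if (chartr("ACGT", "TGCA", substr(s, ssc, ssc)) == "A") "C" else "A"
  plastome(paste0("q", seed), paste0(l, b, s, plastomics:::revcomp(b)))
}

test_that("planted quadripartite boundaries are recovered exactly", {
  for (seed in 1:5) {
    g <- planted_quadripartite(seed)
    p <- detect_quadripartite(g, min_ir = 500)
    expect_false(p$no_ir)
    expect_equal(p$ir_length, 800L)
    expect_equal(unname(p$lsc[1, ]), c(0L, 5000L))
    expect_equal(unname(p$irb[1, ]), c(5000L, 5800L))
    expect_equal(unname(p$ssc[1, ]), c(5800L, 7000L))
    expect_equal(unname(p$ira[1, ]), c(7000L, 7800L))
    # tiling: region lengths sum to the genome length
    lens <- sum(p$lsc[, 2] - p$lsc[, 1]) + sum(p$irb[, 2] - p$irb[, 1]) +
      sum(p$ssc[, 2] - p$ssc[, 1]) + sum(p$ira[, 2] - p$ira[, 1])
    expect_equal(lens, g$length)
  }
})

test_that("random sequence without duplication reports no IR", {
  set.seed(99)
  g <- plastome("r", random_dna(10000))
  p <- detect_quadripartite(g)
  expect_true(p$no_ir)
  expect_equal(p$ir_length, 0L)
})

test_that("LSC is the longer single-copy region by definition", {
  # swap the single-copy lengths: the short stretch between the copies must
  # become the SSC regardless of position
  set.seed(12)
  l <- random_dna(1200); b <- random_dna(800); s <- random_dna(5000)
  g <- plastome("sw", paste0(l, b, s, plastomics:::revcomp(b)))
  p <- detect_quadripartite(g, min_ir = 500)
  lsc_len <- sum(p$lsc[, 2] - p$lsc[, 1])
  ssc_len <- sum(p$ssc[, 2] - p$ssc[, 1])
  expect_gt(lsc_len, ssc_len)
  # the maximal duplication may absorb a base of chance complementarity at
  # the inner boundary; the length is recovered to within a couple of bases
  expect_gte(lsc_len, 4996L)
  expect_lte(lsc_len, 5000L)
})

guard_ssc <- function(ssc) {
  n <- nchar(ssc)
  if (substr(ssc, 1, 1) == chartr("ACGT", "TGCA", substr(ssc, n, n)))
    substr(ssc, 1, 1) <- if (chartr("ACGT", "TGCA", substr(ssc, n, n)) == "A") "C" else "A"
  ssc
}

test_that("junctions report spanning and nearest features with offsets", {
  set.seed(5)
  lsc <- random_dna(3000); irb <- random_dna(1200); ssc <- guard_ssc(random_dna(800))
  g <- plastome("j", paste0(lsc, irb, ssc, plastomics:::revcomp(irb)),
                tibble::tibble(feature_id = c(1L, 2L),
                               name = c("rps19", "ndhF"), kind = "gene",
                               start = c(2950L, 4250L), end = c(3080L, 4400L),
                               strand = "+"))
  p <- detect_quadripartite(g, min_ir = 500)
  jr <- junction_report(g, p)
  expect_equal(nrow(jr), 4L)
  lscirb <- jr[jr$junction == "LSC/IRb", ]
  expect_true(lscirb$spans)
  expect_equal(lscirb$gene, "rps19")
  expect_equal(lscirb$offset, 3000L - 2950L)
  irbssc <- jr[jr$junction == "IRb/SSC", ]
  expect_false(irbssc$spans)
  expect_equal(irbssc$gene, "ndhF")
  expect_equal(irbssc$offset, -50L)    # gene starts 50 bp downstream
})

test_that("overlapping features across a junction are reported together", {
  set.seed(6)
  lsc <- random_dna(3000); irb <- random_dna(1200); ssc <- random_dna(800)
  feats <- tibble::tibble(feature_id = c(1L, 2L),
                          name = c("ycf1", "ndhF"),
                          kind = c("pseudogene", "gene"),
                          start = c(4100L, 4150L), end = c(4260L, 4900L),
                          strand = c("+", "-"))
  g <- plastome("ov", paste0(lsc, irb, ssc, plastomics:::revcomp(irb)), feats)
  p <- detect_quadripartite(g, min_ir = 500)
  jr <- junction_report(g, p)
  irbssc <- jr[jr$junction == "IRb/SSC", ]   # junction at 4200
  expect_true(irbssc$spans)
  expect_equal(irbssc$overlapping, "ycf1,ndhF")
})

test_that("genomes without features yield placeholder junction records", {
  g <- planted_quadripartite(3)
  jr <- junction_report(g, detect_quadripartite(g, min_ir = 500))
  expect_equal(nrow(jr), 4L)
  expect_true(all(is.na(jr$gene)))
  expect_true(all(!jr$spans))
})

test_that("composition statistics follow their definitions", {
  g <- plastome("at", "ATAT")
  expect_equal(composition_stats(g)$at_fraction, 1.0)
  feats <- tibble::tibble(feature_id = c(1L, 2L), name = c("g1", "g1"),
                          kind = c("gene", "CDS"), start = c(10L, 10L),
                          end = c(40L, 40L), strand = "+")
  set.seed(1)
  g2 <- plastome("c", random_dna(100), feats)
  cs <- composition_stats(g2)
  expect_equal(cs$coding_fraction, 0.30)
  expect_equal(cs$protein_fraction, 0.30)
  expect_equal(cs$unique_genes, 1L)
  expect_equal(cs$duplicated_genes, 0L)
})

test_that("IR-duplicated genes count once as unique and once as duplicated", {
  feats <- tibble::tibble(
    feature_id = 1:3,
    name = c("rrn16", "rrn16", "psbA"),
    kind = "gene",
    start = c(100L, 800L, 400L), end = c(200L, 900L, 500L),
    strand = c("+", "-", "+"))
  set.seed(2)
  g <- plastome("d", random_dna(1000), feats)
  cs <- composition_stats(g)
  expect_equal(cs$unique_genes, 2L)
  expect_equal(cs$duplicated_genes, 1L)
})

test_that("composition fractions are invariant under genome rotation", {
  cfg <- default_cymbidium_like_plan(seed = 3)
  sim <- simulate_plastome_set(cfg)
  g <- sim$genomes[[1]]
  rot <- 1234L
  g2 <- plastome("rot",
                 paste0(substring(g$sequence, rot + 1L),
                        substring(g$sequence, 1L, rot)))
  expect_equal(composition_stats(g2)$at_fraction,
               composition_stats(g)$at_fraction)
})

test_that("planted gene-order inversions are found as single blocks", {
  mk <- function(id, names, strands) {
    plastome(id, strrep("A", 1000),
             tibble::tibble(feature_id = seq_along(names), name = names,
                            kind = "gene",
                            start = seq(0L, by = 100L, length.out = length(names)),
                            end = seq(50L, by = 100L, length.out = length(names)),
                            strand = strands))
  }
  a <- mk("a", c("g1", "g2", "g3", "g4"), rep("+", 4))
  b <- mk("b", c("g1", "g3", "g2", "g4"), c("+", "-", "-", "+"))
  inv <- gene_order_inversions(a, b)
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$genes, "g2,g3")
  expect_equal(inv$length, 2L)
  expect_equal(nrow(gene_order_inversions(a, a)), 0L)
})

test_that("a petN/psbM-style inversion is the only block between two gene orders", {
  # brute-force expectation: the permutations differ only in that segment
  order_a <- c("psbD", "petN", "psbM", "trnD", "rps4")
  strand_a <- c("+", "+", "+", "+", "-")
  order_b <- c("psbD", "psbM", "petN", "trnD", "rps4")
  strand_b <- c("+", "-", "-", "+", "-")
  mk <- function(id, names, strands) {
    plastome(id, strrep("A", 1000),
             tibble::tibble(feature_id = seq_along(names), name = names,
                            kind = "gene",
                            start = seq(0L, by = 150L, length.out = length(names)),
                            end = seq(80L, by = 150L, length.out = length(names)),
                            strand = strands))
  }
  inv <- gene_order_inversions(mk("a", order_a, strand_a),
                               mk("b", order_b, strand_b))
  expect_equal(nrow(inv), 1L)
  expect_setequal(strsplit(inv$genes, ",")[[1]], c("petN", "psbM"))
})
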