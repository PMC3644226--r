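test_that("planted exact direct repeats are found with identity 1", {
  set.seed(7)
  s <- random_dna(2000)
  motif <- random_dna(40)
  s <- overwrite_at(s, 100, motif)
  s <- overwrite_at(s, 900, motif)
  h <- find_repeat_pairs(plastome("d", s))
  expect_equal(nrow(h), 1L)
  expect_equal(h$orientation, "direct")
  expect_equal(h$identity, 1.0)
  # the hit covers the planted copies (chance flanking matches may extend
  # the contiguous run by a base or two)
  expect_lte(h$copy1_start, 100L); expect_gte(h$copy1_end, 140L)
  expect_lte(h$copy2_start, 900L); expect_gte(h$copy2_end, 940L)
})

test_that("planted inverted repeats are found", {
  set.seed(8)
  s <- random_dna(2000)
  motif <- random_dna(35)
  s <- overwrite_at(s, 200, motif)
  s <- overwrite_at(s, 735, plastomics:::revcomp(motif))
  h <- find_repeat_pairs(plastome("i", s))
  expect_equal(nrow(h), 1L)
  expect_equal(h$orientation, "inverted")
  expect_lte(h$copy1_start, 200L); expect_gte(h$copy1_end, 235L)
})

test_that("degraded copies are reported above but not below the identity floor", {
  set.seed(9)
  s <- random_dna(2000)
  motif <- random_dna(40)
  # 3 mismatches clustered at the front: identity 0.925, a long exact seed
  # and >= 8-base runs to chain across
  mism <- plastomics:::chars(motif)
  for (p in c(2, 4, 25)) mism[p] <- setdiff(c("A", "C", "G", "T"), mism[p])[1]
  s <- overwrite_at(s, 300, motif)
  s <- overwrite_at(s, 1300, paste(mism, collapse = ""))
  h <- find_repeat_pairs(plastome("deg", s))
  expect_equal(nrow(h), 1L)
  expect_gte(h$identity, 0.90)
  # 5 mismatches spread every 7 bases: identity 0.875 and no 15-mer seed
  set.seed(10)
  s2 <- random_dna(2000)
  motif2 <- random_dna(40)
  mism2 <- plastomics:::chars(motif2)
  for (p in c(3, 10, 17, 24, 31)) mism2[p] <- setdiff(c("A", "C", "G", "T"), mism2[p])[1]
  s2 <- overwrite_at(s2, 300, motif2)
  s2 <- overwrite_at(s2, 1300, paste(mism2, collapse = ""))
  h2 <- find_repeat_pairs(plastome("deg2", s2))
  expect_equal(nrow(h2), 0L)
})

test_that("find_repeat_pairs agrees with the brute-force oracle", {
  for (seed in 1:4) {
    set.seed(seed * 101)
    s <- random_dna(1500)
    m1 <- random_dna(40); m2 <- random_dna(32); m3 <- random_dna(36)
    s <- overwrite_at(s, 100, m1); s <- overwrite_at(s, 700, m1)
    s <- overwrite_at(s, 300, m2); s <- overwrite_at(s, 332, m2)   # tandem
    s <- overwrite_at(s, 1000, m3)
    s <- overwrite_at(s, 1200, plastomics:::revcomp(m3))
    got <- as.data.frame(find_repeat_pairs(plastome(paste0("bf", seed), s)))
    want <- brute_force_repeats(s)
    rownames(got) <- NULL
    expect_equal(got, want)
  }
})

test_that("no repeats are reported in clean random controls", {
  set.seed(1234)
  s <- random_dna(2000)
  want <- brute_force_repeats(s)
  got <- find_repeat_pairs(plastome("ctrl", s))
  expect_equal(nrow(got), nrow(want))
  expect_equal(nrow(got), 0L)
})

test_that("the whole IR duplication and IRa images are excluded", {
  set.seed(21)
  lsc <- random_dna(6000); irb <- random_dna(1500); ssc <- random_dna(1500)
  motif <- random_dna(40)
  lsc <- overwrite_at(lsc, 500, motif)
  irb <- overwrite_at(irb, 200, motif)       # repeat LSC vs IRb (+ image in IRa)
  g <- plastome("ir", paste0(lsc, irb, ssc, plastomics:::revcomp(irb)))
  h <- find_repeat_pairs(g)
  # the only reported hit pairs the LSC copy with the IRb instance
  expect_equal(nrow(h), 1L)
  expect_true(all(h$copy2_end <= 7500))      # nothing into IRa
  expect_equal(h$orientation, "direct")
})

test_that("tandem has priority over dispersed and palindrome gap is 3 kb", {
  set.seed(11)
  s <- random_dna(9000)
  m1 <- random_dna(40)
  s <- overwrite_at(s, 500, m1); s <- overwrite_at(s, 540, m1)       # gap 0
  m2 <- random_dna(40)
  s <- overwrite_at(s, 1200, m2)
  s <- overwrite_at(s, 1300, plastomics:::revcomp(m2))               # gap 60
  m3 <- random_dna(40)
  s <- overwrite_at(s, 2000, m3)
  s <- overwrite_at(s, 5540, plastomics:::revcomp(m3))               # gap 3500
  g <- plastome("cls", s)
  cl <- classify_repeats(find_repeat_pairs(g), g)
  cats <- cl$category[order(cl$copy1_start)]
  expect_equal(cats, c("tandem", "palindromic", "dispersed"))
  # the > 3 kb inverted pair keeps its inverted orientation in the table
  expect_equal(cl$orientation[order(cl$copy1_start)][3], "inverted")
})

test_that("copies inside two distinct genes classify as gene similarity", {
  set.seed(12)
  s <- random_dna(3000)
  m <- random_dna(40)
  s <- overwrite_at(s, 520, m)
  s <- overwrite_at(s, 1520, m)
  feats <- tibble::tibble(feature_id = 1:2, name = c("rpoC2", "rps3"),
                          kind = "gene", start = c(500L, 1500L),
                          end = c(700L, 1700L), strand = "+")
  g <- plastome("gs", s, feats)
  cl <- classify_repeats(find_repeat_pairs(g), g)
  expect_equal(cl$category, "gene_similarity")
  expect_equal(cl$genes_hit, "rpoC2,rps3")
})

test_that("merged motifs do not overlap and summaries report fractions", {
  set.seed(13)
  s <- random_dna(4000)
  m <- random_dna(40)
  for (at in c(500, 540, 1200, 2000, 2600, 3100)) s <- overwrite_at(s, at, m)
  g <- plastome("mg", s)
  cl <- classify_repeats(find_repeat_pairs(g), g)
  if (nrow(cl) > 1) {
    iv <- cl[order(cl$copy1_start), ]
    for (i in seq_len(nrow(iv) - 1L))
      expect_lte(iv$copy1_end[i], iv$copy1_start[i + 1L] + 2L)
  }
  sm <- repeat_summary(cl)
  expect_equal(sum(sm$by_category$n), sm$total)
  expect_equal(sum(sm$by_category$fraction), 1)
  fake <- tibble::tibble(category = c(rep("tandem", 4), rep("dispersed", 6)),
                         length = 30L)
  sm2 <- repeat_summary(fake)
  expect_equal(sm2$by_category$fraction[sm2$by_category$category == "tandem"], 0.4)
  empty <- repeat_summary(fake[0, ])
  expect_equal(empty$total, 0L)
})

test_that("planted repeats in the default simulation are recovered on the root genome", {
  cfg <- default_cymbidium_like_plan(seed = 5)
  sim <- simulate_plastome_set(cfg)
  truth <- sim$truth$planted_repeats
  h <- find_repeat_pairs(sim$truth$root_genome)
  overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))
  for (i in seq_len(nrow(truth))) {
    # a reported hit must cover most of each planted copy (degraded copies
    # may lose a short tail beyond the last chainable run)
    ov <- overlap_len(h$copy1_start, h$copy1_end,
                      truth$copy1_start[i], truth$copy1_end[i]) +
      overlap_len(h$copy2_start, h$copy2_end,
                  truth$copy2_start[i], truth$copy2_end[i])
    expect_true(any(ov >= 1.5 * truth$length[i]),
                label = sprintf("planted %s repeat recovered", truth$category[i]))
  }
  cl <- classify_repeats(h, sim$truth$root_genome)
  expect_setequal(unique(cl$category),
                  c("tandem", "palindromic", "dispersed", "gene_similarity"))
})
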