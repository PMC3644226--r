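test_that("Fitch length matches textbook single-column cases", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_length(t1, dna_alignment(c(A = "A", B = "A", C = "G", D = "G"))), 1)
  expect_equal(fitch_length(t1, dna_alignment(c(A = "A", B = "G", C = "A", D = "G"))), 2)
  # gap treated as missing never adds steps
  expect_equal(fitch_length(t1, dna_alignment(c(A = "A", B = "-", C = "A", D = "N"))), 0)
  expect_error(fitch_length(t1, dna_alignment(c(A = "A", B = "A", C = "G", X = "G"))),
               "match")
})

test_that("Fitch length equals the uniform-cost Sankoff oracle", {
  set.seed(77)
  for (i in 1:12) {
    n <- sample(4:7, 1)
    tree <- ape::rtree(n, rooted = FALSE, tip.label = paste0("t", 1:n))
    aln <- random_alignment(n, 12, gap_frac = 0.1)
    expect_equal(fitch_length(tree, aln), sankoff_length(tree, aln),
                 label = sprintf("instance %d", i))
  }
})

test_that("Fitch length is invariant under rerooting and leaf order", {
  set.seed(78)
  tree <- ape::rtree(6, rooted = FALSE, tip.label = paste0("t", 1:6))
  aln <- random_alignment(6, 30, gap_frac = 0.05)
  base <- fitch_length(tree, aln)
  rerooted <- ape::root(tree, outgroup = "t3", resolve.root = FALSE)
  expect_equal(fitch_length(rerooted, aln), base)
  aln2 <- dna_alignment(aln$seqs[sample(6)])
  expect_equal(fitch_length(tree, aln2), base)
})

test_that("Fitch length agrees with an established implementation", {
  skip_if_not_installed("phangorn")
  set.seed(79)
  for (i in 1:5) {
    n <- sample(5:8, 1)
    tree <- ape::rtree(n, rooted = FALSE, tip.label = paste0("t", 1:n))
    aln <- random_alignment(n, 40)
    m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
    rownames(m) <- aln$ids
    pd <- phangorn::phyDat(m)
    expect_equal(fitch_length(tree, aln),
                 as.numeric(phangorn::parsimony(tree, pd, method = "fitch")))
  }
})

test_that("a clean AB|CD signal yields that unique topology", {
  aln <- dna_alignment(c(A = strrep("A", 10), B = strrep("A", 10),
                         C = strrep("G", 10), D = strrep("G", 10)))
  for (strat in c("exhaustive", "branch_and_bound", "heuristic")) {
    fit <- mp_search(aln, strategy = strat, seed = 3)
    expect_equal(fit$length, 10)
    expect_equal(fit$n_trees, 1L)
    expect_equal(rf_distance(fit$best_trees[[1]],
                             ape::read.tree(text = "((A,B),(C,D));")), 0)
  }
})

test_that("branch and bound equals exhaustive search on random instances", {
  set.seed(80)
  for (i in 1:6) {
    n <- sample(5:6, 1)
    aln <- random_alignment(n, 20)
    ex <- mp_search(aln, strategy = "exhaustive")
    bb <- mp_search(aln, strategy = "branch_and_bound")
    expect_equal(bb$length, ex$length)
    key <- function(f) sort(vapply(f$best_trees, function(t)
      paste(sort(plastomics:::tree_splits(t)), collapse = ";"), ""))
    expect_equal(key(bb), key(ex))
  }
})

test_that("the heuristic never beats the exact length and often matches it", {
  set.seed(81)
  for (i in 1:4) {
    aln <- random_alignment(6, 25)
    ex <- mp_search(aln, strategy = "branch_and_bound")
    he <- mp_search(aln, strategy = "heuristic", n_starts = 5, seed = i)
    expect_gte(he$length, ex$length)
  }
})

test_that("search preconditions are enforced", {
  aln <- random_alignment(10, 10)
  expect_error(mp_search(aln, strategy = "exhaustive"), "<= 9")
  small <- dna_alignment(c(a = "A", b = "C", c = "G"))
  expect_error(mp_search(small), "at least 4")
})

test_that("heuristic search recovers the true 10-taxon topology", {
  tree <- ape::read.tree(text = paste0(
    "(((a:0.02,b:0.02):0.02,(c:0.02,d:0.02):0.02):0.02,",
    "((e:0.02,f:0.02):0.02,(g:0.02,h:0.02):0.02):0.02,(i:0.03,j:0.03):0.02);"))
  hits <- 0L
  for (rep in 1:5) {
    aln <- sim_alignment_on_tree(tree, 800, multiplier = 1, seed = 200 + rep)
    fit <- mp_search(aln, strategy = "heuristic", n_starts = 5, seed = rep)
    cons <- plastomics:::strict_consensus(fit$best_trees)
    if (rf_distance(cons, tree) == 0) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("bootstrap supports behave at the boundaries and reproduce", {
  aln <- dna_alignment(c(A = strrep("A", 12), B = strrep("A", 12),
                         C = strrep("G", 12), D = strrep("G", 12)))
  b <- bootstrap_support(aln, replicates = 20, seed = 4)
  expect_equal(b$split_support$support[b$split_support$split == "C|D"], 100)
  b1 <- bootstrap_support(aln, replicates = 1, seed = 5)
  expect_true(all(b1$split_support$support %in% c(0, 100)))
  b2 <- bootstrap_support(aln, replicates = 20, seed = 4)
  expect_identical(b$split_support, b2$split_support)
  expect_equal(ape::write.tree(b$consensus), ape::write.tree(b2$consensus))
  expect_error(bootstrap_support(aln, replicates = 0), "at least 1")
})

test_that("true splits earn high bootstrap support on simulated data", {
  tree <- ape::read.tree(text = paste0(
    "(((A:0.01,B:0.01):0.01,(C:0.01,D:0.01):0.01):0.01,",
    "(E:0.015,F:0.015):0.01,(G:0.02,H:0.02):0.01);"))
  aln <- sim_alignment_on_tree(tree, 1500, multiplier = 1, seed = 42)
  b <- bootstrap_support(aln, replicates = 100, strategy = "branch_and_bound",
                         seed = 7)
  true_splits <- plastomics:::tree_splits(tree)
  sup <- b$split_support$support[match(true_splits, b$split_support$split)]
  sup[is.na(sup)] <- 0
  expect_true(all(sup >= 70))
})

test_that("tree statistics are exact on homoplasy-free data and match brute force", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  clean <- dna_alignment(c(A = "AAGG", B = "AAGG", C = "GGAA", D = "GGAA"))
  ts <- tree_statistics(tree, clean)
  expect_equal(ts$CI, 1)
  expect_equal(ts$RI, 1)
  expect_equal(ts$RC, 1)
  # independent recomputation of m and g from raw columns
  set.seed(90)
  aln <- random_alignment(6, 25)
  tr <- ape::rtree(6, rooted = FALSE, tip.label = paste0("t", 1:6))
  m_cols <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  m_tot <- 0; g_tot <- 0
  for (col in seq_len(ncol(m_cols))) {
    res <- m_cols[, col]
    res <- res[res %in% c("A", "C", "G", "T")]
    st <- table(res)
    mm <- length(st) - 1L
    if (mm == 0L) next
    m_tot <- m_tot + mm
    g_tot <- g_tot + (length(res) - max(st))
  }
  L <- fitch_length(tr, aln)
  ts2 <- tree_statistics(tr, aln)
  expect_equal(ts2$L, L)
  expect_equal(ts2$CI, m_tot / L)
  expect_equal(ts2$RI, (g_tot - L) / (g_tot - m_tot))
  expect_equal(ts2$RC, ts2$CI * ts2$RI)
})

test_that("a single quartet column with homoplasy gives CI 0.5 and RI 0", {
  # on the tree pairing A1 with G1, the column needs 2 steps; m = 1, g = 2
  tree <- ape::read.tree(text = "((A1,G1),(A2,G2));")
  aln <- dna_alignment(c(A1 = "A", G1 = "G", A2 = "A", G2 = "G"))
  ts <- tree_statistics(tree, aln)
  expect_equal(ts$L, 2)
  expect_equal(ts$CI, 0.5)
  expect_equal(ts$RI, 0)
})

test_that("RF distance counts symmetric split differences", {
  a <- ape::read.tree(text = "((A,B),(C,D));")
  b <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(a, a), 0)
  expect_equal(rf_distance(a, b), 2)
  expect_error(rf_distance(a, ape::read.tree(text = "((A,B),(C,E));")),
               "leaf sets")
})

test_that("RF distance matches an established implementation", {
  skip_if_not_installed("phangorn")
  set.seed(91)
  for (i in 1:8) {
    a <- ape::rtree(8, rooted = FALSE, tip.label = paste0("t", 1:8))
    b <- ape::rtree(8, rooted = FALSE, tip.label = paste0("t", 1:8))
    expect_equal(rf_distance(a, b), as.numeric(phangorn::RF.dist(a, b)))
  }
})
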