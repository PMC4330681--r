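test_that("p-distance counts mismatches over comparable sites", {
  seqs <- c(a = "AAAA", b = "AAAT", c = "TTTT")
  d <- pairwise_distance(seqs, "p")
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "c"], 1)
  expect_equal(d, t(d))
  # identical sequences
  expect_equal(pairwise_distance(c(x = "ACGT", y = "ACGT", z = "AAAA"))["x", "y"], 0)
  # pairwise deletion of gaps and N
  dg <- pairwise_distance(c(a = "A-GTN", b = "ACGTA", c = "ACGTA"))
  expect_equal(dg["a", "b"], 0)  # only 3 comparable, all equal
  expect_error(pairwise_distance(c(a = "A---", b = "-CCC", c = "ACCC")),
               "no comparable sites")
})

test_that("K2P matches its closed form on hand-counted sites", {
  # 10 sites, 2 transitions (A<->G, C<->T), 2 transversions, hand-counted
  seqs <- c(a = "AACCGGTTAC", b = "AGCTGCTTAA", c = "AACCGGTTAC")
  P <- 2 / 10; Q <- 2 / 10
  oracle <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  d <- pairwise_distance(seqs, "K2P")
  expect_equal(d["a", "b"], oracle)
  # cross-check against ape's independent implementation
  bin <- ape::as.DNAbin(t(sapply(seqs, function(s) strsplit(tolower(s), "")[[1]])))
  dd <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(d["a", "b"], dd["a", "b"], tolerance = 1e-12)
  # saturation refused with a pointer to p-distance
  expect_error(pairwise_distance(c(a = "AAAA", b = "GGGG", c = "AAAA"), "K2P"),
               "undefined")
})

test_that("permutation of taxa permutes the distance matrix", {
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  seqs <- setNames(replicate(5, paste0(sample(bases, 40, TRUE), collapse = "")),
                   species_ids(5))
  d1 <- pairwise_distance(seqs)
  ord <- c(3, 1, 5, 2, 4)
  d2 <- pairwise_distance(seqs[ord])
  expect_equal(d2, d1[names(seqs)[ord], names(seqs)[ord]])
})

test_that("NJ reproduces the 3- and 4-taxon closed forms", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  # star tree with branches 1, 2, 3
  expect_equal(sort(tr$edge.length), c(1, 2, 3))
  expect_equal(patristic_matrix(tr)[rownames(d), rownames(d)], d)
  # additive 4-taxon matrix: split AB|CD, leaf branches 1,2,3,4, internal 1
  d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4["A", "B"] <- 3; d4["A", "C"] <- 5; d4["A", "D"] <- 6
  d4["B", "C"] <- 6; d4["B", "D"] <- 7; d4["C", "D"] <- 7
  d4 <- d4 + t(d4)
  tr4 <- neighbor_joining(d4)
  expect_equal(sort(tr4$edge.length), c(1, 1, 2, 3, 4))
  expect_equal(patristic_matrix(tr4)[LETTERS[1:4], LETTERS[1:4]], d4)
  expect_error(neighbor_joining(d4 - 1), "diagonal|non-negative")
})

test_that("NJ agrees with an independent implementation on random matrices", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    tru <- random_pos_tree(n)
    d <- patristic_matrix(tru)
    mine <- neighbor_joining(d)
    theirs <- ape::nj(as.dist(d))
    expect_same_topology(mine, theirs)
    expect_same_topology(mine, tru)
    expect_lt(max(abs(patristic_matrix(mine)[rownames(d), colnames(d)] - d)),
              1e-9)
  }
})

test_that("NJ clamps negative branch estimates and records the deficit", {
  # strongly non-additive matrix known to produce a negative NJ estimate
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 5.9
  d["A", "C"] <- d["C", "A"] <- 0.1
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "clamped"), 0)
})

test_that("patristic matrices are metrics and satisfy the four-point condition", {
  set.seed(3)
  for (i in 1:10) {
    tru <- random_pos_tree(sample(5:9, 1))
    m <- patristic_matrix(tru)
    expect_true(all(m >= 0))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    n <- nrow(m)
    # triangle inequality, brute force
    for (i1 in 1:n) for (j1 in 1:n) for (k1 in 1:n) {
      expect_lte(m[i1, j1], m[i1, k1] + m[k1, j1] + 1e-12)
    }
    # four-point condition over all quartets
    qs <- combn(n, 4)
    for (q in seq_len(ncol(qs))) {
      ij <- qs[, q]
      s <- sort(c(m[ij[1], ij[2]] + m[ij[3], ij[4]],
                  m[ij[1], ij[3]] + m[ij[2], ij[4]],
                  m[ij[1], ij[4]] + m[ij[2], ij[3]]))
      expect_lt(s[3] - s[2], 1e-9)
    }
  }
})

test_that("patristic_matrix refuses trees with missing branch lengths", {
  tr <- ape::rtree(5)
  tr$edge.length[2] <- NA
  expect_error(patristic_matrix(tr), "missing branch length")
  tr2 <- ape::rtree(4)
  tr2$edge.length <- NULL
  expect_error(patristic_matrix(tr2), "no branch lengths")
})

test_that("bootstrap supports: forced split, single replicate, determinism", {
  # every column shows the same informative pattern AB|CD; resampling
  # cannot change it
  seqs <- c(A = strrep("A", 30), B = strrep("A", 30),
            C = strrep("T", 30), D = strrep("T", 30))
  tr <- nj_bootstrap(seqs, n_reps = 25, seed = 1)
  expect_equal(unname(attr(tr, "support")), 100)
  # one replicate: supports are 0 or 100
  set.seed(8)
  bases <- c("A", "C", "G", "T")
  rs <- setNames(replicate(6, paste0(sample(bases, 50, TRUE), collapse = "")),
                 species_ids(6))
  t1 <- nj_bootstrap(rs, n_reps = 1, seed = 2)
  expect_true(all(attr(t1, "support") %in% c(0, 100)))
  # fixed seed reproduces supports exactly
  t2 <- nj_bootstrap(rs, n_reps = 20, seed = 5)
  t3 <- nj_bootstrap(rs, n_reps = 20, seed = 5)
  expect_identical(attr(t2, "support"), attr(t3, "support"))
})
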