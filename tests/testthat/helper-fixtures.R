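# Shared fixtures and independent oracles used across test files.

species_ids <- function(n) sprintf("s%02d", seq_len(n))

# random symmetric distance matrix with uniform off-diagonal entries
random_sym_matrix <- function(n, min = 0, max = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, min, max)
  m <- m + t(m)
  dimnames(m) <- list(species_ids(n), species_ids(n))
  attr(m, "signed") <- FALSE
  m
}

# textbook Pearson correlation: explicit sums, no shortcuts shared with
# the implementation under test
pearson_oracle <- function(a, b) {
  n <- length(a)
  num <- sum((a - sum(a) / n) * (b - sum(b) / n))
  den <- sqrt(sum((a - sum(a) / n)^2)) * sqrt(sum((b - sum(b) / n)^2))
  num / den
}

# vectorize a matrix the slow, obvious way (row-major loops)
vectorize_oracle <- function(m, mode) {
  n <- nrow(m)
  out <- numeric(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (mode == "upper" && i > j) next
      out <- c(out, m[i, j])
    }
  }
  out[!is.na(out)]
}

# random tree with strictly positive branch lengths
random_pos_tree <- function(n, min_bl = 0.1, max_bl = 1) {
  ape::rtree(n, br = function(k) runif(k, min_bl, max_bl))
}

# fixed imbalanced (pectinate) 13-leaf tree with unit branch lengths
caterpillar13 <- function() {
  tr <- ape::stree(13, type = "left")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- species_ids(13)
  tr
}

expect_same_topology <- function(a, b) {
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(a), ape::unroot(b))), 0)
}
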