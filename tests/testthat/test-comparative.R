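test_that("PCoA recovers collinear coordinates (classical-scaling oracle)", {
  # three collinear points at 0, 1, 3
  pts <- c(p1 = 0, p2 = 1, p3 = 3)
  d <- abs(outer(pts, pts, "-"))
  dimnames(d) <- list(names(pts), names(pts))
  basis <- pcoa_axes(d)
  # independent oracle: base R classical scaling
  cs <- cmdscale(as.dist(d), k = 2, eig = TRUE)
  expect_equal(basis$values[1], cs$eig[1])
  # coordinates proportional to axis 1 up to sign
  mine <- basis$vectors[, 1] * sqrt(basis$values[1])
  expect_true(min(max(abs(mine - cs$points[, 1])),
                  max(abs(mine + cs$points[, 1]))) < 1e-8)
  # only one meaningful positive eigenvalue for collinear points
  expect_lt(abs(basis$values[2]), 1e-8)
})

test_that("equidistant taxa give two equal positive eigenvalues", {
  d <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d) <- 0
  basis <- pcoa_axes(d)
  expect_equal(basis$values[1], basis$values[2])
  expect_gt(basis$values[1], 0)
})

test_that("positive axes reconstruct Euclidean-embeddable distances", {
  set.seed(4)
  pts <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(species_ids(6), NULL))
  d <- as.matrix(dist(pts))
  basis <- pcoa_axes(d)
  conf <- basis$vectors[, basis$positive, drop = FALSE] %*%
    diag(sqrt(basis$values[basis$positive]))
  expect_lt(max(abs(as.matrix(dist(conf)) - d)), 1e-8)
})

test_that("PCoA axes are invariant (up to sign) to species input order", {
  set.seed(9)
  d <- patristic_matrix(random_pos_tree(7))
  b1 <- pcoa_axes(d)
  ord <- sample(rownames(d))
  b2 <- pcoa_axes(d[ord, ord])
  expect_equal(b1$values, b2$values)
  for (k in b1$positive) {
    v1 <- b1$vectors[ord, k]; v2 <- b2$vectors[, k]
    expect_lt(min(max(abs(v1 - v2)), max(abs(v1 + v2))), 1e-8)
  }
})

test_that("broken-stick retention follows the 1/n harmonic expectation", {
  fake <- structure(list(values = c(10, 0.1, 0.05),
                         vectors = matrix(0, 3, 3,
                                          dimnames = list(letters[1:3], NULL)),
                         positive = 1:3),
                    class = "phylo_eigen")
  expect_equal(select_axes(fake, "broken_stick"), 1L)
  expect_equal(select_axes(fake, "first_k", k = 2), c(1L, 2L))
  expect_error(select_axes(fake, "first_k", k = 4), "exceeds")
  # all-equal eigenvalues: every share 1/p is below the first stick H_p/p
  flat <- structure(list(values = rep(2, 4),
                         vectors = matrix(0, 4, 4,
                                          dimnames = list(letters[1:4], NULL)),
                         positive = 1:4),
                    class = "phylo_eigen")
  expect_length(select_axes(flat, "broken_stick"), 0)
  # cross-check the expectation itself against vegan's broken stick
  bs <- vegan::bstick(3, 1)  # n pieces summing to 1
  rel <- c(10, 0.1, 0.05) / 10.15
  expect_identical(unname(which(rel > bs)), 1L)
})

test_that("signal ANOVA: perfect fit, orthogonal trait, affine invariance", {
  set.seed(12)
  d <- patristic_matrix(random_pos_tree(10))
  basis <- pcoa_axes(d)
  axes <- 1:2
  sp <- rownames(basis$vectors)
  # trait equal to axis 1: perfect fit
  tr1 <- setNames(basis$vectors[, 1], sp)
  res1 <- phylo_signal_anova(tr1, basis, axes)
  expect_equal(res1$r_squared, 1)
  expect_identical(res1$F, Inf)
  expect_equal(res1$p, 0)
  # trait orthogonal to the retained axes (a later axis is orthogonal and
  # centred by construction): zero model sum of squares
  tr0 <- setNames(basis$vectors[, 3], sp)
  res0 <- phylo_signal_anova(tr0, basis, axes)
  expect_equal(res0$F, 0, tolerance = 1e-8)
  # affine transformation leaves F unchanged
  set.seed(13)
  trz <- setNames(rnorm(10), sp)
  f1 <- phylo_signal_anova(trz, basis, axes)
  f2 <- phylo_signal_anova(5 * trz - 3, basis, axes)
  expect_equal(f1$F, f2$F)
  expect_equal(f1$p, f2$p)
  # agreement with lm()'s overall F-statistic
  fit <- summary(lm(trz ~ basis$vectors[sp, axes]))
  expect_equal(f1$F, unname(fit$fstatistic["value"]))
  expect_equal(f1$r_squared, fit$r.squared)
})

test_that("signal ANOVA handles NA species, constant traits, low df", {
  set.seed(14)
  d <- patristic_matrix(random_pos_tree(9))
  basis <- pcoa_axes(d)
  sp <- rownames(basis$vectors)
  tr <- setNames(rnorm(9), sp)
  tr[c(2, 5)] <- NA
  res <- phylo_signal_anova(tr, basis, 1:2)
  expect_equal(res$n, 7)
  expect_equal(res$df2, 7 - 2 - 1)
  cst <- setNames(rep(1, 9), sp)
  rc <- phylo_signal_anova(cst, basis, 1:2)
  expect_identical(rc$flag, "constant_trait")
  expect_true(is.na(rc$F))
  tiny <- tr; tiny[4:9] <- NA
  expect_error(phylo_signal_anova(tiny, basis, 1:2), "insufficient")
})
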