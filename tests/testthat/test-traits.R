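test_that("leaf traits follow their defining ratios and units", {
  lt <- compute_leaf_traits(20, 0.5, 0.1)
  expect_equal(lt$sla_m2_kg, 20)
  expect_equal(lt$ldmc_mg_g, 200)
  # fully dry leaf: dry = fresh
  expect_equal(compute_leaf_traits(10, 0.2, 0.2)$ldmc_mg_g, 1000)
  expect_error(compute_leaf_traits(10, 0.1, 0.2), "fresh")
  expect_error(compute_leaf_traits(-1, 0.5, 0.1), "positive")
})

test_that("fine-root traits: weighted diameter, SRL, very-fine fraction", {
  fr <- compute_fine_root_traits(c(0.15, 0.35), c(3, 1),
                                 dry_mass_g = 0.02, volume_cm3 = 0.1,
                                 p_concentration_mg_g = 1)
  expect_equal(fr$diameter_mm, 0.20)
  expect_equal(fr$srl_m_g, 200)
  expect_equal(fr$very_fine_pct, 75)
  expect_equal(fr$rtd_mg_cm3, 200)
  # RPUE = SRL / P concentration
  fr2 <- compute_fine_root_traits(c(0.15, 0.35), c(3, 1), 0.02, 0.1,
                                  p_concentration_mg_g = 2)
  expect_equal(fr2$rpue_m_mg, 100)
  # single class: SRL = L/M, diameter = class median
  fr3 <- compute_fine_root_traits(0.3, 5, 0.05, 0.2)
  expect_equal(fr3$srl_m_g, 100)
  expect_equal(fr3$diameter_mm, 0.3)
  expect_equal(fr3$very_fine_pct, 0)
  expect_error(compute_fine_root_traits(numeric(0), numeric(0), 0.1, 0.1),
               "empty")
  expect_error(compute_fine_root_traits(0.3, 5, 0.05, 0.2,
                                        p_concentration_mg_g = 0),
               "RPUE")
})

test_that("taproot traits and boundary cases", {
  tp <- compute_taproot_traits(1, 0.5, 0.2, coarse_mass_g = 2,
                               total_root_mass_g = 4)
  expect_equal(tp$strl_m_g, 2)
  expect_equal(tp$trtd_g_cm3, 2.5)
  expect_equal(tp$taproot_pct, 50)
  expect_equal(compute_taproot_traits(1, 0.5, 0.2, 0, 4)$taproot_pct, 0)
  expect_equal(compute_taproot_traits(1, 0.5, 0.2, 4, 4)$taproot_pct, 100)
  expect_error(compute_taproot_traits(1, 0.5, 0.2, 5, 4), "exceed")
})

test_that("depth95: exact on linear profiles, OLS oracle otherwise", {
  # uniform profile over 0-100 cm: cumulative curve is the fitted line
  expect_equal(compute_depth95(seq(0, 100, 20), rep(2, 5)), 95)
  # scale invariance
  expect_equal(compute_depth95(seq(0, 100, 20), rep(2, 5) * 7), 95)
  # uneven profile: agree with an explicit lm() fit on the 5 cumulative points
  lens <- c(5, 1, 1, 1, 0.5)
  x <- seq(20, 100, 20); y <- cumsum(lens)
  fit <- lm(y ~ x)
  oracle <- (0.95 * sum(lens) - coef(fit)[[1]]) / coef(fit)[[2]]
  expect_equal(compute_depth95(seq(0, 100, 20), lens), oracle)
  # degenerate profiles
  expect_error(compute_depth95(seq(0, 100, 20), rep(0, 5)), "undefined")
  expect_error(compute_depth95(seq(0, 100, 20), c(3, 0, 0, 0, 0)), "slope")
})

test_that("root length density combines fine length and taproot length", {
  expect_equal(compute_rld(2, 100, 100, 10000), 2.01)
  expect_equal(compute_rld(2, 100, 0, 10000), 2)       # no taproot
  expect_equal(compute_rld(c(1, 1), 100, 0, 10000), 2) # per-segment masses
  expect_error(compute_rld(2, 100, 100, 0), "pot volume")
})

test_that("mycorrhization rate is the AMF intersect fraction", {
  expect_equal(compute_mycorrhization_rate(45, 300), 15)
  expect_equal(compute_mycorrhization_rate(0, 300), 0)
  expect_error(compute_mycorrhization_rate(10, 0), "positive")
  expect_error(compute_mycorrhization_rate(301, 300), "\\[0, total\\]")
})

test_that("trait summary: min/mean/max/CV with NA handling", {
  tab <- data.frame(a = c(1, 1, 1), b = c(0, 10, NA), c = c(NA, NA, NA))
  s <- summarize_traits(tab)
  expect_equal(s$cv_pct[s$trait == "a"], 0)
  expect_equal(s$mean[s$trait == "b"], 5)
  # hand-computed sample sd of c(0, 10)
  expect_equal(s$cv_pct[s$trait == "b"], 100 * sqrt(50) / 5)
  expect_equal(s$n[s$trait == "b"], 2)
  expect_false("c" %in% s$trait)
  expect_identical(attr(s, "skipped"), "c")
  # CV invariant to positive scaling
  s2 <- summarize_traits(data.frame(b = c(0, 10, NA) * 3))
  expect_equal(s2$cv_pct, s$cv_pct[s$trait == "b"])
})

test_that("trait values are positive / bounded on valid records", {
  set.seed(42)
  for (i in 1:20) {
    tgt <- random_trait_targets(5)
    rec <- generate_measurement_records(tgt)
    tt <- compute_all_traits(rec)
    expect_true(all(tt$srl_m_g > 0))
    expect_true(all(tt$rtd_mg_cm3 > 0))
    expect_true(all(tt$sla_m2_kg > 0))
    expect_true(all(tt$ldmc_mg_g > 0 & tt$ldmc_mg_g <= 1000))
    expect_true(all(tt$very_fine_pct >= 0 & tt$very_fine_pct <= 100))
    expect_true(all(tt$taproot_pct >= 0 & tt$taproot_pct <= 100))
    expect_true(all(tt$mycorrhizal_rate_pct >= 0 & tt$mycorrhizal_rate_pct <= 100))
  }
})
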