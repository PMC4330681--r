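# Synthetic data with the statistical structure the analysis assumes:
# Yule trees, traits evolving by Brownian motion (phylogenetic signal) or
# white noise (none), ecological indicators linearly coupled to traits,
# missing-at-random indicator cells, and raw measurement records that
# invert exactly to target trait values.

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree with `n_species` leaves, tips labelled `sp01`, `sp02`,
#' ...
#'
#' @param n_species number of leaves (>= 2).
#' @param birth_rate speciation rate per unit time (default 1).
#' @param seed optional integer seed.
#' @return An ultrametric `phylo` tree.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  if (n_species < 2) stop_invalid("n_species must be >= 2")
  if (birth_rate <= 0) stop_invalid("birth_rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tr
}

#' Simulate a trait on a tree
#'
#' `"brownian"`: root value 0, independent normal increments per branch
#' with variance `sigma2 * branch length`, so expected tip covariance is
#' `sigma2 x` shared path length.  `"white"`: i.i.d. normal values
#' ignoring the tree (no phylogenetic signal).
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param model `"brownian"` or `"white"`.
#' @param sigma2 Brownian rate (trait^2 per unit branch length) or white
#'   variance.
#' @param seed optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_trait <- function(tree, model = c("brownian", "white"), sigma2 = 1,
                           seed = NULL) {
  model <- match.arg(model)
  if (!inherits(tree, "phylo")) stop_invalid("tree must be a phylo object")
  if (sigma2 <= 0) stop_invalid("sigma2 must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  if (model == "white") {
    return(stats::setNames(stats::rnorm(n, 0, sqrt(sigma2)), tree$tip.label))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop_invalid("Brownian simulation needs complete branch lengths")
  }
  tr <- ape::reorder.phylo(tree, "cladewise")
  val <- numeric(max(tr$edge))
  inc <- stats::rnorm(nrow(tr$edge), 0, sqrt(sigma2 * tr$edge.length))
  for (e in seq_len(nrow(tr$edge))) {
    val[tr$edge[e, 2]] <- val[tr$edge[e, 1]] + inc[e]
  }
  stats::setNames(val[seq_len(n)], tr$tip.label)
}

#' Plant an indicator linearly coupled to a trait
#'
#' `indicator_i = slope * trait_i + N(0, noise_sd^2)`.  With zero noise
#' the hierarchical Mantel correlation between trait and indicator is
#' exactly `sign(slope)`.
#'
#' @param trait named numeric vector of trait values.
#' @param slope indicator units per trait unit.
#' @param noise_sd standard deviation of the additive noise (indicator
#'   units).
#' @param seed optional integer seed.
#' @return Named numeric vector of indicator values.
#' @export
plant_indicator <- function(trait, slope = 1, noise_sd = 0, seed = NULL) {
  if (!is.finite(slope)) stop_invalid("slope must be finite")
  if (noise_sd < 0) stop_invalid("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  slope * trait + stats::rnorm(length(trait), 0, noise_sd)
}

#' Noise level for a target trait-indicator correlation
#'
#' For `indicator = trait + e`, pairwise differences correlate with trait
#' differences at the population level with
#' `r = 1 / sqrt(1 + var(e)/var(trait))`; this returns the `sd(e)` that
#' attains a requested `r`, using the sample SD of the supplied trait.
#'
#' @param trait named numeric vector of trait values.
#' @param r target correlation in (0, 1].
#' @return Noise standard deviation.
#' @export
indicator_noise_for_r <- function(trait, r) {
  if (r <= 0 || r > 1) stop_invalid("r must be in (0, 1]")
  stats::sd(trait) * sqrt(1 / r^2 - 1)
}

#' Inject missing values at random
#'
#' Sets each cell to `NA` independently with probability `fraction`
#' (missing-at-random), then verifies every column still has at least
#' `min_complete` observed species.
#'
#' @param table species x variable data.frame or matrix.
#' @param fraction per-cell missingness probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @param min_complete minimum non-`NA` species required per column
#'   (default 3, the minimum for a downstream distance matrix).
#' @return The table with `NA` cells.
#' @export
inject_missing <- function(table, fraction, seed = NULL, min_complete = 3) {
  if (fraction < 0 || fraction >= 1) stop_invalid("fraction must be in [0, 1)")
  if (fraction == 0) return(table)
  if (!is.null(seed)) set.seed(seed)
  m <- as.matrix(table)
  hit <- stats::runif(length(m)) < fraction
  m[hit] <- NA
  if (any(colSums(!is.na(m)) < min_complete)) {
    stop_invalid("missingness left a column with fewer than ", min_complete,
                 " observed species")
  }
  if (is.data.frame(table)) {
    out <- as.data.frame(m)
    rownames(out) <- rownames(table)
    out
  } else {
    m
  }
}

# ---------------------------------------------------------------------------
# Invertible measurement records

# Anchor shapes for the cumulative fine-root profile (depths 20..100 cm,
# total normalized to 1): concave (shallow) u^0.2 and convex (deep) u^3.
# Their convex blend is monotone, and the OLS depth95 is a Moebius function
# of the blend weight, so any target in the achievable range is hit in
# closed form.
depth95_anchors <- function(boundaries_cm = seq(0, 100, by = 20)) {
  x <- boundaries_cm[-1]
  u <- x / max(x)
  ya <- u^0.2
  yb <- u^3
  ols <- function(y) {
    b <- stats::cov(x, y) / stats::var(x)
    c(a = mean(y) - b * mean(x), b = b)
  }
  list(x = x, ya = ya, yb = yb, fa = ols(ya), fb = ols(yb))
}

depth95_from_blend <- function(anch, s) {
  a <- anch$fa["a"] + s * (anch$fb["a"] - anch$fa["a"])
  b <- anch$fa["b"] + s * (anch$fb["b"] - anch$fa["b"])
  unname((0.95 - a) / b)
}

solve_depth95_blend <- function(target_cm, anch) {
  da <- anch$fb["a"] - anch$fa["a"]
  db <- anch$fb["b"] - anch$fa["b"]
  s <- unname((0.95 - anch$fa["a"] - target_cm * anch$fa["b"]) /
                (da + target_cm * db))
  if (!is.finite(s) || s < 0 || s > 1) {
    rng <- sort(c(depth95_from_blend(anch, 0), depth95_from_blend(anch, 1)))
    stop_invalid(sprintf(
      "depth95 target %.2f cm outside achievable range [%.1f, %.1f]",
      target_cm, rng[1], rng[2]))
  }
  s
}

# Diameter classes realizing mean diameter D with a very-fine fraction f.
solve_diameter_classes <- function(D, f, threshold = 0.2) {
  if (f < 0 || f > 1) stop_invalid("very_fine_pct must lie in [0, 100]")
  if (f > 1 - 1e-12) {
    if (D >= threshold) stop_invalid("very_fine_pct 100 requires mean diameter < 0.2 mm")
    return(list(d = D, w = 1))
  }
  if (f < 1e-12) {
    if (D < threshold) stop_invalid("very_fine_pct 0 requires mean diameter >= 0.2 mm")
    return(list(d = D, w = 1))
  }
  d1_max <- (D - threshold * (1 - f)) / f
  if (d1_max <= 0) {
    stop_invalid("mean diameter ", D, " too small for very-fine fraction ", f)
  }
  d1 <- min(0.15, 0.95 * d1_max)
  d2 <- (D - f * d1) / (1 - f)
  list(d = c(d1, d2), w = c(f, 1 - f))
}

rel_err <- function(a, b) abs(a - b) / pmax(1, abs(b))

#' Generate raw measurement records for target trait values
#'
#' Constructs, for each species, a leaf record, a diameter-classified fine
#' root sample, a taproot sample, a five-segment depth profile and a
#' grid-line intersect count whose computed traits
#' ([compute_all_traits()]) equal the targets to within floating error.
#' Free measurement scales (sample masses) are drawn from realistic bench
#' ranges under `seed`; the inversion itself is deterministic given those
#' draws.
#'
#' Targets must be internally consistent: biomass identities
#' (`root_system = fine + taproot`, `taproot_pct`, `root_shoot_ratio`,
#' `total_biomass`), the cylinder identity
#' `sra = pi * diameter * srl / 10`, a mycorrhizal rate expressible as
#' `100 * a / 300` with integer `a`, and a depth95 within the achievable
#' profile range.  [random_trait_targets()] produces such tables.
#'
#' @param targets species x trait data.frame with the columns of
#'   [trait_names()].
#' @param seed optional integer seed for the free measurement scales.
#' @return Named list of per-species record lists (components `leaf`,
#'   `fine_root`, `taproot`, `depth_profile`, `intersects`,
#'   `passthrough`).
#' @export
generate_measurement_records <- function(targets, seed = NULL) {
  targets <- as.data.frame(targets)
  missing_cols <- setdiff(trait_names(), names(targets))
  if (length(missing_cols)) {
    stop_invalid("targets lack columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  anch <- depth95_anchors()
  records <- list()
  for (sp in rownames(targets)) {
    tg <- as.list(targets[sp, ])
    # -- consistency checks -------------------------------------------------
    if (rel_err(tg$root_system_biomass_g,
                tg$fine_root_biomass_g + tg$taproot_biomass_g) > 1e-9) {
      stop_invalid(sp, ": root system biomass != fine + taproot biomass")
    }
    if (rel_err(tg$taproot_pct,
                100 * tg$taproot_biomass_g / tg$root_system_biomass_g) > 1e-9) {
      stop_invalid(sp, ": taproot_pct inconsistent with biomasses")
    }
    if (rel_err(tg$root_shoot_ratio,
                tg$root_system_biomass_g / tg$aboveground_biomass_g) > 1e-9) {
      stop_invalid(sp, ": root_shoot_ratio inconsistent with biomasses")
    }
    if (rel_err(tg$total_biomass_g,
                tg$root_system_biomass_g + tg$aboveground_biomass_g) > 1e-9) {
      stop_invalid(sp, ": total biomass inconsistent")
    }
    if (rel_err(tg$sra_dm2_g, pi * tg$diameter_mm * tg$srl_m_g / 10) > 1e-9) {
      stop_invalid(sp, ": sra inconsistent with cylinder geometry (pi*D*SRL/10)")
    }
    if (tg$ldmc_mg_g > 1000) stop_invalid(sp, ": LDMC cannot exceed 1000 mg/g")
    amf <- round(tg$mycorrhizal_rate_pct * 3)
    if (rel_err(100 * amf / 300, tg$mycorrhizal_rate_pct) > 1e-9) {
      stop_invalid(sp, ": mycorrhizal rate not expressible over 300 intersects")
    }
    # -- leaf ---------------------------------------------------------------
    leaf_dry <- stats::runif(1, 0.05, 0.2)
    leaf <- list(leaf_area_cm2 = 10 * tg$sla_m2_kg * leaf_dry,
                 leaf_fresh_mass_g = 1000 * leaf_dry / tg$ldmc_mg_g,
                 leaf_dry_mass_g = leaf_dry)
    # -- fine-root sample ---------------------------------------------------
    cls <- solve_diameter_classes(tg$diameter_mm, tg$very_fine_pct / 100)
    sample_mass <- stats::runif(1, 0.01, 0.05)
    total_len <- tg$srl_m_g * sample_mass
    fine_root <- list(
      class_diameter_mm = cls$d,
      class_length_m = cls$w * total_len,
      dry_mass_g = sample_mass,
      volume_cm3 = 1000 * sample_mass / tg$rtd_mg_cm3,
      p_concentration_mg_g = tg$srl_m_g / tg$rpue_m_mg,
      nodule_dry_mass_g = tg$nodule_investment_g_m * total_len
    )
    # -- taproot ------------------------------------------------------------
    taproot <- list(
      length_m = tg$strl_m_g * tg$taproot_biomass_g,
      dry_mass_g = tg$taproot_biomass_g,
      volume_cm3 = tg$taproot_biomass_g / tg$trtd_g_cm3
    )
    # -- depth profile ------------------------------------------------------
    s <- solve_depth95_blend(tg$depth95_cm, anch)
    shape <- (1 - s) * anch$ya + s * anch$yb
    total_fine_len <- tg$fine_root_biomass_g * tg$srl_m_g
    cum_len <- shape * total_fine_len
    seg_len <- diff(c(0, cum_len))
    taproot_len_cm <- 100 * taproot$length_m
    pot_volume <- (tg$fine_root_biomass_g * tg$srl_m_g * 100 + taproot_len_cm) /
      tg$rld_cm_cm3
    depth_profile <- list(
      boundaries_cm = c(0, anch$x),
      fine_root_length_m = seg_len,
      fine_root_mass_g = seg_len / tg$srl_m_g,
      coarse_root_mass_g = rep(tg$taproot_biomass_g / length(seg_len),
                               length(seg_len)),
      taproot_length_cm = taproot_len_cm,
      pot_volume_cm3 = pot_volume
    )
    records[[sp]] <- list(
      leaf = leaf,
      fine_root = fine_root,
      taproot = taproot,
      depth_profile = depth_profile,
      intersects = list(amf_intersects = amf, total_intersects = 300),
      passthrough = list(
        aerenchyma_pct = tg$aerenchyma_pct,
        hairs_um = tg$hairs_um,
        phosphatase_ug_m_h = tg$phosphatase_ug_m_h,
        stele_pct = tg$stele_pct,
        aboveground_biomass_g = tg$aboveground_biomass_g
      )
    )
  }
  records
}

#' Random feasible trait-target tables
#'
#' Draws species-level values uniformly within the ranges observed for
#' grassland legumes, with dependent traits (specific root area, biomass
#' ratios, mycorrhizal rate over 300 intersects) derived so the table
#' satisfies every consistency constraint of
#' [generate_measurement_records()].
#'
#' @param n_species number of species rows.
#' @param seed optional integer seed.
#' @return species x 25 trait data.frame (rows `sp01`, ...).
#' @export
random_trait_targets <- function(n_species = 13, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_species
  f <- stats::runif(n, 0.15, 0.90)
  d1 <- stats::runif(n, 0.08, 0.18)
  d2 <- stats::runif(n, 0.22, 0.45)
  D <- f * d1 + (1 - f) * d2
  srl <- stats::runif(n, 38, 650)
  p_conc <- stats::runif(n, 1.5, 5)
  fine <- stats::runif(n, 0.42, 5)
  taproot <- stats::runif(n, 0.25, 5)
  above <- stats::runif(n, 4, 19)
  root_system <- fine + taproot
  amf <- sample(2:78, n, replace = TRUE)
  out <- data.frame(
    aerenchyma_pct = stats::runif(n, 0, 12.9),
    diameter_mm = D,
    hairs_um = stats::runif(n, 7.9, 39.6),
    nodule_investment_g_m = stats::runif(n, 0.02, 0.34),
    mycorrhizal_rate_pct = 100 * amf / 300,
    rpue_m_mg = srl / p_conc,
    phosphatase_ug_m_h = stats::runif(n, 140, 740),
    rtd_mg_cm3 = stats::runif(n, 54.9, 209.6),
    sra_dm2_g = pi * D * srl / 10,
    srl_m_g = srl,
    stele_pct = stats::runif(n, 9.3, 38),
    very_fine_pct = 100 * f,
    strl_m_g = stats::runif(n, 0.24, 2.24),
    trtd_g_cm3 = stats::runif(n, 1.61, 5.35),
    depth95_cm = stats::runif(n, 82, 99.7),
    fine_root_biomass_g = fine,
    root_system_biomass_g = root_system,
    rld_cm_cm3 = stats::runif(n, 1.23, 9.94),
    taproot_biomass_g = taproot,
    taproot_pct = 100 * taproot / root_system,
    sla_m2_kg = stats::runif(n, 19.2, 31.1),
    ldmc_mg_g = stats::runif(n, 138, 288),
    aboveground_biomass_g = above,
    root_shoot_ratio = root_system / above,
    total_biomass_g = root_system + above,
    row.names = sprintf("sp%02d", seq_len(n))
  )
  out[trait_names()]
}

#' Ellenberg-type indicator table for the 13 grassland Fabaceae species
#'
#' The packaged species x indicator table: continentality (C), edaphic
#' humidity (HE), nitrogen (N), phosphorus requirement (P, 0-10), soil pH
#' and salinity (S), with the published `NA` cells preserved (3 in C, 4 in
#' N, 2 in P, 1 in pH).
#'
#' @return 13 x 6 data.frame, rownames = species names.
#' @export
fixture_table1 <- function() {
  path <- system.file("extdata", "fabaceae_indicators.csv",
                      package = "nichedist", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(tab) <- tab$species
  tab$species <- NULL
  tab
}
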