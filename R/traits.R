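# Functional trait calculators: leaf, fine-root, taproot, whole-root-system
# and mycorrhizal traits computed from raw measurement records.
#
# Units follow the conventions of comparative plant ecology: SLA in m2.kg-1,
# LDMC in mg.g-1, SRL in m.g-1, RTD in mg.cm-3, SRA in dm2.g-1, RPUE in
# m.mg-1, STRL in m.g-1, TRTD in g.cm-3, RLD in cm.cm-3.  Raw measurements
# arrive in bench units (cm2, g, mm, m, cm3) and are converted internally.

#' Leaf traits from a leaf measurement record
#'
#' Computes specific leaf area (SLA) and leaf dry matter content (LDMC) from
#' the area, fresh mass and dry mass of a leaf sample.
#'
#' @param leaf_area_cm2 projected leaf area (cm2).
#' @param leaf_fresh_mass_g water-saturated fresh mass (g).
#' @param leaf_dry_mass_g oven-dry mass (g).
#' @return A list with `sla_m2_kg` (ratio of area to dry mass, m2.kg-1) and
#'   `ldmc_mg_g` (ratio of dry to fresh mass, mg.g-1).
#' @examples
#' compute_leaf_traits(20, 0.5, 0.1)  # SLA 20, LDMC 200
#' @export
compute_leaf_traits <- function(leaf_area_cm2, leaf_fresh_mass_g, leaf_dry_mass_g) {
  if (any(leaf_area_cm2 <= 0)) stop_invalid("leaf area must be positive")
  if (any(leaf_dry_mass_g <= 0) || any(leaf_fresh_mass_g <= 0)) {
    stop_invalid("leaf masses must be positive")
  }
  if (any(leaf_dry_mass_g > leaf_fresh_mass_g)) {
    stop_invalid("leaf dry mass cannot exceed fresh mass")
  }
  # cm2/g -> m2/kg: (1e-4 m2) / (1e-3 kg) = 0.1
  list(
    sla_m2_kg = 0.1 * leaf_area_cm2 / leaf_dry_mass_g,
    ldmc_mg_g = 1000 * leaf_dry_mass_g / leaf_fresh_mass_g
  )
}

#' Fine-root traits from a scanned root sample
#'
#' Computes mean diameter, specific root length, root tissue density,
#' specific root area, very fine root percentage, root phosphorus use
#' efficiency and specific investment in nodules from a diameter-classified
#' root scan.
#'
#' Mean diameter is the mean of the class median diameters weighted by root
#' length per class.  Specific root area treats roots as cylinders:
#' lateral surface `pi * d * L` summed over classes, per unit dry mass.
#'
#' @param class_diameter_mm median diameter of each root-diameter class (mm).
#' @param class_length_m root length in each class (m).
#' @param dry_mass_g sample dry mass (g).
#' @param volume_cm3 sample volume (cm3).
#' @param p_concentration_mg_g root phosphorus concentration (mg P g-1);
#'   `NA` if unmeasured (RPUE then `NA`).
#' @param nodule_dry_mass_g dry mass of nodules borne by the sample (g);
#'   `NA` if unmeasured.
#' @param total_length_m optional independently recorded total length (m);
#'   checked against the class sum.
#' @param very_fine_threshold_mm diameter below which a class counts as very
#'   fine (default 0.2 mm).
#' @return A list with `diameter_mm`, `srl_m_g`, `rtd_mg_cm3`, `sra_dm2_g`,
#'   `very_fine_pct`, `rpue_m_mg`, `nodule_investment_g_m`.
#' @examples
#' compute_fine_root_traits(c(0.15, 0.35), c(3, 1), dry_mass_g = 0.02,
#'                          volume_cm3 = 0.05, p_concentration_mg_g = 2)
#' @export
compute_fine_root_traits <- function(class_diameter_mm, class_length_m,
                                     dry_mass_g, volume_cm3,
                                     p_concentration_mg_g = NA_real_,
                                     nodule_dry_mass_g = NA_real_,
                                     total_length_m = NULL,
                                     very_fine_threshold_mm = 0.2) {
  if (length(class_diameter_mm) == 0 || length(class_length_m) == 0) {
    stop_invalid("empty root-diameter class list")
  }
  if (length(class_diameter_mm) != length(class_length_m)) {
    stop_invalid("class diameters and lengths differ in length")
  }
  if (any(class_length_m < 0)) stop_invalid("class lengths must be non-negative")
  if (any(class_diameter_mm <= 0)) stop_invalid("class diameters must be positive")
  if (dry_mass_g <= 0) stop_invalid("root dry mass must be positive")
  if (volume_cm3 <= 0) stop_invalid("root volume must be positive")
  total <- sum(class_length_m)
  if (total <= 0) stop_invalid("total root length must be positive")
  if (!is.null(total_length_m) &&
      abs(total_length_m - total) > 1e-9 * max(1, abs(total))) {
    stop_invalid("recorded total length disagrees with class sum")
  }
  if (!is.na(p_concentration_mg_g) && p_concentration_mg_g == 0) {
    stop_invalid("root P concentration of zero leaves RPUE undefined")
  }
  srl <- total / dry_mass_g
  # pi * d[mm] * L[m] is lateral surface in pi*1e-3 m2 = pi/10 dm2
  sra <- sum(pi * class_diameter_mm * class_length_m) / 10 / dry_mass_g
  list(
    diameter_mm = sum(class_diameter_mm * class_length_m) / total,
    srl_m_g = srl,
    rtd_mg_cm3 = 1000 * dry_mass_g / volume_cm3,
    sra_dm2_g = sra,
    very_fine_pct = 100 * sum(class_length_m[class_diameter_mm < very_fine_threshold_mm]) / total,
    rpue_m_mg = if (is.na(p_concentration_mg_g)) NA_real_ else srl / p_concentration_mg_g,
    nodule_investment_g_m = if (is.na(nodule_dry_mass_g)) NA_real_ else nodule_dry_mass_g / total
  )
}

#' Taproot traits
#'
#' Specific taproot length (length per dry mass), taproot tissue density
#' (dry mass per volume, g.cm-3) and the percentage of the root system made
#' of coarse (taproot) tissue.
#'
#' @param taproot_length_m taproot sample length (m).
#' @param taproot_dry_mass_g taproot sample dry mass (g).
#' @param taproot_volume_cm3 taproot sample volume (cm3).
#' @param coarse_mass_g coarse-root (taproot) dry mass of the whole root
#'   system (g).
#' @param total_root_mass_g total root system dry mass (g).
#' @return A list with `strl_m_g`, `trtd_g_cm3`, `taproot_pct`.
#' @export
compute_taproot_traits <- function(taproot_length_m, taproot_dry_mass_g,
                                   taproot_volume_cm3,
                                   coarse_mass_g, total_root_mass_g) {
  if (taproot_dry_mass_g <= 0 || taproot_volume_cm3 <= 0 ||
      total_root_mass_g <= 0) {
    stop_invalid("taproot masses and volume must be positive")
  }
  if (coarse_mass_g < 0) stop_invalid("coarse mass must be non-negative")
  if (coarse_mass_g > total_root_mass_g) {
    stop_invalid("coarse root mass cannot exceed total root mass")
  }
  list(
    strl_m_g = taproot_length_m / taproot_dry_mass_g,
    trtd_g_cm3 = taproot_dry_mass_g / taproot_volume_cm3,
    taproot_pct = 100 * coarse_mass_g / total_root_mass_g
  )
}

#' Depth of 95% of fine root length
#'
#' Fits an ordinary least-squares line to the cumulative fine-root-length
#' profile (cumulative length at the lower boundary of each soil segment)
#' and returns the depth at which the fitted line reaches 95% of the total
#' fine root length.
#'
#' @param segment_boundaries_cm segment boundary depths (cm), strictly
#'   increasing, starting at 0; e.g. `c(0, 20, 40, 60, 80, 100)`.
#' @param fine_root_length_m fine root length per segment (m), one value per
#'   segment.
#' @return Depth (cm) at which the regression line equals 0.95 x total
#'   fine root length.
#' @examples
#' compute_depth95(seq(0, 100, 20), rep(2, 5))  # 95
#' @export
compute_depth95 <- function(segment_boundaries_cm, fine_root_length_m) {
  nb <- length(segment_boundaries_cm)
  if (nb < 3 || length(fine_root_length_m) != nb - 1) {
    stop_invalid("need >= 2 segments and one length per segment")
  }
  if (segment_boundaries_cm[1] != 0 || any(diff(segment_boundaries_cm) <= 0)) {
    stop_invalid("boundaries must start at 0 and be strictly increasing")
  }
  if (any(fine_root_length_m < 0)) stop_invalid("segment lengths must be non-negative")
  total <- sum(fine_root_length_m)
  if (total <= 0) stop_invalid("zero total fine root length: depth95 undefined")
  x <- segment_boundaries_cm[-1]
  y <- cumsum(fine_root_length_m)
  b <- stats::cov(x, y) / stats::var(x)
  if (!is.finite(b) || b == 0) stop_invalid("degenerate profile: zero regression slope")
  a <- mean(y) - b * mean(x)
  (0.95 * total - a) / b
}

#' Root length density
#'
#' Total fine root length (fine root dry mass times SRL) plus taproot length
#' within the pot, per unit pot volume.
#'
#' @param fine_root_mass_g fine root dry mass (g); a vector (per segment) is
#'   summed.
#' @param srl_m_g specific root length of the species (m.g-1).
#' @param taproot_length_cm taproot length within the pot (cm).
#' @param pot_volume_cm3 pot volume (cm3).
#' @return Root length density (cm.cm-3).
#' @export
compute_rld <- function(fine_root_mass_g, srl_m_g, taproot_length_cm,
                        pot_volume_cm3) {
  if (pot_volume_cm3 <= 0) stop_invalid("pot volume must be positive")
  if (any(fine_root_mass_g < 0) || taproot_length_cm < 0 || srl_m_g < 0) {
    stop_invalid("masses and lengths must be non-negative")
  }
  (sum(fine_root_mass_g) * srl_m_g * 100 + taproot_length_cm) / pot_volume_cm3
}

#' Mycorrhization rate from grid-line intersect counts
#'
#' @param amf_intersects number of root-gridline intersects showing
#'   arbuscular mycorrhizal fungal structures.
#' @param total_intersects total number of intersects scored.
#' @return Colonization rate (%).
#' @export
compute_mycorrhization_rate <- function(amf_intersects, total_intersects) {
  if (total_intersects <= 0) stop_invalid("total intersect count must be positive")
  if (amf_intersects < 0 || amf_intersects > total_intersects) {
    stop_invalid("AMF intersects must lie in [0, total]")
  }
  100 * amf_intersects / total_intersects
}

#' Species-level trait summary
#'
#' Per-trait minimum, mean, maximum and coefficient of variation across
#' species, `NA` dropped.  CV is 100 x sample standard deviation / mean.
#'
#' @param table species x trait data.frame or matrix of numeric columns.
#' @return data.frame with columns `trait`, `min`, `mean`, `max`, `cv_pct`,
#'   `n`.  Columns that are entirely `NA` (or have < 2 values) are omitted
#'   and listed in the `"skipped"` attribute.
#' @export
summarize_traits <- function(table) {
  tab <- as.data.frame(table)
  num <- vapply(tab, function(x) is.numeric(x) || all(is.na(x)), logical(1))
  tab <- tab[num]
  rows <- list()
  skipped <- character(0)
  for (nm in names(tab)) {
    v <- tab[[nm]]
    v <- v[!is.na(v)]
    if (length(v) < 2) {
      skipped <- c(skipped, nm)
      next
    }
    m <- mean(v)
    rows[[nm]] <- data.frame(
      trait = nm, min = min(v), mean = m, max = max(v),
      cv_pct = 100 * stats::sd(v) / m, n = length(v),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# Canonical names of the 25 species-level traits handled by the pipeline.
#' Canonical trait names
#'
#' The full set of functional traits the pipeline computes and analyses,
#' in fixed order: fine-root, taproot, whole-root-system, aboveground and
#' whole-plant traits.
#'
#' @return Character vector of 25 trait names.
#' @export
trait_names <- function() {
  c("aerenchyma_pct", "diameter_mm", "hairs_um", "nodule_investment_g_m",
    "mycorrhizal_rate_pct", "rpue_m_mg", "phosphatase_ug_m_h", "rtd_mg_cm3",
    "sra_dm2_g", "srl_m_g", "stele_pct", "very_fine_pct",
    "strl_m_g", "trtd_g_cm3",
    "depth95_cm", "fine_root_biomass_g", "root_system_biomass_g",
    "rld_cm_cm3", "taproot_biomass_g", "taproot_pct",
    "sla_m2_kg", "ldmc_mg_g", "aboveground_biomass_g",
    "root_shoot_ratio", "total_biomass_g")
}

#' Compute the full trait table from raw measurement records
#'
#' Applies every trait calculator to a set of per-species measurement
#' records (as produced in the field/greenhouse, or by
#' [generate_measurement_records()]) and assembles the species x trait
#' table.  Histology- and assay-derived traits (aerenchyma, stele, root
#' hairs, phosphatase activity) and aboveground biomass enter as
#' already-quantified numbers in the `passthrough` component.
#'
#' @param records named list (one element per species), each a list with
#'   components `leaf`, `fine_root`, `taproot`, `depth_profile`,
#'   `intersects`, `passthrough` (see [generate_measurement_records()] for
#'   field layout).
#' @return species x trait data.frame with the 25 columns of
#'   [trait_names()].
#' @export
compute_all_traits <- function(records) {
  stopifnot(is.list(records), length(records) >= 1, !is.null(names(records)))
  rows <- lapply(names(records), function(sp) {
    r <- records[[sp]]
    leaf <- compute_leaf_traits(r$leaf$leaf_area_cm2,
                                r$leaf$leaf_fresh_mass_g,
                                r$leaf$leaf_dry_mass_g)
    fr <- compute_fine_root_traits(
      r$fine_root$class_diameter_mm, r$fine_root$class_length_m,
      dry_mass_g = r$fine_root$dry_mass_g,
      volume_cm3 = r$fine_root$volume_cm3,
      p_concentration_mg_g = r$fine_root$p_concentration_mg_g,
      nodule_dry_mass_g = r$fine_root$nodule_dry_mass_g
    )
    fine_biomass <- sum(r$depth_profile$fine_root_mass_g)
    taproot_biomass <- r$taproot$dry_mass_g
    root_system <- fine_biomass + taproot_biomass
    tp <- compute_taproot_traits(
      r$taproot$length_m, r$taproot$dry_mass_g, r$taproot$volume_cm3,
      coarse_mass_g = taproot_biomass, total_root_mass_g = root_system
    )
    depth95 <- compute_depth95(r$depth_profile$boundaries_cm,
                               r$depth_profile$fine_root_length_m)
    rld <- compute_rld(r$depth_profile$fine_root_mass_g, fr$srl_m_g,
                       r$depth_profile$taproot_length_cm,
                       r$depth_profile$pot_volume_cm3)
    myco <- compute_mycorrhization_rate(r$intersects$amf_intersects,
                                        r$intersects$total_intersects)
    above <- r$passthrough$aboveground_biomass_g
    data.frame(
      aerenchyma_pct = r$passthrough$aerenchyma_pct,
      diameter_mm = fr$diameter_mm,
      hairs_um = r$passthrough$hairs_um,
      nodule_investment_g_m = fr$nodule_investment_g_m,
      mycorrhizal_rate_pct = myco,
      rpue_m_mg = fr$rpue_m_mg,
      phosphatase_ug_m_h = r$passthrough$phosphatase_ug_m_h,
      rtd_mg_cm3 = fr$rtd_mg_cm3,
      sra_dm2_g = fr$sra_dm2_g,
      srl_m_g = fr$srl_m_g,
      stele_pct = r$passthrough$stele_pct,
      very_fine_pct = fr$very_fine_pct,
      strl_m_g = tp$strl_m_g,
      trtd_g_cm3 = tp$trtd_g_cm3,
      depth95_cm = depth95,
      fine_root_biomass_g = fine_biomass,
      root_system_biomass_g = root_system,
      rld_cm_cm3 = rld,
      taproot_biomass_g = taproot_biomass,
      taproot_pct = tp$taproot_pct,
      sla_m2_kg = leaf$sla_m2_kg,
      ldmc_mg_g = leaf$ldmc_mg_g,
      aboveground_biomass_g = above,
      root_shoot_ratio = root_system / above,
      total_biomass_g = root_system + above,
      row.names = sp, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
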