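# End-to-end analysis: trait summary -> phylogeny -> phylogenetic signal ->
# absolute and hierarchical distance matrices -> Mantel grids -> report.

#' Run the full trait / phylogeny / niche-distance analysis
#'
#' Computes, in order: the species-level trait summary; the phylogenetic
#' (patristic) distance matrix (building an NJ tree first when an
#' alignment is supplied); phylogenetic-eigenvector signal tests per
#' trait; Mantel tests of absolute trait distances against phylogenetic
#' distance and against each indicator's absolute distance (one-sided,
#' greater); and Mantel tests of hierarchical trait distances against
#' hierarchical indicator distances (two-sided) for every trait x
#' indicator pair.  Indicator absolute distances are also tested against
#' phylogeny.  Cells whose test cannot be computed (e.g. too few complete
#' pairs) are reported with `NA` and the error message, never dropped
#' silently.
#'
#' One master seed drives every permutation test through a deterministic
#' per-cell sub-seed, so reruns with the same inputs are bit-identical.
#'
#' @param traits species x trait data.frame (numeric columns, `NA`
#'   allowed).
#' @param indicators species x indicator data.frame (numeric, `NA`
#'   allowed).
#' @param tree a `phylo` tree over the same species (mutually exclusive
#'   with `alignment`).
#' @param alignment named character vector of aligned sequences, used to
#'   build an NJ tree via [pairwise_distance()] + [neighbor_joining()].
#' @param n_perm permutations per Mantel test (default 999).
#' @param seed master seed (default 1).
#' @param tail_absolute tail for absolute-distance tests (default
#'   `"greater"`).
#' @param tail_hierarchical tail for hierarchical tests (default
#'   `"two_sided"`).
#' @param axis_rule eigenvector retention rule for the signal tests
#'   (`"broken_stick"` or `"first_k"`); when broken-stick retains no axis
#'   the leading positive axis is used.
#' @param k number of axes for `axis_rule = "first_k"`.
#' @param alpha significance level for starring (default 0.05).
#' @param na_policy `"pairwise"` (default: each test keeps its complete
#'   pairs) or `"listwise"` (species with any missing indicator are
#'   dropped from all matrices first).
#' @param p_adjust `"none"` (default) or `"holm"`, applied within each
#'   Mantel grid.
#' @param distance_model model for [pairwise_distance()] when an
#'   alignment is given.
#' @return An object of class `niche_report`; see [render_report()].
#' @export
run_analysis <- function(traits, indicators, tree = NULL, alignment = NULL,
                         n_perm = 999, seed = 1,
                         tail_absolute = "greater",
                         tail_hierarchical = "two_sided",
                         axis_rule = "broken_stick", k = NULL,
                         alpha = 0.05, na_policy = c("pairwise", "listwise"),
                         p_adjust = c("none", "holm"),
                         distance_model = "p") {
  na_policy <- match.arg(na_policy)
  p_adjust <- match.arg(p_adjust)
  traits <- as.data.frame(traits)
  indicators <- as.data.frame(indicators)
  if (is.null(tree) == is.null(alignment)) {
    stop_invalid("supply exactly one of tree or alignment")
  }
  if (!is.null(alignment)) {
    tree <- neighbor_joining(pairwise_distance(alignment, distance_model))
  }
  species <- rownames(traits)
  if (length(species) < 4) stop_invalid("need >= 4 species")
  for (other in list(indicators = rownames(indicators),
                     tree = tree$tip.label)) {
    bad <- union(setdiff(species, other), setdiff(other, species))
    if (length(bad)) {
      stop_invalid("species sets disagree; offending IDs: ",
                   paste(bad, collapse = ", "))
    }
  }
  indicators <- indicators[species, , drop = FALSE]
  if (na_policy == "listwise") {
    keep <- species[stats::complete.cases(indicators)]
    if (length(keep) < 4) stop_invalid("listwise deletion leaves < 4 species")
    traits <- traits[keep, , drop = FALSE]
    indicators <- indicators[keep, , drop = FALSE]
    tree <- ape::keep.tip(tree, keep)
    species <- keep
  }

  summary_tab <- summarize_traits(traits)
  phylo_d <- patristic_matrix(tree)[species, species]
  attr(phylo_d, "signed") <- FALSE

  # phylogenetic signal per trait
  basis <- pcoa_axes(phylo_d)
  axes <- select_axes(basis, rule = axis_rule, k = k)
  axes_note <- ""
  if (length(axes) == 0) {
    axes <- basis$positive[1]
    axes_note <- "broken-stick retained no axis; leading positive axis used"
  }
  signal <- do.call(rbind, lapply(names(traits), function(tr) {
    res <- tryCatch(phylo_signal_anova(stats::setNames(traits[[tr]], species),
                                       basis, axes),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(trait = tr, F = NA_real_, df1 = NA_integer_,
                 df2 = NA_integer_, p = NA_real_, r_squared = NA_real_,
                 n = NA_integer_, note = res, stringsAsFactors = FALSE)
    } else {
      data.frame(trait = tr, F = res$F, df1 = res$df1, df2 = res$df2,
                 p = res$p, r_squared = res$r_squared, n = res$n,
                 note = res$flag, stringsAsFactors = FALSE)
    }
  }))
  signal$stars <- p_stars(signal$p)

  # distance matrices per trait / indicator
  abs_or_msg <- function(v) tryCatch(absolute_matrix(v),
                                     error = function(e) conditionMessage(e))
  hier_or_msg <- function(v) tryCatch(hierarchical_matrix(v),
                                      error = function(e) conditionMessage(e))
  tr_abs <- lapply(traits, function(v) abs_or_msg(stats::setNames(v, species)))
  tr_hier <- lapply(traits, function(v) hier_or_msg(stats::setNames(v, species)))
  in_abs <- lapply(indicators, function(v) abs_or_msg(stats::setNames(v, species)))
  in_hier <- lapply(indicators, function(v) hier_or_msg(stats::setNames(v, species)))

  cell <- function(x, y, tail, sub_seed) {
    if (is.character(x)) return(list(r = NA, p = NA, n_pairs = NA, note = x))
    if (is.character(y)) return(list(r = NA, p = NA, n_pairs = NA, note = y))
    res <- tryCatch(mantel_test(x, y, n_perm = n_perm, tail = tail,
                                seed = sub_seed),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) return(list(r = NA, p = NA, n_pairs = NA, note = res))
    list(r = res$r, p = res$p, n_pairs = res$n_pairs, note = "")
  }
  counter <- 0L
  grid_rows <- list()
  add_row <- function(grid, trait, indicator, tail, x, y) {
    counter <<- counter + 1L
    res <- cell(x, y, tail, derive_seed(seed, counter))
    grid_rows[[length(grid_rows) + 1L]] <<- data.frame(
      grid = grid, trait = trait, indicator = indicator, tail = tail,
      r = res$r, p = res$p, n_pairs = res$n_pairs, note = res$note,
      stringsAsFactors = FALSE)
  }
  for (tr in names(traits)) {
    add_row("absolute", tr, "phylogeny", tail_absolute, tr_abs[[tr]], phylo_d)
    for (ind in names(indicators)) {
      add_row("absolute", tr, ind, tail_absolute, tr_abs[[tr]], in_abs[[ind]])
    }
  }
  for (ind in names(indicators)) {
    add_row("indicator_absolute", ind, "phylogeny", tail_absolute,
            in_abs[[ind]], phylo_d)
  }
  for (tr in names(traits)) {
    for (ind in names(indicators)) {
      add_row("hierarchical", tr, ind, tail_hierarchical,
              tr_hier[[tr]], in_hier[[ind]])
    }
  }
  long <- do.call(rbind, grid_rows)
  if (p_adjust == "holm") {
    for (g in unique(long$grid)) {
      sel <- long$grid == g
      long$p[sel] <- stats::p.adjust(long$p[sel], method = "holm")
    }
  }
  long$stars <- p_stars(long$p)

  structure(list(
    trait_summary = summary_tab,
    signal = signal,
    mantel_long = long,
    tree = tree,
    meta = list(seed = seed, n_perm = n_perm, alpha = alpha,
                tail_absolute = tail_absolute,
                tail_hierarchical = tail_hierarchical,
                axis_rule = axis_rule, retained_axes = axes,
                axes_note = axes_note, na_policy = na_policy,
                p_adjust = p_adjust,
                n_species = length(species),
                package_version = as.character(utils::packageVersion("nichedist")))
  ), class = "niche_report")
}

# wide r-with-stars grid from the long table
grid_wide <- function(long, grid_name) {
  sub <- long[long$grid == grid_name, , drop = FALSE]
  traits <- unique(sub$trait)
  cols <- unique(sub$indicator)
  out <- data.frame(trait = traits, stringsAsFactors = FALSE)
  for (cn in cols) {
    vals <- vapply(traits, function(tr) {
      row <- sub[sub$trait == tr & sub$indicator == cn, ]
      if (!nrow(row) || is.na(row$r[1])) return(NA_character_)
      paste0(formatC(row$r[1], digits = 3, format = "f"), row$stars[1])
    }, character(1))
    out[[cn]] <- vals
  }
  out
}

#' Write the analysis report to disk
#'
#' Writes `summary.csv` (trait summary), `signal.csv` (phylogenetic
#' signal tests), `mantel_absolute.csv` and `mantel_hierarchical.csv`
#' (wide grids of r values with significance stars at 0.05/0.01/0.001),
#' `mantel_long.csv` (r, p, n_pairs, tail, notes for every attempted
#' cell), `tree.nwk`, `run_metadata.json`, and `run_log.txt`.
#'
#' @param report a `niche_report` from [run_analysis()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, out_dir) {
  if (!inherits(report, "niche_report")) stop_invalid("not a niche_report")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_invalid("cannot create output directory ", out_dir)
  }
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "NA")
    paths <<- c(paths, p)
  }
  wr(report$trait_summary, "summary.csv")
  wr(report$signal, "signal.csv")
  wr(grid_wide(report$mantel_long, "absolute"), "mantel_absolute.csv")
  wr(grid_wide(report$mantel_long, "hierarchical"), "mantel_hierarchical.csv")
  wr(report$mantel_long, "mantel_long.csv")
  tp <- file.path(out_dir, "tree.nwk")
  ape::write.tree(report$tree, tp)
  paths <- c(paths, tp)
  mp <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(report$meta, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, mp)
  lp <- file.path(out_dir, "run_log.txt")
  notes <- report$mantel_long[report$mantel_long$note != "", , drop = FALSE]
  log_lines <- c(
    sprintf("species: %d", report$meta$n_species),
    sprintf("permutations per test: %d", report$meta$n_perm),
    sprintf("retained eigenvector axes: %s",
            paste(report$meta$retained_axes, collapse = ", ")),
    if (nzchar(report$meta$axes_note)) report$meta$axes_note,
    sprintf("mantel cells attempted: %d", nrow(report$mantel_long)),
    sprintf("mantel cells unavailable: %d", nrow(notes)),
    if (nrow(notes)) paste0("  ", notes$grid, " ", notes$trait, " x ",
                            notes$indicator, ": ", notes$note)
  )
  writeLines(log_lines, lp)
  paths <- c(paths, lp)
  invisible(paths)
}

#' @export
print.niche_report <- function(x, ...) {
  cat("Niche-distance analysis report\n")
  cat(sprintf("  %d species, %d traits, %d indicators; %d permutations/test\n",
              x$meta$n_species, nrow(x$signal),
              length(unique(x$mantel_long$indicator[x$mantel_long$grid == "hierarchical"])),
              x$meta$n_perm))
  sig <- x$signal[!is.na(x$signal$p) & x$signal$p < x$meta$alpha, "trait"]
  cat("  traits with phylogenetic signal:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  hier <- x$mantel_long[x$mantel_long$grid == "hierarchical", ]
  cat(sprintf("  significant hierarchical cells: %d of %d\n",
              sum(!is.na(hier$p) & hier$p < x$meta$alpha), nrow(hier)))
  invisible(x)
}
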