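# Pairwise distance matrices over species for a single trait or ecological
# indicator: absolute |tA - tB| (symmetric) and hierarchical tA - tB
# (anti-symmetric, sign carries direction along the gradient).

check_values <- function(values) {
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop_invalid("values must be uniquely named by species")
  }
  if (sum(!is.na(values)) < 3) {
    stop_invalid("need >= 3 species with non-NA values")
  }
  invisible(values)
}

#' Absolute pairwise distance matrix
#'
#' `M[i, j] = |v_i - v_j|`; `NA` wherever either species' value is missing
#' (diagonal kept at zero).
#'
#' @param values named numeric vector (names = species), `NA` allowed.
#' @return Symmetric species x species matrix, attribute `signed = FALSE`.
#' @export
absolute_matrix <- function(values) {
  check_values(values)
  m <- abs(outer(values, values, "-"))
  diag(m) <- 0
  dimnames(m) <- list(names(values), names(values))
  attr(m, "signed") <- FALSE
  m
}

#' Hierarchical (signed) pairwise distance matrix
#'
#' `M[i, j] = v_i - v_j`, an anti-symmetric matrix whose sign records which
#' species has the larger value; its elementwise absolute value equals
#' [absolute_matrix()].
#'
#' @inheritParams absolute_matrix
#' @return Anti-symmetric species x species matrix, attribute
#'   `signed = TRUE`.
#' @export
hierarchical_matrix <- function(values) {
  check_values(values)
  m <- outer(values, values, "-")
  diag(m) <- 0
  dimnames(m) <- list(names(values), names(values))
  attr(m, "signed") <- TRUE
  m
}

#' Vectorize the pair entries of a distance matrix
#'
#' Deterministic row-major extraction of pair entries, excluding `NA`
#' pairs.  `"upper"` takes each unordered pair once (i < j), appropriate
#' for symmetric matrices; `"all_offdiag"` takes both orientations,
#' required for anti-symmetric matrices (their pair vector then sums to
#' zero and is invariant to species relabeling).
#'
#' @param m species x species matrix.
#' @param mode `"upper"` or `"all_offdiag"`.
#' @param mask optional 2-column matrix of (row, col) index pairs to keep.
#' @return List with `values`, `pairs` (2-column index matrix aligned with
#'   `values`), and `n_dropped` (unordered pairs lost to `NA`).
#' @export
vectorize_pairs <- function(m, mode = c("upper", "all_offdiag"), mask = NULL) {
  mode <- match.arg(mode)
  check_square_named(m, "matrix")
  n <- nrow(m)
  idx <- which(if (mode == "upper") upper.tri(m) else row(m) != col(m))
  # row-major ordering
  ii <- row(m)[idx]; jj <- col(m)[idx]
  ord <- order(ii, jj)
  ii <- ii[ord]; jj <- jj[ord]
  if (!is.null(mask)) {
    keykeep <- paste(mask[, 1], mask[, 2])
    sel <- paste(ii, jj) %in% keykeep
    ii <- ii[sel]; jj <- jj[sel]
  }
  v <- m[cbind(ii, jj)]
  drop <- is.na(v)
  n_dropped <- if (mode == "upper") sum(drop) else sum(drop) / 2
  ii <- ii[!drop]; jj <- jj[!drop]; v <- v[!drop]
  n_pairs <- if (mode == "upper") length(v) else length(v) / 2
  if (n_pairs < 3) stop_invalid("fewer than 3 complete pairs after masking")
  list(values = v, pairs = cbind(ii, jj), n_dropped = n_dropped)
}
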