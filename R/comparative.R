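# Phylogenetic-eigenvector analysis of trait values (PVR-style): principal
# coordinates of the patristic distance matrix, eigenvalue-based axis
# retention, and an F-test of each trait regressed on the retained axes.

#' Principal coordinates of a distance matrix
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition.
#' Eigenvector columns are unit-norm and sign-canonicalized (largest
#' absolute loading positive) so results do not depend on species input
#' order beyond a row permutation.
#'
#' @param d complete symmetric species x species distance matrix.
#' @return An object of class `phylo_eigen`: list with `values` (descending
#'   eigenvalues), `vectors` (species x axis, unit-norm columns), and
#'   `positive` (indices of axes with eigenvalue > 0, the only ones
#'   eligible for retention).
#' @export
pcoa_axes <- function(d) {
  check_square_named(d, "distance matrix")
  if (anyNA(d)) stop_invalid("distance matrix contains NA")
  n <- nrow(d)
  if (n < 3) stop_invalid("need >= 3 species")
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (d * d) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vec <- e$vectors
  # canonical sign: largest-magnitude loading positive
  for (k in seq_len(ncol(vec))) {
    piv <- which.max(abs(vec[, k]))
    if (vec[piv, k] < 0) vec[, k] <- -vec[, k]
  }
  rownames(vec) <- rownames(d)
  colnames(vec) <- paste0("axis", seq_len(ncol(vec)))
  tol <- max(abs(e$values)) * 1e-10
  structure(list(values = e$values, vectors = vec,
                 positive = which(e$values > tol)),
            class = "phylo_eigen")
}

#' @export
print.phylo_eigen <- function(x, ...) {
  cat("Principal-coordinate basis:", nrow(x$vectors), "species,",
      length(x$positive), "positive axes\n")
  cat("Leading eigenvalues:",
      paste(signif(utils::head(x$values, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Select eigenvector axes for signal analysis
#'
#' `broken_stick` retains the leading axes whose share of the
#' positive-eigenvalue total exceeds the broken-stick expectation
#' `b_k = (1/p) * sum(1/(k:p))`, stopping at the first axis that falls
#' below its stick; `first_k` retains the `k` leading positive axes.
#'
#' @param basis a `phylo_eigen` object from [pcoa_axes()].
#' @param rule `"broken_stick"` (default) or `"first_k"`.
#' @param k number of axes when `rule = "first_k"`.
#' @return Integer vector of retained axis indices (possibly empty for
#'   `broken_stick` when no axis beats its expectation).
#' @export
select_axes <- function(basis, rule = c("broken_stick", "first_k"), k = NULL) {
  rule <- match.arg(rule)
  if (!inherits(basis, "phylo_eigen")) stop_invalid("basis must come from pcoa_axes()")
  pos <- basis$positive
  p <- length(pos)
  if (p < 1) stop_invalid("no positive eigenvalues")
  if (rule == "first_k") {
    if (is.null(k) || k < 1) stop_invalid("first_k needs k >= 1")
    if (k > p) stop_invalid("k exceeds the number of positive axes (", p, ")")
    return(pos[seq_len(k)])
  }
  ev <- basis$values[pos]
  rel <- ev / sum(ev)
  bstick <- rev(cumsum(1 / rev(seq_len(p)))) / p
  # leading run only: stop at the first axis that falls below its stick,
  # so a flat spectrum retains nothing
  ok <- rel > bstick
  k0 <- if (all(ok)) p else which(!ok)[1] - 1L
  pos[seq_len(k0)]
}

#' Phylogenetic signal by eigenvector variance analysis
#'
#' Least-squares regression of a trait on retained phylogenetic
#' eigenvectors (with intercept), reported as an overall F-test: a
#' significant fit means trait variation follows the phylogenetic
#' structure captured by the axes.  Species with `NA` trait values are
#' dropped from this trait's fit only.
#'
#' @param trait named numeric vector of trait values (names = species,
#'   matching the basis rows).
#' @param basis a `phylo_eigen` object.
#' @param axes integer vector of axis indices (e.g. from [select_axes()]).
#' @return An object of class `signal_result`: list with `trait`
#'   (name, if the vector carried one as an attribute), `F`, `df1`, `df2`,
#'   `p`, `r_squared`, `n`, and `flag` (`""`, or `"constant_trait"` when F
#'   is undefined).  A perfect fit reports `F = Inf`, `p = 0`.
#' @export
phylo_signal_anova <- function(trait, basis, axes) {
  if (!inherits(basis, "phylo_eigen")) stop_invalid("basis must come from pcoa_axes()")
  if (length(axes) < 1) stop_invalid("need >= 1 retained axis")
  sp <- rownames(basis$vectors)
  if (is.null(names(trait)) || !all(names(trait) %in% sp)) {
    stop_invalid("trait must be named by species present in the basis")
  }
  keep <- names(trait)[!is.na(trait)]
  n <- length(keep)
  k <- length(axes)
  if (n < k + 2) stop_invalid("insufficient species (", n, ") for ", k, " axes")
  y <- trait[keep]
  X <- cbind(1, basis$vectors[keep, axes, drop = FALSE])
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    return(structure(list(F = NA_real_, df1 = k, df2 = n - k - 1,
                          p = NA_real_, r_squared = NA_real_, n = n,
                          flag = "constant_trait"),
                     class = "signal_result"))
  }
  fit <- stats::lm.fit(X, y)
  ssr <- sum(fit$residuals^2)
  ssm <- sst - ssr
  df1 <- k
  df2 <- n - k - 1
  if (ssr <= 1e-12 * sst) {
    Fv <- Inf; pv <- 0; r2 <- 1
  } else {
    Fv <- (ssm / df1) / (ssr / df2)
    if (Fv < 0) Fv <- 0
    pv <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    r2 <- ssm / sst
  }
  structure(list(F = Fv, df1 = df1, df2 = df2, p = pv, r_squared = r2,
                 n = n, flag = ""),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  if (identical(x$flag, "constant_trait")) {
    cat("Phylogenetic signal: constant trait, F undefined\n")
  } else {
    cat(sprintf("Phylogenetic signal: F(%d, %d) = %.3f, p = %.4g, R2 = %.3f (n = %d)\n",
                x$df1, x$df2, x$F, x$p, x$r_squared, x$n))
  }
  invisible(x)
}
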