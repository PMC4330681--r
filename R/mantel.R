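# Mantel statistic and permutation test for symmetric and anti-symmetric
# (hierarchical) distance matrices, with exact enumeration for small
# species sets.
#
# The statistic is the Pearson correlation of the two matrices' aligned
# pair vectors.  For anti-symmetric matrices the full off-diagonal is used:
# each unordered pair contributes +x and -x, so both vectors are exactly
# centred and the statistic does not depend on species ordering.  The null
# distribution permutes species labels, i.e. rows and columns of one
# matrix jointly, which preserves (anti-)symmetry.

# Fast Pearson correlation; NA_real_ when either vector is constant.
pearson_or_na <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sa <- sum(am * am); sb <- sum(bm * bm)
  if (sa <= 0 || sb <= 0) return(NA_real_)
  sum(am * bm) / sqrt(sa * sb)
}

# Align y to x's species order; decide vectorization mode; extract pair
# indices once.  Returns the state shared by mantel_r / mantel_test.
mantel_prepare <- function(x, y, mode = NULL) {
  check_square_named(x, "x"); check_square_named(y, "y")
  if (!setequal(rownames(x), rownames(y))) {
    stop_invalid("x and y must cover the same species; differ by: ",
                 paste(union(setdiff(rownames(x), rownames(y)),
                             setdiff(rownames(y), rownames(x))), collapse = ", "))
  }
  y <- y[rownames(x), rownames(x)]
  signed <- is_signed_dist(x) || is_signed_dist(y)
  if (is.null(mode)) {
    mode <- if (signed) "all_offdiag" else "upper"
  } else {
    mode <- match.arg(mode, c("upper", "all_offdiag"))
    if (signed && mode == "upper") {
      stop_invalid("signed (anti-symmetric) matrices require mode = \"all_offdiag\"")
    }
  }
  n <- nrow(x)
  if (mode == "upper") {
    ut <- which(upper.tri(x))
    ii <- row(x)[ut]; jj <- col(x)[ut]
  } else {
    od <- which(row(x) != col(x))
    ii <- row(x)[od]; jj <- col(x)[od]
  }
  ord <- order(ii, jj)
  list(y = y, mode = mode, ii = ii[ord], jj = jj[ord],
       xv = x[cbind(ii[ord], jj[ord])], n = n)
}

# r over complete pairs for a given relabeling `perm` of y's species.
mantel_r_perm <- function(st, perm) {
  yv <- st$y[cbind(perm[st$ii], perm[st$jj])]
  keep <- !is.na(st$xv) & !is.na(yv)
  np <- if (st$mode == "upper") sum(keep) else sum(keep) / 2
  if (np < 3) return(list(r = NA_real_, n_pairs = np))
  list(r = pearson_or_na(st$xv[keep], yv[keep]), n_pairs = np)
}

#' Mantel correlation statistic
#'
#' Pearson correlation between the aligned pair vectors of two distance
#' matrices over the same species, using pairwise-complete pairs.
#'
#' @param x,y species x species distance matrices (symmetric, or
#'   anti-symmetric as from [hierarchical_matrix()]); species sets must
#'   match (order may differ).
#' @param mode `"upper"` (each unordered pair once) or `"all_offdiag"`
#'   (both orientations).  Defaults to `"upper"` for two symmetric
#'   matrices and is forced to `"all_offdiag"` when either matrix is
#'   anti-symmetric.
#' @return The correlation (a scalar in `[-1, 1]`).  Errors if fewer than
#'   3 complete pairs remain or either pair vector is constant.
#' @export
mantel_r <- function(x, y, mode = NULL) {
  st <- mantel_prepare(x, y, mode)
  res <- mantel_r_perm(st, seq_len(st$n))
  if (res$n_pairs < 3) stop_invalid("fewer than 3 complete pairs")
  if (is.na(res$r)) stop_invalid("undefined statistic: zero variance in a pair vector")
  res$r
}

#' Mantel permutation test
#'
#' Tests the Mantel correlation against the null distribution obtained by
#' jointly permuting the rows and columns of `y` (uniform random species
#' relabelings).  The p-value uses the add-one rule
#' `p = (1 + #extreme) / (n_perm + 1)`, so it is never zero.  `NA`
#' masking is re-applied to every permuted matrix, mirroring
#' pairwise-complete deletion.
#'
#' @inheritParams mantel_r
#' @param n_perm number of random permutations (default 999).
#' @param tail `"greater"`, `"less"` or `"two_sided"`.  Defaults to
#'   `"greater"` for symmetric (absolute) matrices — the working
#'   hypothesis being a more positive correlation than chance — and
#'   `"two_sided"` for hierarchical matrices, where either sign is
#'   meaningful.
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `mantel_result`: list with `r`, `p`, `tail`,
#'   `n_perm` (non-degenerate permutations used), `n_pairs`, `mode`,
#'   `seed`.
#' @export
mantel_test <- function(x, y, n_perm = 999, tail = NULL, seed = NULL,
                        mode = NULL) {
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  st <- mantel_prepare(x, y, mode)
  if (is.null(tail)) {
    tail <- if (st$mode == "all_offdiag") "two_sided" else "greater"
  }
  tail <- match.arg(tail, c("two_sided", "greater", "less"))
  obs <- mantel_r_perm(st, seq_len(st$n))
  if (obs$n_pairs < 3) stop_invalid("fewer than 3 complete pairs")
  if (is.na(obs$r)) stop_invalid("undefined statistic: zero variance in a pair vector")
  if (!is.null(seed)) set.seed(seed)
  rs <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    rs[b] <- mantel_r_perm(st, sample.int(st$n))$r
  }
  degenerate <- is.na(rs)
  rs <- rs[!degenerate]
  used <- length(rs)
  if (used == 0) stop_invalid("all permutations degenerate")
  count <- switch(tail,
                  greater   = sum(rs >= obs$r),
                  less      = sum(rs <= obs$r),
                  two_sided = sum(abs(rs) >= abs(obs$r)))
  structure(list(r = obs$r, p = (1 + count) / (used + 1), tail = tail,
                 n_perm = used, n_pairs = obs$n_pairs, mode = st$mode,
                 seed = seed, n_degenerate = sum(degenerate)),
            class = "mantel_result")
}

# All n! permutations of 1..n as rows (n <= 8).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    out[[k]] <- cbind(k, p + (p >= k), deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Exact Mantel permutation test
#'
#' Enumerates all `n!` species relabelings (feasible for n <= 8), giving
#' the exact permutation p-value.  The identity permutation is part of the
#' reference set, so `p >= 1/n!`.
#'
#' @inheritParams mantel_test
#' @return A `mantel_result` with `n_perm = n!` (minus degenerate
#'   relabelings, if any).
#' @export
mantel_exact <- function(x, y, tail = NULL, mode = NULL) {
  st <- mantel_prepare(x, y, mode)
  if (st$n > 8) stop_invalid("exact enumeration limited to n <= 8 species")
  if (is.null(tail)) {
    tail <- if (st$mode == "all_offdiag") "two_sided" else "greater"
  }
  tail <- match.arg(tail, c("two_sided", "greater", "less"))
  obs <- mantel_r_perm(st, seq_len(st$n))
  if (obs$n_pairs < 3) stop_invalid("fewer than 3 complete pairs")
  if (is.na(obs$r)) stop_invalid("undefined statistic: zero variance in a pair vector")
  perms <- all_permutations(st$n)
  rs <- apply(perms, 1, function(p) mantel_r_perm(st, p)$r)
  rs <- rs[!is.na(rs)]
  count <- switch(tail,
                  greater   = sum(rs >= obs$r),
                  less      = sum(rs <= obs$r),
                  two_sided = sum(abs(rs) >= abs(obs$r)))
  structure(list(r = obs$r, p = count / length(rs), tail = tail,
                 n_perm = length(rs), n_pairs = obs$n_pairs, mode = st$mode,
                 seed = NULL, n_degenerate = nrow(perms) - length(rs)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %s): r = %.4f, p = %.4g (%d permutations, %d pairs)\n",
              x$mode, x$tail, x$r, x$p, x$n_perm, x$n_pairs))
  invisible(x)
}
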