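# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Consistent error signalling without call noise.
stop_invalid <- function(...) stop(..., call. = FALSE)

# Derive a reproducible sub-seed from a master seed and an integer offset.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483647L)
}

# Significance stars at the conventional 0.05 / 0.01 / 0.001 thresholds.
p_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05]  <- "*"
  out[!is.na(p) & p < 0.01]  <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

# Validate a species-labelled square numeric matrix; returns it invisibly.
check_square_named <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_invalid(what, " must be a numeric matrix")
  }
  if (nrow(m) != ncol(m)) stop_invalid(what, " must be square")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_invalid(what, " must have species IDs as dimnames")
  }
  if (!identical(rownames(m), colnames(m))) {
    stop_invalid(what, " row and column names must match")
  }
  invisible(m)
}

# A distance matrix is either symmetric (absolute/phylogenetic) or
# anti-symmetric (hierarchical).  Constructors tag their output; untagged
# matrices are classified numerically.
is_signed_dist <- function(m, tol = 1e-8) {
  s <- attr(m, "signed")
  if (!is.null(s)) return(isTRUE(s))
  sym  <- max(abs(m - t(m)), na.rm = TRUE) <= tol * max(1, max(abs(m), na.rm = TRUE))
  anti <- max(abs(m + t(m)), na.rm = TRUE) <= tol * max(1, max(abs(m), na.rm = TRUE))
  if (sym) return(FALSE)
  if (anti) return(TRUE)
  stop_invalid("matrix is neither symmetric nor anti-symmetric")
}
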