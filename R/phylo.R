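# Phylogeny estimation: pairwise sequence distances, neighbor-joining,
# bootstrap supports and patristic distances.  Trees are ape "phylo"
# objects throughout.

#' Read an aligned FASTA file
#'
#' Accepts wrapped lines and lower-case bases; sequences are upper-cased.
#'
#' @param path FASTA file of aligned sequences.
#' @return Named character vector of equal-length sequences.
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(dna), paste0, "", collapse = ""))
  validate_alignment(seqs)
  seqs
}

validate_alignment <- function(seqs) {
  if (length(seqs) < 3) stop_invalid("alignment needs >= 3 taxa")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop_invalid("taxa must be uniquely named")
  }
  if (length(unique(nchar(seqs))) != 1) {
    stop_invalid("sequences must be aligned (equal length)")
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop_invalid("unexpected characters in sequences of: ",
                 paste(names(seqs)[bad], collapse = ", "))
  }
  invisible(seqs)
}

#' Pairwise genetic distances from an alignment
#'
#' Computes uncorrected p-distances or Kimura two-parameter (K2P) distances
#' with pairwise deletion: for each pair, alignment columns where either
#' sequence has a gap or `N` are dropped before counting differences.
#'
#' @param seqs named character vector of aligned sequences over
#'   `A,C,G,T,-,N` (as from [read_alignment()]).
#' @param model `"p"` (default) for the proportion of differing sites, or
#'   `"K2P"` for the Kimura (1980) correction from transition and
#'   transversion proportions.
#' @return Symmetric species x species distance matrix, zero diagonal.
#' @export
pairwise_distance <- function(seqs, model = c("p", "K2P")) {
  model <- match.arg(model)
  validate_alignment(seqs)
  taxa <- names(seqs)
  n <- length(seqs)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  ok <- lapply(chars, function(x) x %in% c("A", "C", "G", "T"))
  purine <- lapply(chars, function(x) x %in% c("A", "G"))
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- ok[[i]] & ok[[j]]
      L <- sum(use)
      if (L == 0) {
        stop_invalid("no comparable sites between ", taxa[i], " and ", taxa[j])
      }
      a <- chars[[i]][use]
      b <- chars[[j]][use]
      diff <- a != b
      if (model == "p") {
        dij <- sum(diff) / L
      } else {
        ts <- sum(diff & (purine[[i]][use] == purine[[j]][use]))
        P <- ts / L
        Q <- (sum(diff) - ts) / L
        w1 <- 1 - 2 * P - Q
        w2 <- 1 - 2 * Q
        if (w1 <= 0 || w2 <= 0) {
          stop_invalid("K2P distance undefined for ", taxa[i], " vs ", taxa[j],
                       " (too divergent); consider model = \"p\"")
        }
        dij <- -0.5 * log(w1) - 0.25 * log(w2)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree estimation
#'
#' Saitou & Nei agglomeration with the rate-corrected Q-criterion.  At each
#' step the pair minimizing `Q[i,j] = (m-2) d[i,j] - r[i] - r[j]` is joined
#' (ties broken at the lowest row, then column, index for determinism).
#' Negative branch-length estimates are clamped to zero; the total clamped
#' amount is recorded in the `"clamped"` attribute of the returned tree.
#' For an additive input matrix the patristic distances of the result
#' reproduce the input exactly (up to floating error).
#'
#' @param d symmetric species x species distance matrix, zero diagonal,
#'   non-negative, >= 3 taxa.
#' @return Unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  check_square_named(d, "distance matrix")
  n <- nrow(d)
  if (n < 3) stop_invalid("neighbor joining needs >= 3 taxa")
  if (anyNA(d)) stop_invalid("distance matrix contains NA")
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d)))) {
    stop_invalid("distance matrix must be symmetric")
  }
  if (any(diag(d) != 0)) stop_invalid("distance matrix diagonal must be zero")
  if (any(d < 0)) stop_invalid("distances must be non-negative")

  labels <- rownames(d)
  # Working copy grows one row/col per internal node; `active` indexes the
  # current cluster set, `node_id` its phylo node id.  Tips are 1..n; the
  # final join point is n+1 (the root of the unrooted representation),
  # internal nodes created along the way take n+2, n+3, ...
  size <- 2 * n - 2
  D <- matrix(0, size, size)
  D[1:n, 1:n] <- d
  active <- 1:n
  node_id <- integer(size)
  node_id[1:n] <- 1:n
  next_row <- n + 1L
  next_internal <- n + 2L
  parent <- integer(0); child <- integer(0); blen <- numeric(0)
  clamped <- 0

  while (length(active) > 3) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest (row, col) among ties, row-major
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    dij <- Dm[i, j]
    vi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- dij - vi
    if (vi < 0) { clamped <- clamped - vi; vi <- 0 }
    if (vj < 0) { clamped <- clamped - vj; vj <- 0 }
    new_id <- next_internal; next_internal <- next_internal + 1L
    parent <- c(parent, new_id, new_id)
    child <- c(child, node_id[active[i]], node_id[active[j]])
    blen <- c(blen, vi, vj)
    # distances from the new cluster to the remaining ones
    rest <- active[-c(i, j)]
    newd <- (D[active[i], rest] + D[active[j], rest] - dij) / 2
    row <- next_row; next_row <- next_row + 1L
    D[row, rest] <- newd
    D[rest, row] <- newd
    node_id[row] <- new_id
    active <- c(rest, row)
  }

  # final three clusters join at the central node (three-taxon closed form)
  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  vb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  vc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  for (v in c(va, vb, vc)) if (v < 0) clamped <- clamped - v
  centre <- n + 1L
  parent <- c(parent, centre, centre, centre)
  child <- c(child, node_id[a], node_id[b], node_id[c3])
  blen <- c(blen, max(va, 0), max(vb, 0), max(vc, 0))

  tr <- build_phylo(parent, child, blen, labels, root = centre)
  attr(tr, "clamped") <- clamped
  tr
}

# Assemble a valid ape phylo from parent/child edge lists, renumbering
# internal nodes in preorder from the root.
build_phylo <- function(parent, child, blen, labels, root) {
  n <- length(labels)
  n_internal <- length(unique(parent))
  kids <- split(seq_along(parent), parent)
  new_id <- integer(max(c(parent, child)))
  new_id[1:n] <- 1:n
  # preorder walk assigning internal ids n+1, n+2, ...
  counter <- n
  order_edges <- integer(0)
  stack <- root
  while (length(stack)) {
    node <- stack[[1]]; stack <- stack[-1]
    counter <- counter + 1L
    new_id[node] <- counter
    es <- kids[[as.character(node)]]
    order_edges <- c(order_edges, es)
    ch <- child[es]
    stack <- c(ch[ch > n], stack)  # depth-first
  }
  edge <- cbind(new_id[parent[order_edges]], new_id[child[order_edges]])
  tr <- structure(list(edge = edge,
                       edge.length = blen[order_edges],
                       tip.label = labels,
                       Nnode = n_internal),
                  class = "phylo")
  attr(tr, "order") <- "cladewise"
  tr
}

#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' leaves i and j.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return Symmetric species x species matrix, zero diagonal, rows/columns
#'   in `tree$tip.label` order.
#' @export
patristic_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) stop_invalid("tree must be a phylo object")
  if (is.null(tree$edge.length)) stop_invalid("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    stop_invalid("missing branch length on edge ", tree$edge[bad, 1], "-",
                 tree$edge[bad, 2])
  }
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}

# Canonical keys for the non-trivial bipartitions (splits) of an unrooted
# tree; each internal edge contributes one split, identified by the sorted
# tip labels on the side containing the alphabetically first label.
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n + po$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  anchor <- min(tree$tip.label)
  keys <- character(0)
  nodes <- integer(0)
  root <- n + 1L
  for (node in seq.int(n + 1L, n + po$Nnode)) {
    if (node == root) next
    side <- sets[[node]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (!(anchor %in% side)) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, node)
  }
  list(keys = keys, nodes = nodes)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and scores each internal split of the point-estimate tree by
#' the percentage of replicate trees containing it.  Replicates in which
#' some pair has no comparable sites are dropped (and counted in the
#' `"dropped_replicates"` attribute).
#'
#' @param seqs named character vector of aligned sequences.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed optional integer seed for reproducible resampling.
#' @param model distance model passed to [pairwise_distance()].
#' @return The point-estimate `phylo` tree with `node.label` holding
#'   bootstrap percentages for internal nodes (empty for the root).
#' @export
nj_bootstrap <- function(seqs, n_reps = 100, seed = NULL, model = "p") {
  if (n_reps < 1) stop_invalid("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  validate_alignment(seqs)
  point <- neighbor_joining(pairwise_distance(seqs, model))
  sp <- tree_splits(point)
  counts <- stats::setNames(numeric(length(sp$keys)), sp$keys)
  L <- nchar(seqs[[1]])
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  used <- 0L; dropped <- 0L
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- apply(mat[, cols, drop = FALSE], 1, paste0, collapse = "")
    tr <- tryCatch(neighbor_joining(pairwise_distance(boot, model)),
                   error = function(e) NULL)
    if (is.null(tr)) { dropped <- dropped + 1L; next }
    used <- used + 1L
    hit <- tree_splits(tr)$keys
    present <- sp$keys %in% hit
    counts[present] <- counts[present] + 1
  }
  if (used == 0L) stop_invalid("all bootstrap replicates failed")
  support <- 100 * counts / used
  n <- length(point$tip.label)
  labs <- rep("", point$Nnode)
  labs[sp$nodes - n] <- format(round(support[sp$keys], 1), trim = TRUE)
  point$node.label <- labs
  attr(point, "support") <- support
  attr(point, "dropped_replicates") <- dropped
  point
}
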