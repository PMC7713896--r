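#' Neighbor-joining starting tree
#'
#' Standard neighbor-joining agglomeration on a complete distance matrix
#' (via \pkg{ape}), with negative branch lengths clamped to zero.  Used as
#' the initial tree of [ratchet_search()].
#'
#' @param m An `evo_dist` matrix, or a plain symmetric matrix.
#' @return Unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(m) {
  d <- if (inherits(m, "evo_dist")) m$d else m
  if (anyNA(d)) stop("matrix has missing entries; run impute_missing() first")
  stopifnot(nrow(d) >= 3)
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Balanced tree length (Pauplin's formula)
#'
#' The balanced minimum-evolution score of a topology given pairwise
#' distances: `sum over leaf pairs of 2^(1 - t_uv) d_uv`, where `t_uv` is
#' the number of edges on the path between leaves `u` and `v`.  Branch
#' lengths of `t` are ignored; only the topology matters.
#'
#' @param t An unrooted binary `ape::phylo` spanning the matrix taxa.
#' @param m An `evo_dist` or plain symmetric matrix.
#' @return Balanced tree length (scalar).
#' @export
bme_length <- function(t, m) {
  d <- if (inherits(m, "evo_dist")) m$d else m
  stopifnot(inherits(t, "phylo"))
  if (!setequal(t$tip.label, rownames(d)))
    stop("tree and matrix taxa differ")
  tu <- ape::unroot(t)   # Pauplin weights are defined on unrooted trees
  tu$edge.length <- rep(1, nrow(tu$edge))
  ntip <- length(t$tip.label)
  topo <- ape::dist.nodes(tu)[seq_len(ntip), seq_len(ntip)]
  dd <- d[t$tip.label, t$tip.label]
  ut <- upper.tri(topo)
  sum(2^(1 - topo[ut]) * dd[ut])
}

# steepest-descent NNI hill climb under the BME criterion
.nni_climb <- function(tree, d) {
  tree <- ape::unroot(tree)   # the NNI neighborhood assumes unrooted input
  cur <- bme_length(tree, d)
  repeat {
    nn <- phangorn::nni(tree)
    # extract via [[ so compressed multiPhylo tip labels are restored
    nbrs <- lapply(seq_along(nn), function(i) nn[[i]])
    scores <- vapply(nbrs, bme_length, numeric(1), m = d)
    best <- which.min(scores)
    if (scores[best] < cur - 1e-12) {
      tree <- nbrs[[best]]
      cur <- scores[best]
    } else {
      return(list(tree = tree, score = cur))
    }
  }
}

#' Ratchet-accelerated balanced minimum-evolution search
#'
#' Starts from the neighbor-joining tree and hill-climbs through
#' nearest-neighbor-interchange moves under the balanced minimum-evolution
#' criterion ([bme_length()]).  Each ratchet round perturbs all distances
#' multiplicatively by `U(1 - perturb, 1 + perturb)`, hill-climbs on the
#' perturbed matrix to escape local optima, then re-climbs and re-scores on
#' the original matrix, keeping the best tree seen.  The result never scores
#' worse than the neighbor-joining start and is deterministic given `seed`.
#' Final branch lengths are fitted by ordinary least squares with negative
#' estimates clamped to zero.
#'
#' @param m An `evo_dist` or plain complete symmetric matrix.
#' @param rounds Number of ratchet rounds (0 = plain hill climb).
#' @param perturb Relative amplitude of the multiplicative perturbation.
#' @param seed Optional RNG seed.
#' @return Unrooted binary `ape::phylo` with fitted branch lengths; the
#'   balanced length on the input matrix is in attribute `"bme"`.
#' @export
ratchet_search <- function(m, rounds = 100, perturb = 0.2, seed = NULL) {
  d <- if (inherits(m, "evo_dist")) m$d else m
  if (anyNA(d)) stop("matrix has missing entries; run impute_missing() first")
  if (all(d[upper.tri(d)] == 0))
    stop("degenerate zero matrix: all pairwise distances are 0")
  if (!is.null(seed)) set.seed(seed)
  best <- .nni_climb(nj_tree(d), d)
  cur <- best
  n <- nrow(d)
  ut <- upper.tri(d)
  for (r in seq_len(rounds)) {
    noise <- matrix(0, n, n)
    noise[ut] <- runif(sum(ut), 1 - perturb, 1 + perturb)
    noise <- noise + t(noise)
    pd <- d * noise
    dimnames(pd) <- dimnames(d)
    shaken <- .nni_climb(cur$tree, pd)
    cand <- .nni_climb(shaken$tree, d)
    if (cand$score < best$score - 1e-12) best <- cand
    cur <- cand
  }
  out <- .ols_branch_lengths(best$tree, d)
  attr(out, "bme") <- best$score
  out
}

# OLS branch lengths: regress pairwise distances on the path-edge incidence
# matrix, clamping negative estimates to zero.
.ols_branch_lengths <- function(tree, d) {
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  pairs <- which(upper.tri(matrix(0, ntip, ntip)), arr.ind = TRUE)
  # per-node edge-to-root incidence via paths
  tu <- tree
  tu$edge.length <- rep(1, nedge)
  A <- matrix(0, nrow(pairs), nedge)
  y <- numeric(nrow(pairs))
  dd <- d[tree$tip.label, tree$tip.label]
  edge_id <- function(a, b) which(tree$edge[, 1L] == a & tree$edge[, 2L] == b |
                                  tree$edge[, 1L] == b & tree$edge[, 2L] == a)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    np <- ape::nodepath(tree, i, j)
    for (s in seq_len(length(np) - 1L))
      A[r, edge_id(np[s], np[s + 1L])] <- 1
    y[r] <- dd[i, j]
  }
  bl <- stats::lm.fit(A, y)$coefficients
  bl[is.na(bl) | bl < 0] <- 0
  tree$edge.length <- unname(bl)
  tree
}

#' Robinson-Foulds distance between unrooted topologies
#'
#' Counts the non-trivial bipartitions present in exactly one of the two
#' trees.  Zero means identical unrooted topologies regardless of branch
#' lengths, rotation or rooting.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return Non-negative even integer.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  s1 <- .bipartitions(t1)
  s2 <- .bipartitions(t2)
  sum(!(s1 %in% s2)) + sum(!(s2 %in% s1))
}

# canonical string keys of the non-trivial bipartitions of an unrooted tree
.bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  labs <- sort(tree$tip.label)
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  ord <- rev(.preorder_edges(tree))   # postorder: children before parents
  for (e in ord) {
    par <- tree$edge[e, 1L]; chi <- tree$edge[e, 2L]
    below[[par]] <- c(below[[par]], below[[chi]])
  }
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    chi <- tree$edge[e, 2L]
    if (chi <= ntip) next                      # trivial split
    side <- sort(below[[chi]])
    if (length(side) >= ntip - 1L) next        # trivial complement
    if (!(labs[1L] %in% side)) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}
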