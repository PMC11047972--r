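# Reconstruction-vs-ground-truth metrics: precision/recall/F1 with distance
# matching, and the structure-distance triple ESA/DSA/PDS.

tree_coords <- function(x) {
  if (inherits(x, "neuron_tree")) as.matrix(x$nodes[, c("x", "y", "z")])
  else as.matrix(x)
}

nn_dist <- function(A, B) {
  # per-row nearest-neighbor distance from A to B; distances below 1e-4
  # voxel are rounding residue of the quadratic expansion, snapped to 0
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d <- sqrt(pmax(apply(d2, 1, min), 0))
  d[d < 1e-4] <- 0
  d
}

#' Distance-matched node counts between two reconstructions
#'
#' A node of R is matched when its nearest node of G lies within `d_match`
#' (inclusive), and symmetrically for G against R.
#'
#' @param R,G `neuron_tree`s (or n x 3 coordinate matrices)
#' @param d_match match distance (voxels)
#' @return list `n_R`, `n_G`, `matched_R`, `matched_G`
#' @export
match_nodes <- function(R, G, d_match = 2) {
  A <- tree_coords(R); B <- tree_coords(G)
  if (nrow(A) == 0L || nrow(B) == 0L)
    return(list(n_R = nrow(A), n_G = nrow(B), matched_R = 0L, matched_G = 0L))
  list(n_R = nrow(A), n_G = nrow(B),
       matched_R = sum(nn_dist(A, B) <= d_match),
       matched_G = sum(nn_dist(B, A) <= d_match))
}

#' Precision, recall and F1 between a reconstruction and its reference
#'
#' `precision = |R matched in G| / |R|`, `recall = |G matched in R| / |G|`,
#' `F1 = 2 P R / (P + R)`. An empty reconstruction scores 0 by convention.
#'
#' @inheritParams match_nodes
#' @return list `precision`, `recall`, `f1`, `n_R`, `n_G`
#' @export
precision_recall_f1 <- function(R, G, d_match = 2) {
  m <- match_nodes(R, G, d_match)
  if (m$n_R == 0L || m$n_G == 0L) {
    warning("empty reconstruction: precision/recall/F1 set to 0")
    return(list(precision = 0, recall = 0, f1 = 0, n_R = m$n_R, n_G = m$n_G))
  }
  p <- m$matched_R / m$n_R
  r <- m$matched_G / m$n_G
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1, n_R = m$n_R, n_G = m$n_G)
}

#' Structure-distance metrics ESA, DSA and PDS
#'
#' Bidirectional nearest-node distances: ESA is the mean over all nodes of
#' both trees; DSA the mean over the "different" nodes (distance beyond
#' `d_thresh`; 0 when there are none); PDS the fraction of such nodes.
#'
#' @inheritParams match_nodes
#' @param d_thresh structure-difference threshold (voxels)
#' @return list `esa`, `dsa`, `pds`
#' @export
esa_dsa_pds <- function(R, G, d_thresh = 2) {
  A <- tree_coords(R); B <- tree_coords(G)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    warning("empty reconstruction: ESA/DSA/PDS undefined, returning NA")
    return(list(esa = NA_real_, dsa = NA_real_, pds = NA_real_))
  }
  d <- c(nn_dist(A, B), nn_dist(B, A))
  diffids <- d > d_thresh
  list(esa = mean(d),
       dsa = if (any(diffids)) mean(d[diffids]) else 0,
       pds = mean(diffids))
}

#' All reconstruction metrics in one call
#'
#' @inheritParams match_nodes
#' @param d_thresh threshold for the structure-difference metrics
#' @return list with precision, recall, f1, esa, dsa, pds, n_R, n_G
#' @export
compare_reconstructions <- function(R, G, d_match = 2, d_thresh = 2) {
  c(precision_recall_f1(R, G, d_match), esa_dsa_pds(R, G, d_thresh))
}
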