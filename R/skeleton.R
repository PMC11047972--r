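# Extraction of candidate unreconstructed skeleton branches from the image:
# enhancement, binarization, topology-preserving 3D thinning, Frangi
# vesselness, soma removal, point filtering and adjacency linking.

#' Weak-signal enhancement (truncated gamma transform)
#'
#' Intensities are clipped to the `[pct_lo, pct_hi]` percentile window,
#' rescaled to `[0, 1]`, raised to the power `gamma` (a gamma below 1 boosts
#' weak signal) and rescaled back to the window. The map is monotone;
#' constant images are returned unchanged.
#'
#' @param vol an `image_volume`
#' @param gamma positive exponent, default 0.6
#' @param pct_lo,pct_hi truncation percentiles
#' @return an `image_volume` of the same shape
#' @export
enhance_volume <- function(vol, gamma = 0.6, pct_lo = 1, pct_hi = 99.5) {
  stopifnot(gamma > 0, pct_lo >= 0, pct_hi <= 100, pct_lo < pct_hi)
  v <- vol$data
  q <- quantile(v, c(pct_lo, pct_hi) / 100, names = FALSE)
  if (q[2] <= q[1]) return(vol)  # constant (or near-constant) image
  w <- pmin(pmax(v, q[1]), q[2])
  w <- ((w - q[1]) / (q[2] - q[1]))^gamma * (q[2] - q[1]) + q[1]
  image_volume(array(w, dim(v)), vol$dtype_max)
}

#' Extended bounding box of a branch
#'
#' Axis-aligned box around the branch nodes, dilated by `margin` voxels and
#' clipped to the volume; `lo` is inclusive, `hi` exclusive (x, y, z order).
#'
#' @param tree a `neuron_tree`
#' @param branch a `branch` (or a numeric n x 3 matrix of points)
#' @param margin dilation in voxels
#' @param vol_shape volume dim `(nz, ny, nx)`
#' @export
extended_bbox <- function(tree, branch, margin, vol_shape) {
  stopifnot(margin >= 0)
  P <- if (is.matrix(branch)) branch else node_xyz(tree, branch$node_path)
  lim <- c(vol_shape[3], vol_shape[2], vol_shape[1])  # (x, y, z) extents
  lo <- pmax(floor(apply(P, 2, min)) - margin, 0)
  hi <- pmin(ceiling(apply(P, 2, max)) + margin + 1, lim)
  structure(list(lo = as.integer(lo), hi = as.integer(hi),
                 margin = margin), class = "bbox_ext")
}

#' Fixed-threshold binarization
#'
#' Foreground is every voxel strictly greater than `mean + k * sd` of the
#' (sub)volume, a global-statistic threshold in the style of automated
#' tracers.
#'
#' @param vol an `image_volume`
#' @param k multiplier on the standard deviation, default 2
#'   (chosen so the foreground isolates tubular structure rather than the
#'   gamma-lifted noise floor)
#' @return 3D logical array
#' @export
binarize_volume <- function(vol, k = 2) {
  v <- vol$data
  thr <- mean(v) + k * sd(as.numeric(v))
  m <- v > thr
  attr(m, "threshold") <- thr
  m
}

#' Topology-preserving 3D thinning
#'
#' Iterative border peeling over six directional subiterations; a voxel is
#' deleted only if it is a simple point (one 26-connected object component
#' in the punctured neighborhood and one 6-connected background component in
#' the 18-neighborhood touching the center) and not a curve endpoint.
#' Deletion is sequential, so topology is preserved exactly; iteration runs
#' to a fixed point, which makes the operation idempotent and leaves
#' 1-voxel-wide curves unchanged.
#'
#' @param mask 3D logical array
#' @return 3D logical array of surviving skeleton voxels
#' @export
thin3d <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  .nc_thin3(mask, dim(mask))
}

#' Multi-scale Frangi vesselness response
#'
#' Hessian eigenvalue filter for bright tubular structures, gamma-normalized
#' and maximized over scales. Sensitivity constants use the standard values
#' (alpha = beta = 0.5; the structureness constant is set per scale to half
#' the maximum Hessian norm).
#'
#' @param vol an `image_volume`
#' @param scales Gaussian scales (voxels)
#' @return 3D numeric array of responses in `[0, 1]`
#' @export
frangi_vesselness <- function(vol, scales = c(1, 1.5, 2)) {
  stopifnot(length(scales) >= 1)
  .nc_frangi3(vol$data, dim(vol$data), as.numeric(scales), 0.5, 0.5)
}

#' Boolean tubularity mask
#'
#' Thresholds the multi-scale Frangi response at `threshold` times its
#' maximum.
#'
#' @inheritParams frangi_vesselness
#' @param threshold fraction of the maximum response, default 0.05
#' @return 3D logical array
#' @export
tubularity_mask <- function(vol, scales = c(1, 1.5, 2), threshold = 0.05) {
  r <- frangi_vesselness(vol, scales)
  mx <- max(r)
  if (mx <= 0) return(array(FALSE, dim(r)))
  r > threshold * mx
}

#' Remove skeleton points inside the (inflated) soma
#'
#' Vesselness is unreliable near the soma, so points within
#' `soma_radius * inflation` (inclusive) of the soma center are dropped.
#'
#' @param pts integer matrix n x 3 of voxels `(x, y, z)`, 0-based
#' @param soma_center numeric `(x, y, z)`
#' @param soma_radius reconstructed soma radius (> 0)
#' @param inflation multiplier, default 1.5
#' @export
remove_soma_region <- function(pts, soma_center, soma_radius, inflation = 1.5) {
  stopifnot(soma_radius > 0)
  if (nrow(pts) == 0L) return(pts)
  d <- sqrt(colSums((t(pts) - soma_center)^2))
  pts[d > soma_radius * inflation, , drop = FALSE]
}

#' Filter skeleton points by tubularity, degree and reconstruction coverage
#'
#' Keeps points that (a) pass [point_has_tubularity()], (b) have one or two
#' 26-neighbors among the surviving skeleton points (dropping isolated points
#' and branching points), and (c) lie farther than `d_cover` from every
#' reconstruction node. Tubularity is applied first; degree is computed on
#' the tubularity survivors.
#'
#' @param pts integer matrix n x 3 `(x, y, z)`, 0-based
#' @param mask 3D logical tubularity mask
#' @param tree a `neuron_tree` (or NULL to skip the coverage test)
#' @param params a [confidence_params()] (uses `d_cover`)
#' @export
filter_skeleton_points <- function(pts, mask, tree = NULL,
                                   params = confidence_params()) {
  pts <- filter_points_tub_degree(pts, mask)
  if (!is.null(tree)) pts <- filter_points_coverage(pts, tree, params$d_cover)
  pts
}

# (a) tubularity + (b) degree 1-2, reconstruction-independent
filter_points_tub_degree <- function(pts, mask) {
  if (nrow(pts) == 0L) return(pts)
  dil <- dilate_mask26(mask)
  pts <- pts[points_tubular(dil, pts), , drop = FALSE]
  if (nrow(pts) == 0L) return(pts)
  d <- dim(mask)
  m <- array(FALSE, d)
  m[cbind(pts[, 3] + 1L, pts[, 2] + 1L, pts[, 1] + 1L)] <- TRUE
  cnt <- .nc_neighbor_count26(m, d)
  deg <- cnt[cbind(pts[, 3] + 1L, pts[, 2] + 1L, pts[, 1] + 1L)]
  pts[deg >= 1L & deg <= 2L, , drop = FALSE]
}

# (c) strictly farther than d_cover from every reconstruction node
filter_points_coverage <- function(pts, tree, d_cover) {
  if (nrow(pts) == 0L) return(pts)
  N <- as.matrix(tree$nodes[, c("x", "y", "z")])
  d2 <- outer(rowSums(pts^2), rowSums(N^2), "+") - 2 * pts %*% t(N)
  keep <- sqrt(pmax(apply(d2, 1, min), 0)) > d_cover
  pts[keep, , drop = FALSE]
}

#' Link skeleton points into undirected skeleton branches
#'
#' 26-connected components of the point set are traced into simple chains
#' ordered endpoint to endpoint; components with residual high-degree voxels
#' are split at those voxels, and cycles are opened at their smallest index.
#'
#' @param pts integer matrix n x 3 `(x, y, z)`, 0-based
#' @param dim_zyx volume dim `(nz, ny, nx)` used to key voxels
#' @return list of `skeleton_branch`: `skeleton_id`, `chain_xyz` (ordered
#'   matrix), `length` (arc length), `endpoints`, `tubular`
#' @export
link_skeleton_branches <- function(pts, dim_zyx) {
  if (nrow(pts) == 0L) return(list())
  nz <- dim_zyx[1]; ny <- dim_zyx[2]; nx <- dim_zyx[3]
  key <- pts[, 3] + nz * (pts[, 2] + ny * pts[, 1])  # z + nz*(y + ny*x)
  ord <- order(key)
  pts <- pts[ord, , drop = FALSE]
  key <- key[ord]
  n <- nrow(pts)
  # adjacency via 26 neighbor-key lookups
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  efrom <- integer(0); eto <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nk <- (pts[, 3] + offs[r, 3]) + nz * ((pts[, 2] + offs[r, 2]) +
                                          ny * (pts[, 1] + offs[r, 1]))
    hit <- match(nk, key)
    src <- which(!is.na(hit))
    efrom <- c(efrom, src)
    eto <- c(eto, hit[src])
  }
  adj <- unname(split(eto, factor(efrom, levels = seq_len(n))))
  deg <- lengths(adj)
  # split at residual high-degree voxels: remove them, re-run on survivors
  if (any(deg >= 3L)) {
    keep <- deg <= 2L
    return(link_skeleton_branches(pts[keep, , drop = FALSE], dim_zyx))
  }
  visited <- logical(n)
  out <- list()
  trace_from <- function(start) {
    path <- start
    visited[start] <<- TRUE
    cur <- start
    prev <- -1L
    repeat {
      nxt <- setdiff(adj[[cur]], c(prev, path))
      if (!length(nxt)) break
      prev <- cur
      cur <- nxt[1]
      visited[cur] <<- TRUE
      path <- c(path, cur)
    }
    path
  }
  for (i in seq_len(n)) {
    if (visited[i] || deg[i] != 1L) next  # start at endpoints
    path <- trace_from(i)
    out[[length(out) + 1L]] <- path
  }
  for (i in seq_len(n)) {                # leftover cycles / isolated
    if (visited[i]) next
    path <- trace_from(i)
    if (length(path) >= 2L) out[[length(out) + 1L]] <- path
  }
  res <- vector("list", length(out))
  for (i in seq_along(out)) {
    chain <- pts[out[[i]], , drop = FALSE]
    len <- if (nrow(chain) >= 2) sum(sqrt(rowSums(diff(chain)^2))) else 1
    res[[i]] <- structure(
      list(skeleton_id = i, chain_xyz = chain, length = max(len, 1),
           endpoints = rbind(chain[1, ], chain[nrow(chain), ]),
           tubular = TRUE),
      class = "skeleton_branch")
  }
  res
}

# ---------------------------------------------------------------------------
# Pipeline wrappers
# ---------------------------------------------------------------------------

#' Reconstruction-independent image context for skeleton extraction
#'
#' Runs enhancement, binarization, thinning and vesselness once per volume;
#' the result can be reused across detection passes on different
#' reconstructions of the same image.
#'
#' @param vol an `image_volume`
#' @param soma numeric `(x, y, z)` soma position
#' @param soma_radius reconstructed soma radius (voxels)
#' @param params a [confidence_params()]
#' @param gamma,pct_lo,pct_hi enhancement parameters
#' @param binarize_k binarization multiplier
#' @param scales,vessel_threshold vesselness parameters
#' @param soma_inflation soma-removal inflation factor
#' @return an `image_context` with the enhanced volume, tubularity mask and
#'   pre-filtered skeleton points
#' @export
image_context <- function(vol, soma, soma_radius = 5,
                          params = confidence_params(),
                          gamma = 0.6, pct_lo = 1, pct_hi = 99.5,
                          binarize_k = 2, scales = c(1, 1.5, 2),
                          vessel_threshold = 0.05, soma_inflation = 1.5) {
  enh <- enhance_volume(vol, gamma, pct_lo, pct_hi)
  bin <- binarize_volume(enh, binarize_k)
  d <- dim(bin)
  idx <- which(bin, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    thin <- array(FALSE, d)
    mask <- array(FALSE, d)
  } else {
    # thinning and vesselness only act near foreground: crop to its
    # bounding box (+4 voxels) and re-embed
    lo <- pmax(apply(idx, 2, min) - 4L, 1L)
    hi <- pmin(apply(idx, 2, max) + 4L, d)
    rz <- lo[1]:hi[1]; ry <- lo[2]:hi[2]; rx <- lo[3]:hi[3]
    thin <- array(FALSE, d)
    thin[rz, ry, rx] <- thin3d(bin[rz, ry, rx, drop = FALSE])
    mask <- array(FALSE, d)
    mask[rz, ry, rx] <- tubularity_mask(
      image_volume(enh$data[rz, ry, rx, drop = FALSE], enh$dtype_max),
      scales, vessel_threshold)
  }
  idx <- which(thin, arr.ind = TRUE)                  # (z, y, x), 1-based
  pts <- cbind(x = idx[, 3], y = idx[, 2], z = idx[, 1]) - 1L
  pts <- remove_soma_region(pts, soma, soma_radius, soma_inflation)
  pts <- filter_points_tub_degree(pts, mask)
  structure(list(vol = vol, enhanced = enh, mask = mask,
                 points = pts, dim = dim(vol$data), soma = soma,
                 soma_radius = soma_radius, params = params),
            class = "image_context")
}

#' @export
print.image_context <- function(x, ...) {
  cat(sprintf("<image_context> %s, %d candidate skeleton points\n",
              paste(x$dim, collapse = "x"), nrow(x$points)))
  invisible(x)
}

#' Skeleton branches outside a given reconstruction
#'
#' Applies the reconstruction-coverage filter to the context's candidate
#' skeleton points and links the survivors into chains.
#'
#' @param ictx an [image_context()]
#' @param tree a `neuron_tree`
#' @param min_length minimum chain arc length (voxels); shorter chains are
#'   residual noise, not candidate branches
#' @export
skeleton_for_tree <- function(ictx, tree, min_length = 4) {
  pts <- filter_points_coverage(ictx$points, tree, ictx$params$d_cover)
  sk <- link_skeleton_branches(pts, ictx$dim)
  sk <- merge_skeleton_chains(sk)
  sk <- sk[vapply(sk, function(s) s$length >= min_length, logical(1))]
  for (i in seq_along(sk)) sk[[i]]$skeleton_id <- i
  sk
}

# End directions of a chain (pointing outward at each end).
chain_end_dirs <- function(P) {
  n <- nrow(P)
  k <- min(n, 4L)
  d1 <- P[1, ] - P[k, ]
  d2 <- P[n, ] - P[n - k + 1, ]
  list(start = d1 / max(sqrt(sum(d1^2)), 1e-9),
       end = d2 / max(sqrt(sum(d2^2)), 1e-9))
}

#' Merge near-collinear skeleton chain fragments
#'
#' Thinning and point filtering can split one underlying tube into several
#' chain fragments (at removed junction voxels or small mask holes). Two
#' chains are merged when a pair of their endpoints lies within `max_gap`
#' voxels and the chains continue each other (the gap direction deviates
#' from both end directions by less than `max_angle`). Merging repeats to a
#' fixed point.
#'
#' @param sk list of `skeleton_branch`
#' @param max_gap maximum endpoint gap (voxels)
#' @param max_angle maximum deviation (degrees)
#' @export
merge_skeleton_chains <- function(sk, max_gap = 5, max_angle = 70) {
  if (length(sk) < 2L) return(sk)
  chains <- lapply(sk, `[[`, "chain_xyz")
  repeat {
    merged <- FALSE
    n <- length(chains)
    for (i in seq_len(n - 1L)) {
      if (merged) break
      for (j in (i + 1L):n) {
        A <- chains[[i]]; B <- chains[[j]]
        ea <- rbind(A[1, ], A[nrow(A), ])
        eb <- rbind(B[1, ], B[nrow(B), ])
        dd <- sqrt(outer(rowSums(ea^2), rowSums(eb^2), "+") - 2 * ea %*% t(eb))
        if (min(dd) > max_gap) next
        w <- which(dd == min(dd), arr.ind = TRUE)[1, ]
        # orient both so the junction is A-end -> B-start
        if (w[1] == 1L) A <- A[rev(seq_len(nrow(A))), , drop = FALSE]
        if (w[2] == 2L) B <- B[rev(seq_len(nrow(B))), , drop = FALSE]
        g <- B[1, ] - A[nrow(A), ]
        gn <- sqrt(sum(g^2))
        da <- chain_end_dirs(A)$end
        db <- chain_end_dirs(B)$start
        # continuation requires the gap to align with both end directions
        # AND the directions to agree with each other - two different
        # structures passing close to the same point must not be glued
        ok <- if (gn < 1e-9) angle_between(da, -db) <= max_angle else {
          ga <- angle_between(da, g)
          gb <- angle_between(-db, g)
          ga <= max_angle && gb <= max_angle &&
            angle_between(da, -db) <= max_angle
        }
        if (!ok) next
        chains[[i]] <- rbind(A, B)
        chains[[j]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  out <- vector("list", length(chains))
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    len <- if (nrow(ch) >= 2) sum(sqrt(rowSums(diff(ch)^2))) else 1
    out[[i]] <- structure(
      list(skeleton_id = i, chain_xyz = ch, length = max(len, 1),
           endpoints = rbind(ch[1, ], ch[nrow(ch), ]), tubular = TRUE),
      class = "skeleton_branch")
  }
  out
}

#' One-call skeleton extraction
#'
#' Convenience wrapper: [image_context()] followed by [skeleton_for_tree()].
#' @inheritParams image_context
#' @param tree a `neuron_tree`
#' @export
extract_skeleton <- function(vol, tree, soma, soma_radius = 5,
                             params = confidence_params(), ...) {
  ictx <- image_context(vol, soma, soma_radius, params, ...)
  skeleton_for_tree(ictx, tree)
}
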