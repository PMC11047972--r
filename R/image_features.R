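# Intensity statistics along branching segments and tubularity predicates.

#' Construct an image volume
#'
#' @param data 3D numeric array indexed `(z, y, x)`, non-negative intensities.
#' @param dtype_max full-scale value used to normalize intensities (255 for
#'   8-bit stacks, 65535 for 16-bit).
#' @return an `image_volume`
#' @export
image_volume <- function(data, dtype_max = 255) {
  if (length(dim(data)) != 3L)
    .nc_stop("nc_format_error", "volume must be a 3D array (z, y, x)")
  if (min(data) < 0)
    .nc_stop("nc_format_error", "intensities must be non-negative")
  structure(list(data = data, shape = dim(data), dtype_max = dtype_max),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s (z,y,x), dtype_max %g\n",
              paste(x$shape, collapse = "x"), x$dtype_max))
  invisible(x)
}

# Trilinear sample at (x,y,z) 0-based voxel coordinates (matrix n x 3),
# clipped to the volume border.
sample_volume <- function(vol, xyz) {
  .nc_trilinear(vol$data, dim(vol$data), as.matrix(xyz))
}

#' Intensity statistics along a branching segment
#'
#' Samples the volume by trilinear interpolation at the segment points
#' (points outside the volume are clipped to the border and still counted)
#' and returns the mean and the population standard deviation.
#'
#' @param vol an `image_volume`
#' @param seg a `branch_segment`
#' @return list `mean_intensity`, `intensity_sd`, `n_samples`
#' @export
segment_intensity_stats <- function(vol, seg) {
  if (is.null(seg$points) || nrow(seg$points) < 1L)
    .nc_stop("nc_degenerate_segment", "empty segment")
  v <- sample_volume(vol, seg$points)
  n <- length(v)
  m <- mean(v)
  list(mean_intensity = m,
       intensity_sd = sqrt(sum((v - m)^2) / n),
       n_samples = n)
}

#' Tubularity at a voxel (lenient 26-neighborhood reading)
#'
#' A point has tubularity when the mask is set at the point itself or at any
#' of its 26 neighbors.
#'
#' @param mask 3D logical array `(z, y, x)` (a tubularity mask)
#' @param p integer voxel as `(x, y, z)`, 0-based
#' @export
point_has_tubularity <- function(mask, p) {
  d <- dim(mask)
  if (p[1] < 0 || p[1] >= d[3] || p[2] < 0 || p[2] >= d[2] ||
      p[3] < 0 || p[3] >= d[1])
    .nc_stop("nc_bounds_error", "point outside the grid")
  xs <- pmin(pmax(p[1] + (-1:1), 0), d[3] - 1)
  ys <- pmin(pmax(p[2] + (-1:1), 0), d[2] - 1)
  zs <- pmin(pmax(p[3] + (-1:1), 0), d[1] - 1)
  any(mask[unique(zs) + 1L, unique(ys) + 1L, unique(xs) + 1L])
}

# Precompute the 26-neighborhood OR of a mask (point_has_tubularity for every
# voxel at once).
dilate_mask26 <- function(mask) {
  mask | (.nc_neighbor_count26(mask, dim(mask)) > 0L)
}

#' Branch-level tubularity (70 percent rule)
#'
#' A branch has tubularity when at least 70 percent (inclusive) of its node
#' positions, rounded to voxels, pass [point_has_tubularity()].
#'
#' @param mask 3D logical tubularity mask
#' @param tree a `neuron_tree`
#' @param branch a `branch`
#' @param frac inclusive threshold, default 0.70
#' @export
branch_has_tubularity <- function(mask, tree, branch, frac = 0.70) {
  P <- round(node_xyz(tree, branch$node_path))
  d <- dim(mask)
  P[, 1] <- pmin(pmax(P[, 1], 0), d[3] - 1)
  P[, 2] <- pmin(pmax(P[, 2], 0), d[2] - 1)
  P[, 3] <- pmin(pmax(P[, 3], 0), d[1] - 1)
  dil <- dilate_mask26(mask)
  hit <- dil[cbind(P[, 3] + 1L, P[, 2] + 1L, P[, 1] + 1L)]
  mean(hit) >= frac - 1e-12
}

# Fast variant against a precomputed dilated mask and integer positions.
points_tubular <- function(dil, P) {
  d <- dim(dil)
  P <- round(P)
  P[, 1] <- pmin(pmax(P[, 1], 0), d[3] - 1)
  P[, 2] <- pmin(pmax(P[, 2], 0), d[2] - 1)
  P[, 3] <- pmin(pmax(P[, 3], 0), d[1] - 1)
  dil[cbind(P[, 3] + 1L, P[, 2] + 1L, P[, 1] + 1L)]
}
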