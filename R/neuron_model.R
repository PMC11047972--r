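# SWC tree representation, branch decomposition and branching-segment
# extraction. Coordinates are 0-based voxel positions in (x, y, z) order;
# image arrays are indexed (z, y, x).

#' Construct a neuron tree from an SWC-style node table
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent`. `parent = -1` marks the root (soma).
#' @param validate check structural invariants (single root, acyclic,
#'   connected, unique ids).
#' @return An object of class `neuron_tree`: the node table plus `soma_id`.
#' @export
neuron_tree <- function(nodes, validate = TRUE) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes)))
    .nc_stop("nc_structural_error", "node table must have columns: %s",
             paste(need, collapse = ", "))
  nodes <- as.data.frame(nodes)[, need]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  tree <- structure(list(nodes = nodes,
                         soma_id = nodes$id[nodes$parent == -1L][1]),
                    class = "neuron_tree")
  if (validate) validate_neuron_tree(tree)
  tree
}

#' Validate neuron tree invariants
#'
#' Checks unique ids, exactly one root, no self-parenting, existing parents,
#' finite coordinates and acyclicity (every node reaches the root).
#' @param tree a `neuron_tree`
#' @return the tree, invisibly; signals `nc_structural_error` on violation.
#' @export
validate_neuron_tree <- function(tree) {
  nd <- tree$nodes
  if (anyDuplicated(nd$id))
    .nc_stop("nc_structural_error", "duplicate node id(s): %s",
             paste(unique(nd$id[duplicated(nd$id)]), collapse = ","))
  roots <- nd$id[nd$parent == -1L]
  if (length(roots) != 1L)
    .nc_stop("nc_structural_error", "expected exactly one root, found %d",
             length(roots))
  if (any(nd$parent == nd$id))
    .nc_stop("nc_structural_error", "self-parenting node")
  known <- nd$parent == -1L | nd$parent %in% nd$id
  if (!all(known))
    .nc_stop("nc_structural_error", "missing parent id(s): %s",
             paste(unique(nd$parent[!known]), collapse = ","))
  if (!all(is.finite(nd$x) & is.finite(nd$y) & is.finite(nd$z)))
    .nc_stop("nc_structural_error", "non-finite coordinates")
  # acyclic + connected: follow parents with a depth visit
  pidx <- match(nd$parent, nd$id)
  depth <- rep(NA_integer_, nrow(nd))
  depth[nd$parent == -1L] <- 0L
  for (pass in seq_len(nrow(nd))) {
    todo <- which(is.na(depth) & !is.na(depth[pidx]))
    if (!length(todo)) break
    depth[todo] <- depth[pidx[todo]] + 1L
  }
  if (anyNA(depth))
    .nc_stop("nc_structural_error",
             "cycle or disconnected component (nodes: %s)",
             paste(head(nd$id[is.na(depth)], 5L), collapse = ","))
  invisible(tree)
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat(sprintf("<neuron_tree> %d nodes, soma id %d\n",
              nrow(x$nodes), x$soma_id))
  invisible(x)
}

node_xyz <- function(tree, ids) {
  i <- match(ids, tree$nodes$id)
  as.matrix(tree$nodes[i, c("x", "y", "z"), drop = FALSE])
}

#' Decompose a neuron tree into hierarchical branches
#'
#' A branch is a maximal path free of interior branching points, running from
#' a branching point (or the soma) to the next branching point or terminal.
#' Levels are assigned breadth-first from the soma (soma branch = level 0);
#' when a node has more than two children each child starts its own branch,
#' in node-id order.
#'
#' @param tree a `neuron_tree`
#' @return list of `branch` objects with fields `branch_id`, `node_path`
#'   (ordered node ids, proximal anchor first), `parent_branch_id`, `level`,
#'   `is_terminal`.
#' @export
decompose_branches <- function(tree) {
  validate_neuron_tree(tree)
  nd <- tree$nodes
  kids <- split(nd$id[nd$parent != -1L], factor(nd$parent[nd$parent != -1L],
                                                levels = nd$id))
  n_kids <- lengths(kids)
  names(n_kids) <- nd$id
  get_kids <- function(id) sort(kids[[as.character(id)]])

  branches <- list()
  bid <- 0L
  # queue entries: (start node = proximal anchor, first child, level, parent branch)
  queue <- lapply(get_kids(tree$soma_id), function(ch)
    list(anchor = tree$soma_id, child = ch, level = 0L, parent = NA_integer_))
  while (length(queue)) {
    ent <- queue[[1]]; queue <- queue[-1]
    path <- c(ent$anchor, ent$child)
    cur <- ent$child
    while (n_kids[as.character(cur)] == 1L) {
      cur <- get_kids(cur)
      path <- c(path, cur)
    }
    bid <- bid + 1L
    branches[[bid]] <- structure(
      list(branch_id = bid, node_path = path,
           parent_branch_id = ent$parent, level = ent$level,
           is_terminal = n_kids[as.character(cur)] == 0L),
      class = "branch")
    if (n_kids[as.character(cur)] >= 2L) {
      this_bid <- bid
      queue <- c(queue, lapply(get_kids(cur), function(ch)
        list(anchor = cur, child = ch, level = ent$level + 1L,
             parent = this_bid)))
    }
  }
  branches
}

#' @export
print.branch <- function(x, ...) {
  cat(sprintf("<branch %d> level %d, %d nodes%s\n", x$branch_id, x$level,
              length(x$node_path), if (x$is_terminal) ", terminal" else ""))
  invisible(x)
}

# Resample a polyline (n x 3 matrix) at unit arc-length spacing starting at
# row 1. Returns a matrix with floor(arc) + 1 rows.
resample_polyline <- function(P) {
  if (nrow(P) < 2L) .nc_stop("nc_degenerate_segment", "polyline needs >= 2 points")
  step <- sqrt(rowSums(diff(P)^2))
  P <- P[c(TRUE, step > 1e-12), , drop = FALSE]  # drop repeated vertices
  if (nrow(P) < 2L) .nc_stop("nc_degenerate_segment", "zero-length polyline")
  step <- sqrt(rowSums(diff(P)^2))
  cum <- c(0, cumsum(step))
  total <- cum[length(cum)]
  if (total <= 0) .nc_stop("nc_degenerate_segment", "zero-length polyline")
  s <- seq(0, floor(total + 1e-9))
  # preserve the distal endpoint: when the leftover beyond the last unit
  # sample exceeds half a voxel, sample the exact end as well (segments are
  # taken from the anchor, so their unit spacing is unaffected)
  if (total - s[length(s)] > 0.5) s <- c(s, total)
  out <- matrix(0, length(s), 3)
  for (j in 1:3) out[, j] <- stats::approx(cum, P[, j], xout = s, rule = 2)$y
  out
}

#' Extract a fixed-length directed branching segment
#'
#' Starting from the branching point at one end of the branch, the branch
#' polyline is resampled at unit arc-length spacing and truncated to at most
#' `L` points. The direction always follows the direction of growth: for the
#' proximal end it points from the anchor toward the segment's far end (child
#' convention); for the distal end it points from the far end toward the
#' anchor (parent convention). If the branch is shorter than `L - 1` in arc
#' length the whole branch is used and `short = TRUE` is recorded.
#'
#' @param tree a `neuron_tree`
#' @param branch a `branch` from [decompose_branches()]
#' @param end `"proximal"` or `"distal"`
#' @param L segment length in voxels of arc length (>= 2)
#' @return a `branch_segment`: `points` (matrix, first row = anchor),
#'   `anchor`, `direction` (unit), `end`, `short`, `branch_id`.
#' @export
extract_segment <- function(tree, branch, end = c("proximal", "distal"), L = 8) {
  end <- match.arg(end)
  if (L < 2) .nc_stop("nc_degenerate_segment", "L must be >= 2")
  if (length(branch$node_path) < 2L)
    .nc_stop("nc_degenerate_segment", "single-node branch")
  P <- node_xyz(tree, branch$node_path)
  if (end == "distal") P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
  R <- resample_polyline(P)
  short <- nrow(R) < L
  if (nrow(R) > L) R <- R[seq_len(L), , drop = FALSE]
  make_segment(R, end = end, branch_id = branch$branch_id, short = short)
}

# Internal segment constructor from unit-resampled points (anchor first).
make_segment <- function(points, end = "proximal", branch_id = NA_integer_,
                         short = FALSE, kind = "branch", id2 = NA_integer_) {
  n <- nrow(points)
  v <- points[n, ] - points[1, ]
  if (end == "distal") v <- -v  # growth direction: far end -> anchor
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) .nc_stop("nc_degenerate_segment", "degenerate direction")
  structure(list(points = points, anchor = points[1, ],
                 direction = v / nv, end = end, short = short,
                 branch_id = branch_id, kind = kind, id2 = id2),
            class = "branch_segment")
}

segment_endpoints <- function(seg) {
  rbind(seg$points[1, ], seg$points[nrow(seg$points), ])
}

# Minimum endpoint-pair distance between two segments.
segment_dist <- function(a, b) {
  ea <- segment_endpoints(a); eb <- segment_endpoints(b)
  min(sqrt(outer(rowSums(ea^2), rowSums(eb^2), "+") - 2 * ea %*% t(eb)))
}

#' Angle between two direction vectors, in degrees
#'
#' @param d1,d2 non-zero 3-vectors
#' @return angle in `[0, 180]`
#' @export
angle_between <- function(d1, d2) {
  n1 <- sqrt(sum(d1^2)); n2 <- sqrt(sum(d2^2))
  if (n1 < 1e-12 || n2 < 1e-12)
    .nc_stop("nc_invalid_direction", "zero direction vector")
  acos(max(-1, min(1, sum(d1 * d2) / (n1 * n2)))) * 180 / pi
}

# Split a branch into consecutive unit-resampled segments of length L
# (shared boundary samples); the last chunk may be shorter. These are the
# per-segment units of the local (within-branch) confidence chain.
branch_chunks <- function(tree, branch, L) {
  P <- node_xyz(tree, branch$node_path)
  R <- resample_polyline(P)
  N <- nrow(R)
  if (N < 2L) return(list())
  starts <- seq(1L, max(1L, N - 1L), by = L - 1L)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    a <- starts[i]
    b <- min(a + L - 1L, N)
    if (b - a < 1L) { a <- max(1L, b - 1L) }
    out[[i]] <- make_segment(R[a:b, , drop = FALSE], end = "proximal",
                             branch_id = branch$branch_id,
                             short = (b - a + 1L) < L, id2 = i)
  }
  out
}
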