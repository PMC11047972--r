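# Markov-chain connection confidence: energy function, candidate sets,
# partition sum, global (PG) and local (PL) confidences.

#' Confidence and detection parameters
#'
#' @param alpha,beta non-negative weights of the intensity-mean and
#'   intensity-sd terms of the connection energy.
#' @param Td candidate distance threshold (voxels): a segment competes for a
#'   connection when its minimum endpoint distance to the conditioning
#'   segment lies strictly inside `(0, Td)`.
#' @param D incomplete-tracing gap threshold (voxels, strict upper bound).
#' @param L branching-segment length (voxels of arc length).
#' @param tau low-confidence threshold in `[0, 1]`. A correct connection
#'   among k equally plausible candidates scores `1 - 1/k`, i.e. 0.5 for the
#'   commonest two-candidate case, so `tau` sits below that value.
#' @param d_cover reconstruction-coverage distance (voxels): skeleton voxels
#'   closer than this to any reconstructed node are considered covered.
#' @param d_match evaluation match distance (voxels).
#' @param theta_cont maximum deflection (degrees) at which a co-child counts
#'   as the parent's continuation (spurious-branch-point signature) in the
#'   branch-branch misconnection test.
#' @param pl_sum use the literal sum over per-segment confidences for PL
#'   instead of the mean (the sum may exceed 1).
#' @return a `confidence_params` list.
#' @export
confidence_params <- function(alpha = 0.5, beta = 0.5, Td = 20, D = 10,
                              L = 8, tau = 0.3, d_cover = 3, d_match = 2,
                              theta_cont = 15, pl_sum = FALSE) {
  stopifnot(alpha >= 0, beta >= 0, Td >= 0, D >= 0, L >= 2,
            tau >= 0, tau <= 1, d_cover >= 0, d_match >= 0)
  structure(list(alpha = alpha, beta = beta, Td = Td, D = D, L = L,
                 tau = tau, d_cover = d_cover, d_match = d_match,
                 theta_cont = theta_cont, pl_sum = pl_sum),
            class = "confidence_params")
}

#' Connection energy between two branching segments
#'
#' `U = alpha * |dI| + beta * |dsigma|` when the angle between the two
#' directions is below 90 degrees, and `+Inf` otherwise (a reverse-growth
#' connection is impossible). Intensity differences are divided by `scale`
#' (the volume's full-scale value) so both terms are commensurate.
#'
#' @param featA,featB segment features from [segment_intensity_stats()]
#' @param theta angle between the two segment directions, degrees
#' @param params a [confidence_params()]
#' @param scale intensity normalization (default 1)
#' @return an `energy_breakdown`: `delta_I`, `delta_sigma`, `theta`, `U`
#' @export
connection_energy <- function(featA, featB, theta, params = confidence_params(),
                              scale = 1) {
  dI <- abs(featA$mean_intensity - featB$mean_intensity) / scale
  ds <- abs(featA$intensity_sd - featB$intensity_sd) / scale
  U <- if (theta >= 90) Inf else params$alpha * dI + params$beta * ds
  structure(list(delta_I = dI, delta_sigma = ds, theta = theta, U = U),
            class = "energy_breakdown")
}

#' Connection probabilities over a candidate set (partition rule)
#'
#' Given the connection energies of all candidates in the set S, the
#' probability of candidate i is `1 - U_i / Z` with `Z = sum of finite
#' energies`. Infinite-energy candidates are excluded from Z and receive
#' probability 0. When every finite energy is zero the probability mass is
#' split uniformly among the zero-energy candidates.
#'
#' @param U numeric vector of energies (may contain `Inf`)
#' @return numeric vector of probabilities in `[0, 1]`, same length
#' @export
candidate_probabilities <- function(U) {
  p <- numeric(length(U))
  fin <- is.finite(U)
  if (!any(fin)) return(p)
  Z <- sum(U[fin])
  if (Z <= 0) {
    zero <- fin & U == 0
    p[zero] <- 1 / sum(zero)
  } else {
    p[fin] <- 1 - U[fin] / Z
  }
  p
}

#' Build the candidate set for a parent-child connection
#'
#' Candidates are all segments whose minimum endpoint distance to the
#' conditioning segment `segA` lies strictly within `(0, Td)`, plus the
#' current segment `segB` (always included). The strict lower bound excludes
#' every segment sharing an endpoint with `segA` - in particular co-children
#' anchored at the same branching point.
#'
#' @param segA conditioning (parent) segment
#' @param segB current (child) segment
#' @param other_segments list of `branch_segment`s (branch or skeleton)
#' @param params a [confidence_params()]
#' @return a `candidate_set`: list with `anchor_segment`, `candidates`
#'   (list of `seg`, `kind`, `distance`), `includes_current`.
#' @export
build_candidate_set <- function(segA, segB, other_segments = list(),
                                params = confidence_params()) {
  eps <- 1e-9
  cands <- list(list(seg = segB, kind = segB$kind %||% "branch",
                     distance = segment_dist(segA, segB), current = TRUE))
  for (s in other_segments) {
    d <- segment_dist(segA, s)
    if (d > eps && d < params$Td)
      cands[[length(cands) + 1L]] <- list(seg = s, kind = s$kind %||% "branch",
                                          distance = d, current = FALSE)
  }
  structure(list(anchor_segment = segA, candidates = cands,
                 includes_current = TRUE),
            class = "candidate_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Connection probability of the current segment given its parent
#'
#' Evaluates the energy of every candidate in the set (features sampled from
#' the volume, angle against the conditioning segment), forms the partition
#' sum Z over finite energies, and returns `P = 1 - U(current)/Z`.
#'
#' @param segA conditioning segment
#' @param segB current segment
#' @param cand a [build_candidate_set()] result for `(segA, segB)`
#' @param vol an `image_volume`
#' @param params a [confidence_params()]
#' @return probability in `[0, 1]`; attribute `"breakdown"` carries the
#'   per-candidate energies and probabilities and the partition sum Z.
#' @export
connection_probability <- function(segA, segB, cand, vol,
                                   params = confidence_params()) {
  fA <- segment_intensity_stats(vol, segA)
  U <- vapply(cand$candidates, function(cc) {
    fS <- segment_intensity_stats(vol, cc$seg)
    th <- angle_between(segA$direction, cc$seg$direction)
    connection_energy(fA, fS, th, params, scale = vol$dtype_max)$U
  }, numeric(1))
  p <- candidate_probabilities(U)
  cur <- which(vapply(cand$candidates, function(cc) isTRUE(cc$current),
                      logical(1)))[1]
  out <- p[cur]
  attr(out, "breakdown") <- list(U = U, p = p, Z = sum(U[is.finite(U)]),
                                 current = cur)
  out
}

# ---------------------------------------------------------------------------
# Confidence context: cached segments, features and distances for a whole
# reconstruction (+ optional skeleton), the workhorse behind PG/PL and the
# detectors.
# ---------------------------------------------------------------------------

#' Build a confidence context for a reconstruction
#'
#' Decomposes the tree into branches and consecutive unit-resampled segments,
#' extracts skeleton endpoint segments, and caches segment directions,
#' endpoints and intensity features for fast candidate-set queries.
#'
#' @param tree a `neuron_tree`
#' @param vol an `image_volume`
#' @param params a [confidence_params()]
#' @param skeleton list of skeleton branches (from
#'   [link_skeleton_branches()]), may be empty
#' @return a `confidence_context`
#' @export
confidence_context <- function(tree, vol, params = confidence_params(),
                               skeleton = list()) {
  branches <- decompose_branches(tree)
  L <- params$L
  segs <- list()
  meta <- list()
  chunk_idx <- vector("list", length(branches))   # universe idx per chunk
  for (b in branches) {
    ch <- branch_chunks(tree, b, L)
    ids <- integer(length(ch))
    for (i in seq_along(ch)) {
      segs[[length(segs) + 1L]] <- ch[[i]]
      ids[i] <- length(segs)
      meta[[length(segs)]] <- list(kind = "branch", owner = b$branch_id,
                                   chunk = i, n_chunks = length(ch))
    }
    chunk_idx[[b$branch_id]] <- ids
  }
  skel_idx <- vector("list", length(skeleton))
  for (si in seq_along(skeleton)) {
    for (seg in skeleton_end_segments(skeleton[[si]], L)) {
      segs[[length(segs) + 1L]] <- seg
      meta[[length(segs)]] <- list(kind = "skeleton", owner = si,
                                   chunk = NA_integer_, n_chunks = NA_integer_)
      skel_idx[[si]] <- c(skel_idx[[si]], length(segs))
    }
  }
  n <- length(segs)
  E1 <- t(vapply(segs, function(s) s$points[1, ], numeric(3)))
  E2 <- t(vapply(segs, function(s) s$points[nrow(s$points), ], numeric(3)))
  dirs <- t(vapply(segs, function(s) s$direction, numeric(3)))
  pts <- do.call(rbind, lapply(segs, function(s) s$points))
  counts <- vapply(segs, function(s) nrow(s$points), integer(1))
  vals <- sample_volume(vol, pts)
  grp <- rep.int(seq_len(n), counts)
  mu <- as.numeric(tapply(vals, grp, mean))
  sg <- sqrt(as.numeric(tapply(vals, grp, function(v) mean((v - mean(v))^2))))
  structure(list(tree = tree, vol = vol, params = params,
                 branches = branches, segs = segs,
                 meta = meta, chunk_idx = chunk_idx, skel_idx = skel_idx,
                 skeleton = skeleton,
                 E1 = E1, E2 = E2, dirs = dirs, mu = mu, sigma = sg,
                 scale = vol$dtype_max),
            class = "confidence_context")
}

#' @export
print.confidence_context <- function(x, ...) {
  cat(sprintf("<confidence_context> %d branches, %d segments (%d skeleton)\n",
              length(x$branches), length(x$segs),
              sum(vapply(x$meta, function(m) m$kind == "skeleton", logical(1)))))
  invisible(x)
}

# Endpoint segments of a skeleton branch: one per chain end, anchored at the
# endpoint, direction pointing into the chain (the direction growth would
# take away from a connection at that endpoint).
skeleton_end_segments <- function(skel, L) {
  P <- skel$chain_xyz
  if (nrow(P) < 2L) return(list())
  R <- resample_polyline(P)
  s1 <- R[seq_len(min(L, nrow(R))), , drop = FALSE]
  Rr <- R[rev(seq_len(nrow(R))), , drop = FALSE]
  s2 <- Rr[seq_len(min(L, nrow(Rr))), , drop = FALSE]
  out <- list(make_segment(s1, end = "proximal", kind = "skeleton",
                           branch_id = NA_integer_, short = nrow(s1) < L,
                           id2 = skel$skeleton_id))
  # a very short chain yields two near-identical segments; keep both ends
  out[[2]] <- make_segment(s2, end = "proximal", kind = "skeleton",
                           branch_id = NA_integer_, short = nrow(s2) < L,
                           id2 = skel$skeleton_id)
  out
}

# Universe indices whose minimum endpoint distance to segment index `a`
# (or to an ad-hoc segment) lies strictly within (0, Td).
ctx_in_range <- function(ctx, a, exclude = integer(0)) {
  ea <- rbind(ctx$E1[a, ], ctx$E2[a, ])
  d <- ctx_dist_to(ctx, ea)
  ok <- d > 1e-9 & d < ctx$params$Td
  ok[exclude] <- FALSE
  which(ok)
}

# Min distance from every universe segment to a set of endpoint rows (k x 3).
ctx_dist_to <- function(ctx, ep) {
  d2 <- function(E) {
    m <- outer(rowSums(E^2), rowSums(ep^2), "+") - 2 * E %*% t(ep)
    sqrt(pmax(apply(m, 1, min), 0))
  }
  pmin(d2(ctx$E1), d2(ctx$E2))
}

# Energy of candidate indices `cand` for a connection conditioned on index
# `a` (optionally with an overridden conditioning direction).
ctx_energies <- function(ctx, a, cand, a_dir = NULL) {
  p <- ctx$params
  if (is.null(a_dir)) a_dir <- ctx$dirs[a, ]
  ct <- pmax(-1, pmin(1, ctx$dirs[cand, , drop = FALSE] %*% a_dir))
  theta <- acos(ct) * 180 / pi
  U <- p$alpha * abs(ctx$mu[cand] - ctx$mu[a]) / ctx$scale +
       p$beta * abs(ctx$sigma[cand] - ctx$sigma[a]) / ctx$scale
  U[theta >= 90] <- Inf
  list(U = as.numeric(U), theta = as.numeric(theta))
}

# P(cur | a) with the strict-window candidate set; `extra` indices are force-included
# (used when a detector compares the current child against a specific
# competitor over the shared set).
ctx_probability <- function(ctx, a, cur, extra = integer(0), a_dir = NULL) {
  S <- union(union(ctx_in_range(ctx, a, exclude = a), cur), extra)
  en <- ctx_energies(ctx, a, S, a_dir = a_dir)
  pr <- candidate_probabilities(en$U)
  list(p = pr[match(cur, S)], S = S, U = en$U, theta = en$theta, prob = pr)
}

ctx_branch <- function(ctx, branch_id) ctx$branches[[branch_id]]
ctx_proximal_idx <- function(ctx, branch_id) ctx$chunk_idx[[branch_id]][1]
ctx_distal_idx <- function(ctx, branch_id) {
  ids <- ctx$chunk_idx[[branch_id]]
  ids[length(ids)]
}

#' Global connection confidence PG of a branch
#'
#' The connection probability of the branch's proximal branching segment
#' conditioned on its parent's distal branching segment, with candidates
#' drawn from all nearby branch and skeleton segments. The soma branch has
#' no parent and gets PG = 1 by convention.
#'
#' @param ctx a [confidence_context()]
#' @param branch_id branch id
#' @return probability in `[0, 1]`
#' @export
global_confidence <- function(ctx, branch_id) {
  b <- ctx_branch(ctx, branch_id)
  if (is.na(b$parent_branch_id)) return(1)
  a <- ctx_distal_idx(ctx, b$parent_branch_id)
  cur <- ctx_proximal_idx(ctx, branch_id)
  ctx_probability(ctx, a, cur)$p
}

#' Local connection confidence PL of a branch
#'
#' Each consecutive segment of the branch is scored by its connection
#' probability given its predecessor (the first segment uses the parent's
#' distal segment); PL aggregates the per-segment probabilities by their
#' mean, which keeps PL in `[0, 1]` (set `pl_sum = TRUE` in the parameters
#' for the literal sum).
#'
#' @inheritParams global_confidence
#' @export
local_confidence <- function(ctx, branch_id) {
  b <- ctx_branch(ctx, branch_id)
  ids <- ctx$chunk_idx[[branch_id]]
  preds <- if (is.na(b$parent_branch_id)) {
    if (length(ids) == 1L) return(1)
    cbind(ids[-length(ids)], ids[-1])
  } else {
    cbind(c(ctx_distal_idx(ctx, b$parent_branch_id), ids[-length(ids)]), ids)
  }
  ps <- vapply(seq_len(nrow(preds)), function(i)
    ctx_probability(ctx, preds[i, 1], preds[i, 2])$p, numeric(1))
  if (ctx$params$pl_sum) sum(ps) else mean(ps)
}

#' Branch confidence: min of global and local confidences
#'
#' @inheritParams global_confidence
#' @return a `confidence_result`: `branch_id`, `PG`, `PL`, `confidence`,
#'   `low_confidence` (confidence strictly below `tau`).
#' @export
branch_confidence <- function(ctx, branch_id) {
  PG <- global_confidence(ctx, branch_id)
  PL <- local_confidence(ctx, branch_id)
  conf <- min(PG, PL)
  structure(list(branch_id = branch_id, PG = PG, PL = PL,
                 confidence = conf,
                 low_confidence = conf < ctx$params$tau),
            class = "confidence_result")
}
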