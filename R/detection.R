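# The five artifact detectors, connection legality, and the orchestrator
# that labels every branch and every skeleton branch.

#' Artifact labels
#' @export
artifact_labels <- c("NONE", "OVER_TRACING", "CONN_ERR_BRANCH_SKELETON",
                     "CONN_ERR_BRANCH_BRANCH", "BRANCH_MISSING",
                     "INCOMPLETE_TRACING", "LOW_CONFIDENCE", "CONFIRMED")

# labels a parent passes down to its whole subtree
transitive_labels <- c("OVER_TRACING", "CONN_ERR_BRANCH_SKELETON")

#' Connection legality between a branching segment and a candidate segment
#'
#' With gap vector `g` from the current segment's free endpoint (its anchor)
#' to the candidate's anchor endpoint: `theta` = angle(current direction, g),
#' `phi` = angle(g, candidate direction oriented away from the gap),
#' `omega` = angle(current direction, candidate direction). The connection is
#' legal when all three angles are at most 90 degrees (inclusive). A
#' zero-length gap falls back to the current direction for `g`.
#'
#' @param seg_cur current branching segment (direction = growth direction,
#'   anchor = the free endpoint the connection would extend)
#' @param seg_cand candidate segment (skeleton endpoint segment or branch
#'   proximal segment; direction points away from its anchor)
#' @return list `legal`, `angles` (theta, phi, omega)
#' @export
connection_legality <- function(seg_cur, seg_cand) {
  g <- seg_cand$anchor - seg_cur$anchor
  if (sqrt(sum(g^2)) < 1e-9) g <- seg_cur$direction
  th <- angle_between(seg_cur$direction, g)
  ph <- angle_between(g, seg_cand$direction)
  om <- angle_between(seg_cur$direction, seg_cand$direction)
  list(legal = th <= 90 && ph <= 90 && om <= 90,
       angles = c(theta = th, phi = ph, omega = om))
}

# detection context = confidence context + image context + caches
detection_context <- function(tree, vol, soma, soma_radius,
                              params = confidence_params(), ictx = NULL, ...) {
  if (is.null(ictx))
    ictx <- image_context(vol, soma, soma_radius, params, ...)
  skel <- skeleton_for_tree(ictx, tree)
  ctx <- confidence_context(tree, vol, params, skeleton = skel)
  ctx$ictx <- ictx
  ctx$dil_mask <- dilate_mask26(ictx$mask)
  ctx
}

# angle of a branch against its parent at the branching point
parent_child_angle <- function(ctx, branch_id) {
  b <- ctx_branch(ctx, branch_id)
  if (is.na(b$parent_branch_id)) return(NA_real_)
  a <- ctx_distal_idx(ctx, b$parent_branch_id)
  cur <- ctx_proximal_idx(ctx, branch_id)
  angle_between(ctx$dirs[a, ], ctx$dirs[cur, ])
}

#' Over-tracing detector
#'
#' A branch is over-traced when the angle against its parent's distal
#' branching segment reaches 90 degrees, or when the branch lacks tubularity
#' (fewer than 70 percent of its nodes on tubular voxels). The two cases are
#' disjunctive; the root branch is exempt.
#'
#' @param ctx a detection context (see [classify_branches()])
#' @param branch_id branch id
#' @return logical; attribute `"why"` records which case fired
#' @export
detect_over_tracing <- function(ctx, branch_id) {
  b <- ctx_branch(ctx, branch_id)
  if (is.na(b$parent_branch_id)) return(FALSE)
  th <- parent_child_angle(ctx, branch_id)
  tub <- mean(points_tubular(ctx$dil_mask, node_xyz(ctx$tree, b$node_path))) >=
    0.70 - 1e-12
  out <- (th >= 90) || !tub
  attr(out, "why") <- if (th >= 90) "angle" else if (!tub) "tubularity" else ""
  out
}

#' Branch-skeleton connection-error detector
#'
#' Among legal, tubular skeleton endpoint segments within `Td` of the
#' parent's distal branching segment, fires when some skeleton segment's
#' connection probability given the parent exceeds the current child's
#' (probabilities over the shared candidate set).
#'
#' @inheritParams detect_over_tracing
#' @return logical; attributes `"evidence"` (skeleton id), `"p_current"`,
#'   `"p_evidence"`
#' @export
detect_conn_err_branch_skeleton <- function(ctx, branch_id) {
  b <- ctx_branch(ctx, branch_id)
  if (is.na(b$parent_branch_id)) return(FALSE)
  a <- ctx_distal_idx(ctx, b$parent_branch_id)
  cur <- ctx_proximal_idx(ctx, branch_id)
  skel_all <- unlist(ctx$skel_idx)
  if (!length(skel_all)) return(FALSE)
  ea <- rbind(ctx$E1[a, ], ctx$E2[a, ])
  d <- ctx_dist_to(ctx, ea)[skel_all]
  cand <- skel_all[d > 1e-9 & d < ctx$params$Td]
  cand <- cand[vapply(cand, function(s)
    connection_legality(ctx$segs[[a]], ctx$segs[[s]])$legal, logical(1))]
  if (!length(cand)) return(FALSE)
  pr <- ctx_probability(ctx, a, cur, extra = cand)
  p_cur <- pr$p
  p_sk <- pr$prob[match(cand, pr$S)]
  best <- which.max(p_sk)
  out <- p_sk[best] > p_cur
  attr(out, "evidence") <- ctx$meta[[cand[best]]]$owner
  attr(out, "p_current") <- p_cur
  attr(out, "p_evidence") <- p_sk[best]
  out
}

#' Branch-branch connection-error detector
#'
#' A misconnection attaches a branch into the interior of another branch,
#' creating a spurious branching point at which one "child" is simply the
#' host branch's own continuation. The detector therefore fires when a
#' co-child at the same branching point continues the parent nearly
#' collinearly (deflection at most `theta_cont` degrees, measured over a
#' doubled segment length so direction jitter averages out) and its
#' connection probability given the parent exceeds the current child's
#' (probabilities over the shared candidate set). Genuine bifurcation
#' siblings, which deviate by a visible branching angle, never compete.
#'
#' @inheritParams detect_over_tracing
#' @export
detect_conn_err_branch_branch <- function(ctx, branch_id) {
  b <- ctx_branch(ctx, branch_id)
  if (is.na(b$parent_branch_id)) return(FALSE)
  a <- ctx_distal_idx(ctx, b$parent_branch_id)
  cur <- ctx_proximal_idx(ctx, branch_id)

  # continuation test over a longer arc (2L), where direction jitter
  # averages out and a genuine bifurcation angle remains visible
  L2 <- 2L * ctx$params$L
  pb <- ctx_branch(ctx, b$parent_branch_id)
  adir_long <- extract_segment(ctx$tree, pb, "distal", L2)$direction
  sibs <- vapply(ctx$branches, function(x)
    identical(x$parent_branch_id, b$parent_branch_id) &&
      x$branch_id != branch_id, logical(1))
  cont <- integer(0)
  for (sb in which(sibs)) {
    sdir_long <- extract_segment(ctx$tree, ctx_branch(ctx, sb),
                                 "proximal", L2)$direction
    if (angle_between(adir_long, sdir_long) <= ctx$params$theta_cont)
      cont <- c(cont, ctx_proximal_idx(ctx, sb))
  }
  pool <- cont
  if (!length(pool)) return(FALSE)
  pr <- ctx_probability(ctx, a, cur, extra = pool)
  p_cur <- pr$p
  p_ot <- pr$prob[match(pool, pr$S)]
  best <- which.max(p_ot)
  out <- p_ot[best] > p_cur
  attr(out, "evidence") <- ctx$meta[[pool[best]]]$owner
  attr(out, "p_current") <- p_cur
  attr(out, "p_evidence") <- p_ot[best]
  out
}

#' Incomplete-tracing detector
#'
#' A terminal branch is incompletely traced when a tubular skeleton branch
#' endpoint lies strictly within `D` voxels of the branch's distal endpoint
#' and the connection is legal.
#'
#' @inheritParams detect_over_tracing
#' @export
detect_incomplete_tracing <- function(ctx, branch_id) {
  b <- ctx_branch(ctx, branch_id)
  if (!b$is_terminal) return(FALSE)
  # the distal branching segment, anchored at the terminal tip
  tip_seg <- extract_segment(ctx$tree, b, "distal", ctx$params$L)
  N <- as.matrix(ctx$tree$nodes[, c("x", "y", "z")])
  best <- NULL
  for (si in seq_along(ctx$skeleton)) {
    if (!isTRUE(ctx$skeleton[[si]]$tubular)) next
    for (i in ctx$skel_idx[[si]]) {
      s <- ctx$segs[[i]]
      gap <- sqrt(sum((s$anchor - tip_seg$anchor)^2))
      if (gap >= ctx$params$D) next
      # the gap must be the chain's closest approach to the reconstruction;
      # a chain that hugs a branch interior is missing-branch evidence
      d_int <- min(sqrt(colSums((t(N) - s$anchor)^2)))
      if (d_int < gap - 2) next
      leg <- connection_legality(tip_seg, s)
      if (!leg$legal) next
      if (is.null(best) || gap < best$gap)
        best <- list(gap = gap, skeleton = si, angles = leg$angles)
    }
  }
  out <- !is.null(best)
  if (out) {
    attr(out, "evidence") <- best$skeleton
    attr(out, "gap") <- best$gap
  }
  out
}

#' Branch-missing detector (per skeleton branch)
#'
#' A tubular skeleton branch marks a missing branch of a reconstructed host
#' when (a) its connection probability to the nearest reconstructed branch
#' segment exceeds its probability to every other skeleton segment in range,
#' (b) it is longer than those competing skeleton branches, and (c) the
#' connection to the host is legal. The host is the reconstructed branch
#' minimizing the endpoint distance.
#'
#' @param ctx detection context
#' @param skeleton_id index of the skeleton branch
#' @return logical; attribute `"host"` = host branch id
#' @export
detect_branch_missing <- function(ctx, skeleton_id) {
  sk <- ctx$skeleton[[skeleton_id]]
  if (!isTRUE(sk$tubular)) return(FALSE)
  own <- ctx$skel_idx[[skeleton_id]]
  if (!length(own)) return(FALSE)
  # host branch: the one whose polyline comes closest to a chain endpoint
  # (candidacy gated at D, like every skeleton-connection hint)
  nd <- ctx$tree$nodes
  N <- as.matrix(nd[, c("x", "y", "z")])
  best <- NULL
  for (i in own) {
    anc <- ctx$segs[[i]]$anchor
    d <- sqrt(colSums((t(N) - anc)^2))
    j <- which.min(d)
    if (is.null(best) || d[j] < best$d)
      best <- list(d = d[j], node = nd$id[j], skel_seg = i)
  }
  if (best$d >= ctx$params$D) return(FALSE)
  host <- NA_integer_
  for (b in ctx$branches) {
    if (best$node %in% b$node_path[-1]) { host <- b$branch_id; break }
    if (is.na(host) && best$node %in% b$node_path) host <- b$branch_id
  }
  if (is.na(host)) return(FALSE)
  # conditioning segment: the host chunk nearest to the chain endpoint
  anc <- ctx$segs[[best$skel_seg]]$anchor
  ids <- ctx$chunk_idx[[host]]
  dch <- ctx_dist_to(ctx, matrix(anc, 1))[ids]
  a <- ids[which.min(dch)]
  cur <- best$skel_seg
  # (c) legality of attaching the skeleton at the host segment; the host
  # polyline orientation is arbitrary relative to a side branch, so both
  # directions are admissible
  seg_a <- ctx$segs[[a]]
  seg_rev <- make_segment(seg_a$points[rev(seq_len(nrow(seg_a$points))), ,
                                       drop = FALSE],
                          branch_id = seg_a$branch_id)
  leg_fwd <- connection_legality(seg_a, ctx$segs[[cur]])$legal
  leg_rev <- connection_legality(seg_rev, ctx$segs[[cur]])$legal
  if (!leg_fwd && !leg_rev) return(FALSE)
  a_dir <- if (leg_fwd) NULL else -seg_a$direction
  # competitors: endpoint segments of other skeleton chains within range
  rng <- max(best$d, ctx$params$D)
  other_sk <- setdiff(unlist(ctx$skel_idx), own)
  p1 <- ctx_probability(ctx, a, cur, a_dir = a_dir)$p
  if (length(other_sk)) {
    ep <- rbind(ctx$E1[cur, ], ctx$E2[cur, ])
    d <- ctx_dist_to(ctx, ep)[other_sk]
    comp <- other_sk[d > 1e-9 & d < rng]
    for (j in comp) {
      # (a) would the skeleton rather continue another skeleton?
      p2 <- ctx_probability(ctx, j, cur)$p
      if (p2 >= p1) return(FALSE)
      # (b) must be longer than the competitor chain
      if (ctx$skeleton[[ctx$meta[[j]]$owner]]$length >= sk$length)
        return(FALSE)
    }
  }
  out <- TRUE
  attr(out, "host") <- ctx$meta[[a]]$owner
  attr(out, "p_host") <- p1
  out
}

#' Classify every branch of a reconstruction
#'
#' Runs the full detection pass: per branch in breadth-first order the global
#' detectors (over-tracing, branch-skeleton connection error), then the
#' local detectors (branch-branch connection error; incomplete tracing for
#' terminals); branch-missing runs per skeleton branch and attaches to host
#' branches. Branches whose ancestor carries a transitive artifact are
#' marked inherited; remaining unlabeled branches with confidence below
#' `tau` are marked low-confidence. Precedence within a branch:
#' over-tracing, then branch-skeleton, then branch-branch, then incomplete
#' tracing.
#'
#' @param tree a `neuron_tree`
#' @param vol an `image_volume`
#' @param soma numeric `(x, y, z)` soma position (defaults to the root node)
#' @param soma_radius soma radius (defaults to the root node radius, min 5)
#' @param params a [confidence_params()]
#' @param confirmed integer vector of user-confirmed branch ids (skipped by
#'   all detectors)
#' @param ictx optional precomputed [image_context()] for this volume
#' @param ... forwarded to [image_context()]
#' @return an `artifact_report`: `$branches` data.frame (branch_id, label,
#'   PG, PL, confidence, low_confidence, inherited, evidence_kind,
#'   evidence_id, p_current, p_evidence), `$skeletons` data.frame
#'   (skeleton_id, role), plus the context used.
#' @export
classify_branches <- function(tree, vol, soma = NULL, soma_radius = NULL,
                              params = confidence_params(), confirmed = integer(0),
                              ictx = NULL, ...) {
  root <- tree$nodes[tree$nodes$parent == -1L, ]
  if (is.null(soma)) soma <- c(root$x, root$y, root$z)
  if (is.null(soma_radius)) soma_radius <- max(root$radius, 5)
  ctx <- detection_context(tree, vol, soma, soma_radius, params, ictx, ...)
  nb <- length(ctx$branches)

  lab <- rep("NONE", nb)
  inherited <- rep(FALSE, nb)
  ev_kind <- rep(NA_character_, nb)
  ev_id <- rep(NA_integer_, nb)
  p_cur <- rep(NA_real_, nb)
  p_ev <- rep(NA_real_, nb)
  conf <- lapply(seq_len(nb), function(i) branch_confidence(ctx, i))
  skel_role <- rep("unused", length(ctx$skeleton))

  ord <- order(vapply(ctx$branches, `[[`, integer(1), "level"),
               vapply(ctx$branches, `[[`, integer(1), "branch_id"))
  for (i in ord) {
    b <- ctx$branches[[i]]
    if (i %in% confirmed) { lab[i] <- "CONFIRMED"; next }
    anc <- b$parent_branch_id
    while (!is.na(anc)) {
      if (lab[anc] %in% transitive_labels ||
          (inherited[anc] && lab[anc] != "CONFIRMED")) {
        lab[i] <- lab[anc]
        inherited[i] <- TRUE
        ev_kind[i] <- "branch"; ev_id[i] <- anc
        break
      }
      anc <- ctx$branches[[anc]]$parent_branch_id
    }
    if (inherited[i]) next
    ot <- detect_over_tracing(ctx, i)
    if (isTRUE(c(ot))) { lab[i] <- "OVER_TRACING"; next }
    bs <- detect_conn_err_branch_skeleton(ctx, i)
    if (isTRUE(c(bs))) {
      lab[i] <- "CONN_ERR_BRANCH_SKELETON"
      ev_kind[i] <- "skeleton"; ev_id[i] <- attr(bs, "evidence")
      p_cur[i] <- attr(bs, "p_current"); p_ev[i] <- attr(bs, "p_evidence")
      skel_role[ev_id[i]] <- "reroute hint"
      next
    }
    bb <- detect_conn_err_branch_branch(ctx, i)
    if (isTRUE(c(bb))) {
      lab[i] <- "CONN_ERR_BRANCH_BRANCH"
      ev_kind[i] <- "branch"; ev_id[i] <- attr(bb, "evidence")
      p_cur[i] <- attr(bb, "p_current"); p_ev[i] <- attr(bb, "p_evidence")
      next
    }
    it <- detect_incomplete_tracing(ctx, i)
    if (isTRUE(c(it))) {
      lab[i] <- "INCOMPLETE_TRACING"
      ev_kind[i] <- "skeleton"; ev_id[i] <- attr(it, "evidence")
      skel_role[ev_id[i]] <- "gap hint"
    }
  }
  # branch missing, per skeleton branch (skip chains already used as hints)
  for (si in seq_along(ctx$skeleton)) {
    if (skel_role[si] != "unused") next
    bm <- detect_branch_missing(ctx, si)
    if (!isTRUE(c(bm))) next
    host <- attr(bm, "host")
    skel_role[si] <- "missing-branch hint"
    # interior evidence may override a gap hint on the same host: incomplete
    # tracing is the terminal special case of a missing branch
    if (lab[host] %in% c("NONE", "LOW_CONFIDENCE", "INCOMPLETE_TRACING") &&
        !(host %in% confirmed)) {
      lab[host] <- "BRANCH_MISSING"
      ev_kind[host] <- "skeleton"; ev_id[host] <- si
      p_cur[host] <- attr(bm, "p_host")
    }
  }
  low <- lab == "NONE" &
    vapply(conf, function(x) x$low_confidence, logical(1))
  lab[low] <- "LOW_CONFIDENCE"

  branches_df <- data.frame(
    branch_id = seq_len(nb),
    label = lab,
    PG = vapply(conf, `[[`, numeric(1), "PG"),
    PL = vapply(conf, `[[`, numeric(1), "PL"),
    confidence = vapply(conf, `[[`, numeric(1), "confidence"),
    low_confidence = vapply(conf, `[[`, logical(1), "low_confidence"),
    inherited = inherited,
    evidence_kind = ev_kind,
    evidence_id = ev_id,
    p_current = p_cur,
    p_evidence = p_ev,
    stringsAsFactors = FALSE)
  skeletons_df <- if (length(ctx$skeleton))
    data.frame(skeleton_id = seq_along(ctx$skeleton), role = skel_role,
               stringsAsFactors = FALSE)
  else data.frame(skeleton_id = integer(0), role = character(0))
  structure(list(branches = branches_df, skeletons = skeletons_df,
                 ctx = ctx), class = "artifact_report")
}

#' @export
print.artifact_report <- function(x, ...) {
  tb <- table(x$branches$label)
  cat(sprintf("<artifact_report> %d branches, %d skeleton branches\n",
              nrow(x$branches), nrow(x$skeletons)))
  for (nm in names(tb)) cat(sprintf("  %-26s %d\n", nm, tb[[nm]]))
  invisible(x)
}
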