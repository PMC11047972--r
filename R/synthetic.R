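# Deterministic synthetic fixtures: bifurcating tubular trees with
# parent-child intensity similarity and sub-90-degree branching angles,
# rendered into noisy volumes, plus injectors for the five artifact kinds.

unit3 <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# unit vector at `ang` degrees from d, azimuth `az` degrees around it
deflect <- function(d, ang, az) {
  d <- unit3(d)
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit3(cross3(d, a))
  v <- cross3(d, u)
  ar <- ang * pi / 180; azr <- az * pi / 180
  unit3(cos(ar) * d + sin(ar) * (cos(azr) * u + sin(azr) * v))
}

#' Synthetic-fixture configuration
#'
#' Defaults emulate the measured statistics of parent-child branch pairs in
#' mouse neurons: child branching angles well below 90 degrees and
#' parent-child intensity similarity (child intensity = parent intensity
#' plus zero-mean noise).
#'
#' @param shape volume dim `(nz, ny, nx)`
#' @param depth bifurcation levels below the stem
#' @param branch_len branch length range (voxels)
#' @param branch_angle per-child deflection range (degrees, max < 90)
#' @param tube_radius Gaussian tube radius scale (voxels)
#' @param soma_radius soma ball radius (voxels)
#' @param intensity_base stem intensity (8-bit scale)
#' @param intensity_child_sd sd of the parent-to-child intensity step
#' @param bg_mean,bg_sd additive Gaussian background noise
#' @param n_interferers number of interfering tubes from other neurons
#' @param interferer_intensity intensity range for interferers
#' @param node_spacing SWC node spacing along branches (voxels)
#' @param dir_jitter per-step direction jitter (degrees)
#' @param seed integer seed; the fixture is reproducible from (config, seed)
#' @export
synth_config <- function(shape = c(128, 128, 128), depth = 4,
                         branch_len = c(18, 30), branch_angle = c(20, 60),
                         tube_radius = 1.8, soma_radius = 6,
                         intensity_base = 160, intensity_child_sd = 8,
                         bg_mean = 12, bg_sd = 4, n_interferers = 2,
                         interferer_intensity = c(60, 220),
                         node_spacing = 1.5, dir_jitter = 3, seed = 1) {
  stopifnot(branch_angle[2] < 90, intensity_child_sd >= 0, bg_sd >= 0)
  structure(list(shape = shape, depth = depth, branch_len = branch_len,
                 branch_angle = branch_angle, tube_radius = tube_radius,
                 soma_radius = soma_radius, intensity_base = intensity_base,
                 intensity_child_sd = intensity_child_sd,
                 bg_mean = bg_mean, bg_sd = bg_sd,
                 n_interferers = n_interferers,
                 interferer_intensity = interferer_intensity,
                 node_spacing = node_spacing, dir_jitter = dir_jitter,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic ground-truth neuron tree
#'
#' Recursive bifurcating tree rooted at a soma in the volume center. Child
#' directions deviate from the parent direction by an angle drawn inside
#' `branch_angle` (always below 90 degrees); branches random-walk with small
#' direction jitter and steer gently away from the volume walls. Each branch
#' carries an intensity (child = parent + Gaussian step).
#'
#' @param cfg a [synth_config()]
#' @return a `synth_tree`: `$tree` (a `neuron_tree`), `$intensity` (named by
#'   node id), `$soma`, `$cfg`
#' @export
generate_tree <- function(cfg) {
  set.seed(cfg$seed)
  lim <- c(cfg$shape[3], cfg$shape[2], cfg$shape[1])  # x, y, z extents
  margin <- 2 * cfg$tube_radius + 2
  if (min(lim) <= 2 * (margin + 12))
    .nc_stop("nc_generation_error", "volume too small for the configured tree")
  soma <- (lim - 1) / 2

  ids <- 1L; rows <- list(); intens <- c()
  add_node <- function(pos, type, radius, parent, intensity) {
    id <- ids; ids <<- ids + 1L
    rows[[id]] <<- data.frame(id = id, type = type, x = pos[1], y = pos[2],
                              z = pos[3], radius = radius, parent = parent)
    intens[as.character(id)] <<- intensity
    id
  }
  root_id <- add_node(soma, 1L, cfg$soma_radius, -1L, cfg$intensity_base)

  walk_branch <- function(start_pos, dir, parent_id, intensity) {
    len <- runif(1, cfg$branch_len[1], cfg$branch_len[2])
    n_steps <- max(4L, round(len / cfg$node_spacing))
    pos <- start_pos
    last <- parent_id
    for (s in seq_len(n_steps)) {
      if (s > 1L) {
        dir <- unit3(dir + rnorm(3, sd = tan(cfg$dir_jitter * pi / 180)))
        pull <- numeric(3)
        low <- pos < margin + 8; high <- pos > lim - 1 - margin - 8
        pull[low] <- 1; pull[high] <- -1
        if (any(pull != 0)) dir <- unit3(dir + 0.3 * unit3(pull))
      }
      pos <- pos + cfg$node_spacing * dir
      pos <- pmin(pmax(pos, margin), lim - 1 - margin)
      last <- add_node(pos, 3L, 1, last, intensity)
    }
    list(end = pos, dir = dir, id = last)
  }

  queue <- list(list(pos = soma, dir = unit3(rnorm(3)), parent = root_id,
                     level = 0L, intensity = cfg$intensity_base))
  while (length(queue)) {
    ent <- queue[[1]]; queue <- queue[-1]
    w <- walk_branch(ent$pos, ent$dir, ent$parent, ent$intensity)
    if (ent$level < cfg$depth) {
      az1 <- runif(1, 0, 360)
      az2 <- az1 + runif(1, 120, 240)
      for (az in c(az1, az2)) {
        ang <- runif(1, cfg$branch_angle[1], cfg$branch_angle[2])
        cdir <- deflect(w$dir, ang, az)
        cint <- min(max(ent$intensity + rnorm(1, sd = cfg$intensity_child_sd),
                        60), 240)
        queue[[length(queue) + 1L]] <-
          list(pos = w$end, dir = cdir, parent = w$id,
               level = ent$level + 1L, intensity = cint)
      }
    }
  }
  nodes <- do.call(rbind, rows)
  structure(list(tree = neuron_tree(nodes), intensity = intens,
                 soma = soma, cfg = cfg), class = "synth_tree")
}

# interfering tubes from "other neurons": random curved polylines
gen_interferers <- function(cfg, n = cfg$n_interferers) {
  lim <- c(cfg$shape[3], cfg$shape[2], cfg$shape[1])
  out <- list()
  for (i in seq_len(n)) {
    p <- runif(3, 20, lim - 21)
    d <- unit3(rnorm(3))
    len <- runif(1, 50, 90)
    pts <- list(p)
    for (s in seq_len(round(len / 1.5))) {
      d <- unit3(d + rnorm(3, sd = 0.05))
      p <- pmin(pmax(p + 1.5 * d, 4), lim - 5)
      pts[[length(pts) + 1L]] <- p
    }
    out[[i]] <- list(poly = do.call(rbind, pts),
                     intensity = runif(1, cfg$interferer_intensity[1],
                                       cfg$interferer_intensity[2]))
  }
  out
}

# Stamp Gaussian-profile tubes along polylines into vol (max-combined);
# `tubes` is a list of list(poly, intensity).
stamp_tubes <- function(vol, tubes, radius) {
  keep <- vapply(tubes, function(tb) nrow(tb$poly) >= 1, logical(1))
  tubes <- tubes[keep]
  if (!length(tubes)) return(vol)
  pts <- vector("list", length(tubes))
  for (i in seq_along(tubes)) {
    P <- tubes[[i]]$poly
    pts[[i]] <- if (nrow(P) >= 2) resample_polyline_step(P, 0.5) else P
  }
  n_each <- vapply(pts, nrow, integer(1))
  xyz <- do.call(rbind, pts)
  ii <- rep(vapply(tubes, `[[`, numeric(1), "intensity"), n_each)
  .nc_stamp_points(vol, dim(vol), xyz, ii, radius / sqrt(2),
                   as.integer(ceiling(2.2 * radius)))
}

# resample a polyline with a given step (not necessarily 1)
resample_polyline_step <- function(P, step) {
  seglen <- sqrt(rowSums(diff(P)^2))
  P <- P[c(TRUE, seglen > 1e-12), , drop = FALSE]
  if (nrow(P) < 2L) return(P)
  seglen <- sqrt(rowSums(diff(P)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step)
  out <- matrix(0, length(s), 3)
  for (j in 1:3) out[, j] <- stats::approx(cum, P[, j], xout = s)$y
  out
}

#' Render a synthetic tree into an image volume
#'
#' Branches are drawn as tubes with a Gaussian radial profile at their
#' branch intensity, the soma as a bright ball; optional interfering tubes
#' are added; finally additive Gaussian background noise is applied and the
#' result is clamped to the 8-bit range.
#'
#' @param stree a `synth_tree` from [generate_tree()]
#' @param cfg a [synth_config()]
#' @param tubes optional list of `list(poly, intensity)` extra tubes
#' @param noise add background noise (draws from the current RNG stream)
#' @return an `image_volume` (dtype_max 255)
#' @export
render_volume <- function(stree, cfg = stree$cfg, tubes = list(),
                          noise = TRUE) {
  vol <- array(0, cfg$shape)
  nd <- stree$tree$nodes
  pid <- match(nd$parent, nd$id)
  edge_tubes <- list()
  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] == -1L) next
    P <- rbind(c(nd$x[pid[i]], nd$y[pid[i]], nd$z[pid[i]]),
               c(nd$x[i], nd$y[i], nd$z[i]))
    edge_tubes[[length(edge_tubes) + 1L]] <-
      list(poly = P, intensity = stree$intensity[[as.character(nd$id[i])]])
  }
  vol <- stamp_tubes(vol, edge_tubes, cfg$tube_radius)
  # soma ball (slightly brighter, steeper falloff than the tubes)
  d <- dim(vol)
  soma <- stree$soma
  rs <- ceiling(cfg$soma_radius * 1.6)
  xs <- max(0, floor(soma[1]) - rs):min(d[3] - 1, ceiling(soma[1]) + rs)
  ys <- max(0, floor(soma[2]) - rs):min(d[2] - 1, ceiling(soma[2]) + rs)
  zs <- max(0, floor(soma[3]) - rs):min(d[1] - 1, ceiling(soma[3]) + rs)
  g <- expand.grid(z = zs, y = ys, x = xs)
  r <- sqrt((g$x - soma[1])^2 + (g$y - soma[2])^2 + (g$z - soma[3])^2)
  w <- 1.15 * cfg$intensity_base * exp(-(r / cfg$soma_radius)^4)
  idx <- (g$z + 1) + d[1] * (g$y + d[2] * g$x)
  vol[idx] <- pmax(vol[idx], w)

  vol <- stamp_tubes(vol, tubes, cfg$tube_radius)
  if (noise && (cfg$bg_sd > 0 || cfg$bg_mean > 0))
    vol <- vol + rnorm(length(vol), cfg$bg_mean, cfg$bg_sd)
  vol <- round(pmin(pmax(vol, 0), 255))
  image_volume(array(vol, cfg$shape), 255)
}

# ---------------------------------------------------------------------------
# Artifact injection
# ---------------------------------------------------------------------------

artifact_kinds <- c("OVER_TRACING", "CONN_ERR_BRANCH_SKELETON",
                    "CONN_ERR_BRANCH_BRANCH", "BRANCH_MISSING",
                    "INCOMPLETE_TRACING")

#' Build a complete synthetic fixture
#'
#' Generates the ground-truth tree and interferers, optionally injects one
#' artifact into the reconstruction, and renders the volume. Everything is
#' reproducible from `(cfg, kind)` alone; the RNG stream order is: tree,
#' interferers, injection (seeded `seed + 500000`), noise (seeded
#' `seed + 250000`).
#'
#' @param cfg a [synth_config()]
#' @param kind one of `OVER_TRACING`, `CONN_ERR_BRANCH_SKELETON`,
#'   `CONN_ERR_BRANCH_BRANCH`, `BRANCH_MISSING`, `INCOMPLETE_TRACING`,
#'   or NULL for a clean fixture
#' @return a `synth_fixture`: `volume`, `truth`, `recon` (both
#'   `neuron_tree`), `injected` (NULL or the injection record), `soma`,
#'   `config`
#' @export
make_fixture <- function(cfg = synth_config(), kind = NULL) {
  stree <- generate_tree(cfg)
  interf <- gen_interferers(cfg)
  fx <- structure(list(volume = NULL, truth = stree$tree,
                       recon = stree$tree, injected = NULL,
                       stree = stree, interferers = interf,
                       extra_tubes = list(), soma = stree$soma,
                       config = cfg), class = "synth_fixture")
  if (!is.null(kind)) {
    fx <- inject_artifact(fx, kind, seed = cfg$seed + 500000L)
  } else {
    fx <- fixture_render(fx)
  }
  fx
}

fixture_render <- function(fx) {
  set.seed(fx$config$seed + 250000L)
  fx$volume <- render_volume(fx$stree, fx$config,
                             tubes = c(fx$interferers, fx$extra_tubes))
  fx
}

#' @export
print.synth_fixture <- function(x, ...) {
  cat(sprintf("<synth_fixture> seed %d, %d truth nodes, %d recon nodes%s\n",
              x$config$seed, nrow(x$truth$nodes), nrow(x$recon$nodes),
              if (!is.null(x$injected))
                paste0(", injected ", x$injected$kind) else ""))
  invisible(x)
}

#' Inject a reconstruction artifact into a fixture
#'
#' Modifies the fixture's reconstruction (never the ground truth) to carry
#' exactly one artifact of the requested kind, records the ground-truth
#' site, and re-renders the volume (the reroute injection adds a dedicated
#' interfering tube to the image).
#'
#' @param fx a `synth_fixture`
#' @param kind one of the five artifact kinds
#' @param seed RNG seed for the injection choices
#' @export
inject_artifact <- function(fx, kind, seed = 1L) {
  kind <- match.arg(kind, artifact_kinds)
  set.seed(seed)
  fx <- switch(kind,
    OVER_TRACING = inject_over_tracing(fx),
    CONN_ERR_BRANCH_SKELETON = inject_reroute(fx),
    CONN_ERR_BRANCH_BRANCH = inject_misattach(fx),
    BRANCH_MISSING = inject_missing(fx),
    INCOMPLETE_TRACING = inject_truncate(fx))
  fixture_render(fx)
}

branch_dir_at <- function(tree, node_id) {
  nd <- tree$nodes
  i <- match(node_id, nd$id)
  p <- match(nd$parent[i], nd$id)
  if (is.na(p)) .nc_stop("nc_injection_error", "root has no incoming direction")
  unit3(c(nd$x[i] - nd$x[p], nd$y[i] - nd$y[p], nd$z[i] - nd$z[p]))
}

tree_subtree_ids <- function(tree, root_id) {
  nd <- tree$nodes
  out <- root_id
  frontier <- root_id
  while (length(frontier)) {
    frontier <- nd$id[nd$parent %in% frontier]
    out <- c(out, frontier)
  }
  out
}

# spurious branch appended at an interior node: either into plain background
# (no image support) or folded back at a reverse angle (>= 90 deg)
inject_over_tracing <- function(fx) {
  variant <- sample(c("background", "angle"), 1)
  brs <- decompose_branches(fx$truth)
  brs <- brs[vapply(brs, function(b) length(b$node_path) >= 8, logical(1))]
  b <- brs[[sample(length(brs), 1)]]
  k <- sample(4:(length(b$node_path) - 3), 1)
  a_id <- b$node_path[k]
  nd <- fx$truth$nodes
  apos <- unlist(nd[match(a_id, nd$id), c("x", "y", "z")], use.names = FALSE)
  adir <- branch_dir_at(fx$truth, a_id)
  lim <- c(fx$config$shape[3], fx$config$shape[2], fx$config$shape[1])

  if (variant == "angle") {
    sdir <- deflect(-adir, runif(1, 5, 30), runif(1, 0, 360))
  } else {
    # pick, among candidate directions below 80 deg from the parent, the one
    # whose straight path stays farthest from every tree tube
    best <- NULL
    N <- as.matrix(nd[, c("x", "y", "z")])
    for (tryi in 1:24) {
      cand <- deflect(adir, runif(1, 30, 75), runif(1, 0, 360))
      pts <- t(sapply(seq(2, 20, by = 2), function(s) apos + s * cand))
      if (any(pts < 3) || any(t(t(pts) - lim) > -4)) next
      dmin <- min(sqrt(outer(rowSums(pts^2), rowSums(N^2), "+") -
                         2 * pts %*% t(N)))
      if (is.null(best) || dmin > best$d) best <- list(dir = cand, d = dmin)
    }
    if (is.null(best))
      .nc_stop("nc_injection_error", "no background direction available")
    sdir <- best$dir
  }
  n_new <- 13L
  new_id0 <- max(nd$id) + 1L
  pos <- apos
  dir <- sdir
  newrows <- vector("list", n_new)
  parent <- a_id
  for (i in seq_len(n_new)) {
    pos <- pmin(pmax(pos + 1.5 * dir, 2), lim - 3)
    newrows[[i]] <- data.frame(id = new_id0 + i - 1L, type = 3L,
                               x = pos[1], y = pos[2], z = pos[3],
                               radius = 1, parent = parent)
    parent <- new_id0 + i - 1L
  }
  fx$recon <- neuron_tree(rbind(fx$truth$nodes, do.call(rbind, newrows)))
  fx$injected <- list(kind = "OVER_TRACING", variant = variant,
                      site_nodes = new_id0:(new_id0 + n_new - 1L),
                      truth_site = a_id, attach_node = a_id)
  fx
}

# reroute a terminal child onto a dedicated interfering tube; the true
# continuation stays only in the image
inject_reroute <- function(fx) {
  brs <- decompose_branches(fx$truth)
  term <- brs[vapply(brs, function(b)
    b$is_terminal && b$level >= 1 && length(b$node_path) >= 8, logical(1))]
  if (!length(term)) .nc_stop("nc_injection_error", "no eligible branch")
  b <- term[[sample(length(term), 1)]]
  b_id <- b$node_path[1]                       # branching point
  nd <- fx$truth$nodes
  bpos <- unlist(nd[match(b_id, nd$id), c("x", "y", "z")], use.names = FALSE)
  pdir <- branch_dir_at(fx$truth, b_id)        # parent growth direction
  lim <- c(fx$config$shape[3], fx$config$shape[2], fx$config$shape[1])

  # dedicated interferer passing near the branching point
  gdir <- deflect(pdir, runif(1, 35, 70), runif(1, 0, 360))
  s0 <- bpos + runif(1, 4, 6) * gdir
  tdir <- deflect(pdir, runif(1, 30, 65), runif(1, 0, 360))
  pts <- list(s0)
  p <- s0; dirw <- tdir
  for (s in seq_len(26)) {
    dirw <- unit3(dirw + rnorm(3, sd = 0.04))
    p <- pmin(pmax(p + 1.5 * dirw, 4), lim - 5)
    pts[[length(pts) + 1L]] <- p
  }
  poly <- do.call(rbind, pts)
  ii <- runif(1, fx$config$interferer_intensity[1],
              fx$config$interferer_intensity[2])
  fx$extra_tubes <- c(fx$extra_tubes, list(list(poly = poly, intensity = ii)))

  # recon: drop the true terminal branch, trace the interferer instead
  own <- b$node_path[-1]
  keep <- !(fx$truth$nodes$id %in% own)
  new_id0 <- max(nd$id) + 1L
  R <- resample_polyline_step(poly, 1.5)
  n_new <- min(nrow(R), length(own))
  newrows <- vector("list", n_new)
  parent <- b_id
  for (i in seq_len(n_new)) {
    newrows[[i]] <- data.frame(id = new_id0 + i - 1L, type = 3L,
                               x = R[i, 1], y = R[i, 2], z = R[i, 3],
                               radius = 1, parent = parent)
    parent <- new_id0 + i - 1L
  }
  fx$recon <- neuron_tree(rbind(fx$truth$nodes[keep, ],
                                do.call(rbind, newrows)))
  fx$injected <- list(kind = "CONN_ERR_BRANCH_SKELETON",
                      site_nodes = new_id0:(new_id0 + n_new - 1L),
                      truth_site = own, attach_node = b_id)
  fx
}

# reattach a terminal child's proximal end onto a nearby foreign branch
inject_misattach <- function(fx) {
  brs <- decompose_branches(fx$truth)
  nd <- fx$truth$nodes
  N <- as.matrix(nd[, c("x", "y", "z")])
  # prefer terminal victims (no subtree to drag along), fall back to any
  # non-root branch
  term <- brs[vapply(brs, function(b)
    b$is_terminal && b$level >= 1, logical(1))]
  others <- brs[vapply(brs, function(b)
    !b$is_terminal && b$level >= 1, logical(1))]
  term <- c(term[sample(length(term))], others[sample(length(others))])
  for (b in term) {
    c1 <- b$node_path[2]                       # first own node
    cpos <- N[match(c1, nd$id), ]
    excl <- c(b$node_path,
              brs[[b$parent_branch_id]]$node_path %||% integer(0))
    for (f in brs[sample(length(brs))]) {
      if (f$branch_id == b$branch_id) next
      if (!is.na(b$parent_branch_id) && f$branch_id == b$parent_branch_id) next
      np <- f$node_path
      if (length(np) < 7) next
      interior <- np[3:(length(np) - 3)]
      interior <- setdiff(interior, excl)
      if (!length(interior)) next
      fpos <- N[match(interior, nd$id), , drop = FALSE]
      d <- sqrt(rowSums(t(t(fpos) - cpos)^2))
      ok <- which(d > 2 & d < 16)
      for (j in ok[order(d[ok])]) {
        a_id <- interior[j]
        adir <- branch_dir_at(fx$truth, a_id)
        # realized proximal-segment direction of the reattached branch:
        # from the attachment point toward the start of the child's tube
        own_ids <- b$node_path[2:min(6, length(b$node_path))]
        own_pos <- N[match(own_ids, nd$id), , drop = FALSE]
        segdir <- unit3(colMeans(own_pos) - fpos[j, ])
        if (angle_between(adir, segdir) >= 75) next
        if (angle_between(adir, unit3(cpos - fpos[j, ])) >= 80) next
        recon <- fx$truth$nodes
        recon$parent[match(c1, recon$id)] <- a_id
        fx$recon <- neuron_tree(recon)
        fx$injected <- list(kind = "CONN_ERR_BRANCH_BRANCH",
                            site_nodes = b$node_path[-1],
                            truth_site = b$node_path[-1],
                            attach_node = a_id,
                            original_parent = b$node_path[1])
        return(fx)
      }
    }
  }
  .nc_stop("nc_injection_error", "no eligible branch pair for misattachment")
}

# delete a whole child subtree from the reconstruction (image keeps it)
inject_missing <- function(fx) {
  brs <- decompose_branches(fx$truth)
  elig <- brs[vapply(brs, function(b)
    b$is_terminal && b$level >= 1, logical(1))]
  if (!length(elig)) .nc_stop("nc_injection_error", "no eligible subtree")
  b <- elig[[sample(length(elig), 1)]]
  own <- b$node_path[-1]
  keep <- !(fx$truth$nodes$id %in% own)
  fx$recon <- neuron_tree(fx$truth$nodes[keep, ])
  fx$injected <- list(kind = "BRANCH_MISSING", site_nodes = b$node_path[1],
                      truth_site = own, attach_node = b$node_path[1])
  fx
}

# truncate a terminal branch by 30-60 percent (image keeps the full tube)
inject_truncate <- function(fx) {
  brs <- decompose_branches(fx$truth)
  elig <- brs[vapply(brs, function(b)
    b$is_terminal && length(b$node_path) >= 12, logical(1))]
  if (!length(elig)) .nc_stop("nc_injection_error", "no eligible terminal")
  b <- elig[[sample(length(elig), 1)]]
  own <- b$node_path[-1]
  f <- runif(1, 0.3, 0.6)
  n_cut <- max(6L, round(f * length(own)))
  cut <- tail(own, n_cut)
  keep <- !(fx$truth$nodes$id %in% cut)
  fx$recon <- neuron_tree(fx$truth$nodes[keep, ])
  last_kept <- setdiff(own, cut)
  last_kept <- last_kept[length(last_kept)]
  fx$injected <- list(kind = "INCOMPLETE_TRACING", site_nodes = last_kept,
                      truth_site = cut, attach_node = last_kept)
  fx
}

#' Did a detection report recover the injected artifact?
#'
#' True when some branch carrying the injected artifact's label contains at
#' least one of the injection's site nodes.
#'
#' @param fx an injected `synth_fixture`
#' @param report an `artifact_report` computed on `fx$recon`
#' @export
match_injection <- function(fx, report) {
  if (is.null(fx$injected)) .nc_stop("nc_injection_error", "clean fixture")
  hits <- which(report$branches$label == fx$injected$kind)
  for (i in hits) {
    if (any(fx$injected$site_nodes %in% report$ctx$branches[[i]]$node_path))
      return(TRUE)
  }
  if (fx$injected$kind == "BRANCH_MISSING") {
    # the hint is also correct when the evidence skeleton chain traces the
    # deleted structure (host attribution can be ambiguous for a subtree
    # that hugs its sibling)
    tnd <- fx$truth$nodes
    D <- as.matrix(tnd[match(fx$injected$truth_site, tnd$id),
                       c("x", "y", "z")])
    for (i in hits) {
      si <- report$branches$evidence_id[i]
      if (is.na(si)) next
      ch <- report$ctx$skeleton[[si]]$chain_xyz
      d2 <- outer(rowSums(ch^2), rowSums(D^2), "+") - 2 * ch %*% t(D)
      if (sqrt(max(min(d2), 0)) <= 3) return(TRUE)
    }
  }
  FALSE
}

#' Is the injected artifact's flag cleared after the ground-truth fix?
#'
#' Checks a report computed on the corrected reconstruction (the ground
#' truth): no branch containing the artifact site may still carry the
#' injected label.
#'
#' @param fx an injected `synth_fixture`
#' @param report an `artifact_report` computed on `fx$truth`
#' @export
injection_cleared <- function(fx, report) {
  if (is.null(fx$injected)) .nc_stop("nc_injection_error", "clean fixture")
  site <- fx$injected$attach_node
  hits <- which(report$branches$label == fx$injected$kind)
  for (i in hits) {
    if (any(site %in% report$ctx$branches[[i]]$node_path)) return(FALSE)
  }
  TRUE
}
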