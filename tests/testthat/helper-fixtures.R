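# Shared helpers: tiny trees, toy volumes, and independent oracles used to
# cross-check the package's own computations.

# straight path along +x: n nodes spaced `step`
path_tree <- function(n = 10, step = 1, origin = c(0, 0, 0)) {
  nodes <- data.frame(id = seq_len(n), type = 3L,
                      x = origin[1] + (seq_len(n) - 1) * step,
                      y = origin[2], z = origin[3],
                      radius = 1, parent = c(-1L, seq_len(n - 1)))
  nodes$type[1] <- 1L
  neuron_tree(nodes)
}

# Y-shaped tree: stem of `n_stem` nodes along +x, two children of `n_child`
y_tree <- function(n_stem = 6, n_child = 5) {
  rows <- list(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                          radius = 1, parent = -1L))
  for (i in 2:n_stem)
    rows[[i]] <- data.frame(id = i, type = 3L, x = i - 1, y = 0, z = 0,
                            radius = 1, parent = i - 1L)
  id <- n_stem
  for (s in c(1, -1)) {
    parent <- n_stem
    for (j in seq_len(n_child)) {
      id <- id + 1L
      rows[[id]] <- data.frame(id = id, type = 3L,
                               x = n_stem - 1 + j * 0.7071,
                               y = s * j * 0.7071, z = 0,
                               radius = 1, parent = parent)
      parent <- id
    }
  }
  neuron_tree(do.call(rbind, rows))
}

# random binary tree with k bifurcations (node table only, geometry coarse)
random_binary_tree <- function(k, seed = 1) {
  set.seed(seed)
  nodes <- data.frame(id = 1L, type = 1L, x = 50, y = 50, z = 50,
                      radius = 1, parent = -1L)
  tips <- data.frame(id = 1L, x = 50, y = 50, z = 50,
                     dir1 = 1, dir2 = 0, dir3 = 0)
  nid <- 1L
  grow <- function(tip, ndirs) {
    out <- list()
    for (d in ndirs) {
      dir <- unlist(tip[c("dir1", "dir2", "dir3")]) + rnorm(3, sd = 0.4)
      dir <- dir / sqrt(sum(dir^2))
      pos <- c(tip$x, tip$y, tip$z)
      parent <- tip$id
      for (s in 1:4) {
        nid <<- nid + 1L
        pos <- pos + 2 * dir
        nodes <<- rbind(nodes, data.frame(id = nid, type = 3L, x = pos[1],
                                          y = pos[2], z = pos[3], radius = 1,
                                          parent = parent))
        parent <- nid
      }
      out[[length(out) + 1L]] <- data.frame(id = nid, x = pos[1], y = pos[2],
                                            z = pos[3], dir1 = dir[1],
                                            dir2 = dir[2], dir3 = dir[3])
    }
    do.call(rbind, out)
  }
  tips <- grow(tips[1, ], 1)   # stem
  for (b in seq_len(k)) {
    i <- sample(nrow(tips), 1)
    new <- grow(tips[i, ], 1:2)
    tips <- rbind(tips[-i, ], new)
  }
  neuron_tree(nodes)
}

# independent oracle: count maximal branch-point-free paths by brute force
count_branches_bruteforce <- function(tree) {
  nd <- tree$nodes
  nkids <- table(factor(nd$parent, levels = nd$id))
  root <- nd$id[nd$parent == -1L]
  # every child of a branching point (or of the root) starts one branch
  starts <- nd$id[nd$parent != -1L &
                    (nd$parent == root | nkids[as.character(nd$parent)] >= 2)]
  length(starts)
}

# independent oracle for connection probabilities: direct evaluation of the
# energy formula and partition sum on explicit feature/angle tables
oracle_probabilities <- function(mu, sg, theta, mu0, sg0, alpha, beta, scale) {
  U <- ifelse(theta >= 90, Inf,
              alpha * abs(mu - mu0) / scale + beta * abs(sg - sg0) / scale)
  fin <- is.finite(U)
  p <- numeric(length(U))
  if (any(fin)) {
    Z <- sum(U[fin])
    if (Z > 0) p[fin] <- 1 - U[fin] / Z
    else p[fin & U == 0] <- 1 / sum(fin & U == 0)
  }
  p
}

# small uniform volume
uniform_volume <- function(value = 100, d = c(8, 8, 8)) {
  image_volume(array(value, d))
}

# 26-connected component count (independent of the package's linking code)
components26 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  seen <- setNames(rep(FALSE, nrow(idx)), key)
  nbhd <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbhd <- nbhd[rowSums(abs(nbhd)) > 0, ]
  ncomp <- 0L
  for (s in seq_len(nrow(idx))) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    stack <- s
    seen[s] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- t(t(nbhd) + as.integer(idx[cur, ]))
      kk <- paste(nb[, 1], nb[, 2], nb[, 3])
      hit <- which(kk %in% key)
      for (h in hit) {
        j <- match(kk[h], key)
        if (!seen[j]) { seen[j] <- TRUE; stack <- c(stack, j) }
      }
    }
  }
  ncomp
}

# cycle count of the 26-adjacency graph: edges - vertices + components
cycles26 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(0L)
  d2 <- as.matrix(dist(idx))
  edges <- sum(d2 > 0 & d2 < 1.75) / 2   # 26-adjacency: dist <= sqrt(3)
  edges - n + components26(mask)
}

# digital straight tube mask
tube_mask <- function(d = c(9, 9, 40), r = 2) {
  m <- array(FALSE, d)
  cz <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  for (x in 3:(d[3] - 2))
    for (y in 1:d[2])
      for (z in 1:d[1])
        if ((z - cz)^2 + (y - cy)^2 <= r^2) m[z, y, x] <- TRUE
  m
}

# solid torus mask in the z = mid plane
torus_mask <- function(n = 24, R = 7, r = 2) {
  m <- array(FALSE, c(9, n, n))
  c0 <- (n + 1) / 2
  for (x in 1:n) for (y in 1:n) for (z in 1:9) {
    rad <- sqrt((x - c0)^2 + (y - c0)^2)
    if ((rad - R)^2 + (z - 5)^2 <= r^2) m[z, y, x] <- TRUE
  }
  m
}
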