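test_that("tree generation is deterministic and honors the angle bound", {
  cfg <- synth_config(shape = c(96, 96, 96), depth = 3, seed = 14)
  t1 <- generate_tree(cfg)
  t2 <- generate_tree(cfg)
  expect_identical(t1$tree$nodes, t2$tree$nodes)
  expect_identical(t1$intensity, t2$intensity)
  # depth 0 gives a single unbranched stem
  t0 <- generate_tree(synth_config(shape = c(64, 64, 64), depth = 0, seed = 1))
  expect_length(decompose_branches(t0$tree), 1L)
  # exhaustive angle scan: every realized parent-child branching angle < 90
  tr <- t1$tree
  br <- decompose_branches(tr)
  for (b in br) {
    if (is.na(b$parent_branch_id)) next
    pseg <- extract_segment(tr, br[[b$parent_branch_id]], "distal", 8)
    cseg <- extract_segment(tr, b, "proximal", 8)
    expect_lt(angle_between(pseg$direction, cseg$direction), 90)
  }
  # an infeasible volume errors
  expect_error(generate_tree(synth_config(shape = c(16, 16, 16))),
               class = "nc_generation_error")
})

test_that("parent-child intensity steps follow the configured spread", {
  cfg <- synth_config(shape = c(128, 128, 128), depth = 4, seed = 23,
                      intensity_child_sd = 8)
  st <- generate_tree(cfg)
  br <- decompose_branches(st$tree)
  steps <- c()
  for (b in br) {
    if (is.na(b$parent_branch_id)) next
    own <- b$node_path[2]
    pown <- br[[b$parent_branch_id]]$node_path[2]
    steps <- c(steps, st$intensity[as.character(own)] -
                 st$intensity[as.character(pown)])
  }
  expect_gt(length(steps), 20)
  expect_lt(abs(mean(steps)), 8)        # zero-mean steps
  expect_gt(sd(steps), 2)               # spread present
  expect_lt(sd(steps), 20)
})

test_that("rendering puts the branch intensity on the centerline", {
  cfg <- synth_config(shape = c(64, 64, 64), depth = 0, seed = 2,
                      bg_mean = 0, bg_sd = 0, n_interferers = 0,
                      intensity_base = 150)
  st <- generate_tree(cfg)
  vol <- render_volume(st, cfg, noise = FALSE)
  nd <- st$tree$nodes[-1, ]   # skip the soma ball
  nd <- nd[seq(4, nrow(nd)), ]
  P <- round(as.matrix(nd[, c("x", "y", "z")]))
  # brightest voxel adjacent to each node carries the branch intensity
  # (the continuous centerline can fall up to ~0.87 voxel off-grid)
  vals <- vapply(seq_len(nrow(P)), function(i) {
    max(vol$data[P[i, 3] + 0:2, P[i, 2] + 0:2, P[i, 1] + 0:2])
  }, numeric(1))
  expect_true(all(vals >= 140))
  # centerline clearly exceeds background + 3 sd under defaults
  cfgn <- synth_config(shape = c(64, 64, 64), depth = 0, seed = 2,
                       n_interferers = 0)
  fxn <- render_volume(st, cfgn)
  valn <- fxn$data[cbind(P[, 3] + 1, P[, 2] + 1, P[, 1] + 1)]
  expect_gt(mean(valn), cfgn$bg_mean + 3 * cfgn$bg_sd)
})

test_that("fixtures are bit-reproducible from config alone", {
  cfg <- synth_config(shape = c(64, 64, 64), depth = 2, seed = 31,
                      branch_len = c(10, 16))
  f1 <- make_fixture(cfg, kind = "BRANCH_MISSING")
  f2 <- make_fixture(cfg, kind = "BRANCH_MISSING")
  expect_identical(f1$volume$data, f2$volume$data)
  expect_identical(f1$recon$nodes, f2$recon$nodes)
  expect_identical(f1$injected, f2$injected)
})

test_that("injections modify the reconstruction as specified", {
  cfg <- synth_config(shape = c(96, 96, 96), depth = 3, seed = 41,
                      branch_len = c(14, 22))
  # BRANCH_MISSING: node count drops by the deleted subtree size
  fm <- make_fixture(cfg, kind = "BRANCH_MISSING")
  expect_equal(nrow(fm$recon$nodes),
               nrow(fm$truth$nodes) - length(fm$injected$truth_site))
  # INCOMPLETE_TRACING: recon terminal ends >= 3 voxels early
  ft <- make_fixture(cfg, kind = "INCOMPLETE_TRACING")
  tip_t <- ft$injected$truth_site
  nd <- ft$truth$nodes
  tip_pos <- nd[match(tip_t[length(tip_t)], nd$id), c("x", "y", "z")]
  kept <- ft$recon$nodes[match(ft$injected$site_nodes, ft$recon$nodes$id),
                         c("x", "y", "z")]
  expect_gte(sqrt(sum((tip_pos - kept)^2)), 3)
  # OVER_TRACING: spur present in recon, absent from truth
  fo <- make_fixture(cfg, kind = "OVER_TRACING")
  expect_true(all(fo$injected$site_nodes %in% fo$recon$nodes$id))
  expect_false(any(fo$injected$site_nodes %in% fo$truth$nodes$id))
  # CONN_ERR_BRANCH_BRANCH: the child's parent pointer moved
  fb <- make_fixture(cfg, kind = "CONN_ERR_BRANCH_BRANCH")
  c1 <- fb$injected$site_nodes[1]
  expect_equal(fb$recon$nodes$parent[match(c1, fb$recon$nodes$id)],
               fb$injected$attach_node)
  expect_equal(fb$truth$nodes$parent[match(c1, fb$truth$nodes$id)],
               fb$injected$original_parent)
})
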