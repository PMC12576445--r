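test_that("estimate_trunk_radius reads the slab and resists contamination", {
  set.seed(30)
  cyl <- point_cloud(make_cylinder(4000, 0.05, 2.0, sigma = 0.001))
  expect_equal(estimate_trunk_radius(cyl), 0.05, tolerance = 0.002)

  # hollow ring in the slab: radius recovered exactly at high density
  th <- runif(3000, 0, 2 * pi)
  ring <- point_cloud(cbind(0.1 * cos(th), 0.1 * sin(th),
                            runif(3000, 0, 1)))
  expect_equal(estimate_trunk_radius(ring), 0.1, tolerance = 5e-3)

  # ~10% slab contamination from a low branch: within 20% of truth
  set.seed(31)
  trunk <- make_cylinder(2700, 0.05, 2.0, sigma = 0.001)
  branch <- cbind(runif(30, 0.1, 0.5), rnorm(30, 0, 0.02),
                  runif(30, 0.25, 0.35))
  cont <- point_cloud(rbind(trunk, branch))
  expect_lt(abs(estimate_trunk_radius(cont) - 0.05), 0.01)

  expect_warning(estimate_trunk_radius(point_cloud(
    make_cylinder(200, 0.05, 0.1))), "slab")
})

test_that("build_tree_graph connects nodes within the radius with squared weights", {
  nodes <- rbind(c(0, 0, 0), c(0.05, 0, 0), c(0.10, 0, 0))
  skel <- structure(list(nodes = nodes, edges = NULL, source = "lidar",
                         base_idx = 1), class = "skeleton")
  g1 <- build_tree_graph(skel, 0.06)
  expect_equal(igraph::ecount(g1$graph), 2)
  # radius 0.11 also admits the 0.10 pair: 3 edges, brute-force checked
  g2 <- build_tree_graph(skel, 0.11)
  expect_equal(igraph::ecount(g2$graph), 3)
  d <- as.matrix(dist(nodes))
  expected_edges <- sum(d[upper.tri(d)] <= 0.11)
  expect_equal(igraph::ecount(g2$graph), expected_edges)
  w <- sort(igraph::E(g2$graph)$weight)
  expect_equal(w, sort(c(0.05^2, 0.05^2, 0.10^2)), tolerance = 1e-12)

  # the base is the lowest node regardless of order
  nodes2 <- rbind(c(0, 0, 1), c(0, 0, -0.5), c(0, 0.04, 0.2))
  skel2 <- structure(list(nodes = nodes2[, c(1, 2, 3)], edges = NULL,
                          source = "lidar", base_idx = 1),
                     class = "skeleton")
  expect_equal(build_tree_graph(skel2, 2)$base, 2)
  expect_error(build_tree_graph(skel, 0.01), "larger")
})

test_that("path-union pruning removes structures off every base-tip path", {
  # T-shaped tree with a parallel post connected only near the ground;
  # tips given explicitly as the branch tips of the T
  nodes <- rbind(
    cbind(0, 0, seq(0, 1, by = 0.1)),          # trunk 1..11
    cbind(seq(0.1, 0.4, by = 0.1), 0, 1),      # arm right 12..15
    cbind(-seq(0.1, 0.4, by = 0.1), 0, 1),     # arm left 16..19
    cbind(0.15, 0, seq(0.1, 0.9, by = 0.1)))   # post 20..28
  skel <- structure(list(nodes = nodes, edges = NULL, source = "lidar",
                         base_idx = 1), class = "skeleton")
  g <- build_tree_graph(skel, 0.16)
  g$tips <- c(15L, 19L)
  pruned <- graph_prune_supports(g)
  kept <- attr(pruned, "kept_idx")
  expect_true(all(c(1, 15, 19) %in% kept))
  expect_false(any(20:28 %in% kept))

  # a pure path graph is unchanged
  path_nodes <- cbind(0, 0, seq(0, 1, by = 0.05))
  ps <- structure(list(nodes = path_nodes, edges = NULL, source = "lidar",
                       base_idx = 1), class = "skeleton")
  pg <- build_tree_graph(ps, 0.06)
  expect_equal(nrow(graph_prune_supports(pg)$nodes), nrow(path_nodes))

  # two tips sharing the trunk: trunk vertices retained once (set union)
  expect_equal(anyDuplicated(kept), 0)
})

test_that("path-union pruning agrees with a brute-force Dijkstra oracle", {
  set.seed(32)
  for (rep in 1:5) {
    nodes <- cbind(runif(40), runif(40), runif(40))
    skel <- structure(list(nodes = nodes, edges = NULL, source = "lidar",
                           base_idx = 1), class = "skeleton")
    g <- try(build_tree_graph(skel, 0.35), silent = TRUE)
    if (inherits(g, "try-error")) next
    pruned <- graph_prune_supports(g)
    # oracle: Dijkstra on the dense weight matrix within each component
    d <- as.matrix(dist(nodes))^2
    d[sqrt(d) > 0.35] <- Inf
    diag(d) <- 0
    og <- igraph::graph_from_adjacency_matrix(
      ifelse(is.finite(d) & d > 0, d, 0), mode = "undirected",
      weighted = TRUE)
    comp <- igraph::components(og)$membership
    keep <- integer(0)
    for (cc in unique(comp)) {
      verts <- which(comp == cc)
      lb <- if (g$base %in% verts) g$base
            else verts[which.min(nodes[verts, 3])]
      tips <- setdiff(intersect(g$tips, verts), lb)
      keep <- c(keep, lb)
      for (tp in tips)
        keep <- c(keep, as.integer(igraph::shortest_paths(
          og, from = lb, to = tp)$vpath[[1]]))
    }
    expect_setequal(attr(pruned, "kept_idx"), unique(keep))
  }
})

test_that("intensity pruning removes bright support nodes and spares branches", {
  tr <- fixture_support_tree()
  ch <- prune_chain(tr)
  nl <- node_labels(ch$skeleton$nodes, tr$lidar_view,
                    tr$truth$lidar_labels)
  nl_final <- node_labels(ch$final$nodes, tr$lidar_view,
                          tr$truth$lidar_labels)
  support_before <- sum(nl == "support")
  branch_before <- sum(nl == "branch")
  expect_gte(1 - sum(nl_final == "support") / support_before, 0.95)
  # branch retention measured against the pre-pruning skeleton
  expect_gte(sum(nl_final == "branch") / branch_before, 0.95)

  # uniform intensity: no removal
  set.seed(33)
  cyl <- point_cloud(make_cylinder(2000, 0.05, 2), intensity = 0.5 +
                       rnorm(2000, 0, 0.01))
  sk <- extract_skeleton(cyl)
  out <- intensity_prune_supports(sk, cyl, r = 0.05, alpha = 1)
  expect_equal(nrow(out$nodes), nrow(sk$nodes))

  # alpha -> infinity is the identity
  out2 <- intensity_prune_supports(extract_skeleton(tr$lidar_view),
                                   tr$lidar_view, r = ch$r, alpha = 1e9)
  expect_equal(nrow(out2$nodes),
               nrow(extract_skeleton(tr$lidar_view)$nodes))

  # no intensity channel: warning + no-op
  plain <- point_cloud(cyl$coords)
  expect_warning(out3 <- intensity_prune_supports(sk, plain, r = 0.05),
                 "intensity")
  expect_identical(out3, sk)
})

test_that("gap filling bridges breaks with admissible voxels only", {
  # a straight skeleton with a 10 cm hole; the cloud covers the hole
  set.seed(34)
  cloud <- point_cloud(make_cylinder(4000, 0.01, 1.0, sigma = 0.001))
  z <- seq(0.005, 0.995, by = 0.02)
  keep <- z < 0.45 | z > 0.55
  nodes <- cbind(0, 0, z[keep])
  skel <- structure(list(nodes = nodes, edges = NULL, source = "lidar",
                         base_idx = 1), class = "skeleton")
  filled <- fill_gaps(skel, cloud, voxel = 0.02,
                      removed_mask = rep(FALSE, nrow(
                        canopy3d:::voxel_downsample(cloud$coords, 0.02)$centroids)))
  added <- attr(filled, "added_nodes")
  expect_lte(nrow(added), 8)
  expect_gte(nrow(added), 1)
  g <- build_tree_graph(filled, 0.05)
  expect_equal(igraph::components(g$graph)$no, 1)

  # already-connected input is returned untouched
  solid <- structure(list(nodes = cbind(0, 0, z), edges = NULL,
                          source = "lidar", base_idx = 1),
                     class = "skeleton")
  same <- fill_gaps(solid, cloud, voxel = 0.02)
  expect_equal(same$nodes, solid$nodes)

  # if the only bridge runs through removed-support voxels, the broken
  # component is dropped, never reconnected through the mask
  vox <- canopy3d:::voxel_downsample(cloud$coords, 0.02)$centroids
  mask <- vox[, 3] > 0.42 & vox[, 3] < 0.58
  cut <- fill_gaps(skel, cloud, voxel = 0.02, removed_mask = mask)
  expect_equal(attr(cut, "dropped_components"), 1L)
  expect_lt(max(cut$nodes[, 3]), 0.46)
  if (nrow(attr(cut, "added_nodes")) > 0)
    expect_equal(sum(attr(cut, "added_nodes")[, 3] > 0.42 &
                       attr(cut, "added_nodes")[, 3] < 0.58), 0)
})

test_that("smoothing straightens zigzags and preserves topology", {
  # straight path: unchanged up to resampling
  z <- seq(0, 1, by = 0.05)
  straight <- structure(list(nodes = cbind(0, 0, z),
                             edges = cbind(1:(length(z) - 1), 2:length(z)),
                             source = "lidar", base_idx = 1),
                        class = "skeleton")
  sm <- smooth_interpolate(straight)
  expect_lt(max(abs(sm$nodes[, 1:2])), 1e-9)

  # zigzag around a line (endpoints on it): max deviation strictly drops
  zz <- cbind(c(0, rep(c(0.02, -0.02), 9), 0), 0,
              seq(0, 1, length.out = 20))
  zig <- structure(list(nodes = zz,
                        edges = cbind(1:19, 2:20), source = "lidar",
                        base_idx = 1), class = "skeleton")
  smz <- smooth_interpolate(zig, window = 5)
  expect_lt(max(abs(smz$nodes[, 1])), max(abs(zz[, 1])))

  # junction count before equals after
  yn <- rbind(cbind(0, 0, seq(0, 0.5, by = 0.05)),
              cbind(seq(0.05, 0.3, by = 0.05), 0, 0.5),
              cbind(-seq(0.05, 0.3, by = 0.05), 0, 0.5))
  ye <- rbind(cbind(1:10, 2:11), rbind(c(11, 12)), cbind(12:16, 13:17),
              rbind(c(11, 18)), cbind(18:22, 19:23))
  yk <- structure(list(nodes = yn, edges = ye, source = "lidar",
                       base_idx = 1), class = "skeleton")
  smy <- smooth_interpolate(yk)
  degy <- igraph::degree(igraph::graph_from_edgelist(smy$edges,
                                                     directed = FALSE))
  expect_equal(sum(degy >= 3), 1)
})

test_that("branch counting recovers constructed branches and ignores bare poles", {
  tr <- generate_tree(synthetic_tree_spec(n_branches = 8, seed = 104))
  expect_equal(branch_count_chain(tr), 8)

  # bare pole: zero branches
  set.seed(35)
  pole <- point_cloud(make_cylinder(2000, 0.04, 2.0, sigma = 0.002))
  sk <- extract_skeleton(pole)
  bs <- count_branches(smooth_interpolate(graph_prune_supports(
    build_tree_graph(sk, 0.08))))
  expect_equal(bs$num_branch, 0)
})

test_that("branch counting is invariant to rigid motion", {
  tr <- generate_tree(synthetic_tree_spec(n_branches = 7, seed = 106))
  pc <- tr$lidar_view
  sk <- extract_skeleton(pc)
  r <- estimate_trunk_radius(pc)
  bs1 <- count_branches(smooth_interpolate(graph_prune_supports(
    build_tree_graph(sk, 2 * r))))
  Tr <- rigid_transform(rot_axis(c(0.2, 0.1, 1), 0.4), c(3, -2, 0.5))
  sk2 <- sk
  sk2$nodes <- apply_transform(sk$nodes, Tr)
  sk2$base_idx <- which.min(sk2$nodes[, 3])
  bs2 <- count_branches(smooth_interpolate(graph_prune_supports(
    build_tree_graph(sk2, 2 * r))))
  expect_equal(bs2$num_branch, bs1$num_branch)
})
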