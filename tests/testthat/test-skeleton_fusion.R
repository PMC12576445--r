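test_that("rigid transforms compose, invert and preserve distances", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "proper rotation")

  Rm <- rot_axis(c(0, 0, 1), pi / 2)
  T90 <- rigid_transform(Rm)
  expect_equal(apply_transform(rbind(c(1, 0, 0)), T90), rbind(c(0, 1, 0)),
               tolerance = 1e-12)

  set.seed(20)
  Tr <- rigid_transform(rot_axis(rnorm(3), 0.7), c(0.2, -0.4, 1))
  pts <- matrix(rnorm(60), 20)
  there <- apply_transform(pts, Tr)
  back <- apply_transform(there, invert_transform(Tr))
  expect_equal(back, pts, tolerance = 1e-9)
  # pairwise distances preserved to 1e-9 relative
  expect_equal(as.vector(dist(there)), as.vector(dist(pts)),
               tolerance = 1e-9)
  # composition: applying a then b equals the composed transform
  Tb <- rigid_transform(rot_axis(rnorm(3), 0.3), c(1, 0, 0))
  expect_equal(apply_transform(apply_transform(pts, Tr), Tb),
               apply_transform(pts, compose_transform(Tb, Tr)),
               tolerance = 1e-12)
})

test_that("skeleton contraction collapses a cylinder onto its axis", {
  set.seed(21)
  cyl <- point_cloud(make_cylinder(3000, 0.05, 2.0, cx = 1, cy = 2,
                                   sigma = 0.002))
  sk <- extract_skeleton(cyl)
  expect_lt(nrow(sk$nodes), npoints(cyl))        # M < N always
  d <- sqrt((sk$nodes[, 1] - 1)^2 + (sk$nodes[, 2] - 2)^2)
  expect_lt(median(d), 0.01)
  # nodes stay inside the input bounding box and near the cloud
  bb <- apply(cyl$coords, 2, range)
  expect_true(all(sk$nodes >= matrix(bb[1, ] - 0.01, nrow(sk$nodes), 3,
                                     byrow = TRUE)))
  near <- RANN::nn2(cyl$coords, sk$nodes, k = 1)$nn.dists[, 1]
  expect_lt(max(near), 0.06)
  expect_equal(sk$base_idx, which.min(sk$nodes[, 3]))
  expect_error(extract_skeleton(point_cloud(matrix(runif(30), 10))),
               "at least 100")
})

test_that("a Y-shaped tube skeletonizes with one junction", {
  set.seed(22)
  trunk <- make_cylinder(1500, 0.03, 1.0, sigma = 0.002)
  arm <- function(dirv, n = 900) {
    t <- runif(n, 0, 0.8)
    th <- runif(n, 0, 2 * pi)
    axis <- dirv / sqrt(sum(dirv^2))
    u <- c(axis[2], -axis[1], 0); u <- u / sqrt(sum(u^2))
    v <- c(axis[2] * u[3] - axis[3] * u[2],
           axis[3] * u[1] - axis[1] * u[3],
           axis[1] * u[2] - axis[2] * u[1])
    sweep(outer(t, axis) + 0.03 * (outer(cos(th), u) + outer(sin(th), v)),
          2, -c(0, 0, 1)) + matrix(rnorm(3 * n, 0, 0.002), n)
  }
  y <- point_cloud(rbind(trunk, arm(c(0.6, 0, 0.8)), arm(c(-0.6, 0, 0.8))))
  sk <- extract_skeleton(y)
  g <- build_tree_graph(sk, 0.08)
  pr <- graph_prune_supports(g)
  sm <- smooth_interpolate(pr)
  gg <- igraph::graph_from_edgelist(sm$edges, directed = FALSE)
  expect_equal(sum(igraph::degree(gg) >= 3), 1)
})

test_that("coarse registration of identical skeletons is the identity", {
  sk <- fixture_tree_skeleton()
  Tc <- coarse_register(sk, sk)
  expect_lt(rotation_err_deg(Tc$matrix[1:3, 1:3]), 1e-3)
  expect_lt(sqrt(sum(Tc$matrix[1:3, 4]^2)), 1e-4)
  expect_lt(attr(Tc, "rmse"), 1e-6)
})

test_that("coarse + fine registration recovers a constructed rigid motion", {
  sk <- fixture_tree_skeleton()
  set.seed(23)
  Ttrue <- rigid_transform(rot_axis(c(0, 0, 1), 25 * pi / 180),
                           c(0.5, 0.3, 0.1))
  src <- sk
  src$nodes <- apply_transform(
    sk$nodes + matrix(rnorm(length(sk$nodes), 0, 0.01), nrow(sk$nodes)),
    Ttrue)
  Tc <- coarse_register(src, sk, seed = 23)
  Tf <- fine_register(src, sk, init = Tc)
  Terr <- compose_transform(Tf, Ttrue)
  expect_lt(rotation_err_deg(Terr$matrix[1:3, 1:3]), 2)
  expect_lt(sqrt(sum(Terr$matrix[1:3, 4]^2)), 0.02)
  expect_lte(attr(Tf, "rmse"), attr(Tc, "rmse"))
  expect_lt(attr(Tf, "rmse"), 0.02)
})

test_that("coarse registration tolerates spurious nodes", {
  sk <- fixture_tree_skeleton()
  set.seed(24)
  Ttrue <- rigid_transform(rot_axis(c(0.1, 0.2, 1), 15 * pi / 180),
                           c(-0.3, 0.2, 0))
  m <- nrow(sk$nodes)
  extra <- matrix(runif(3 * round(0.2 * m)), ncol = 3)
  extra <- sweep(sweep(extra, 2, c(1, 1, 2.5), "*"), 2, c(-0.5, -0.5, 0))
  src <- sk
  src$nodes <- apply_transform(
    rbind(sk$nodes + matrix(rnorm(3 * m, 0, 0.005), m), extra), Ttrue)
  Tc <- coarse_register(src, sk, seed = 24)
  moved <- apply_transform(src$nodes[1:m, ], Tc)
  rmse <- sqrt(mean(rowSums((moved - sk$nodes)^2)))
  expect_lt(rmse, 0.05)
})

test_that("fine registration is a fixed point at a perfect init and improves offsets", {
  sk <- fixture_tree_skeleton()
  Tf <- fine_register(sk, sk, init = rigid_transform())
  expect_equal(Tf$matrix, diag(4), tolerance = 1e-8)

  off <- rigid_transform(diag(3), c(0.03, 0, 0))
  src <- sk
  src$nodes <- apply_transform(sk$nodes, off)
  Tf2 <- fine_register(src, sk, init = rigid_transform())
  res <- apply_transform(src$nodes, Tf2) - sk$nodes
  expect_lt(sqrt(mean(rowSums(res^2))), 0.005)
})

test_that("registration is invariant to a common pre-rotation", {
  sk <- fixture_tree_skeleton()
  set.seed(25)
  Ttrue <- rigid_transform(rot_axis(c(0, 0, 1), 0.3), c(0.2, 0.1, 0))
  jit <- matrix(rnorm(length(sk$nodes), 0, 0.005), nrow(sk$nodes))
  src <- sk; src$nodes <- apply_transform(sk$nodes + jit, Ttrue)
  T1 <- fine_register(src, sk, init = coarse_register(src, sk, seed = 1))

  Rpre <- rigid_transform(rot_axis(c(0, 0, 1), 0.5))
  skR <- sk; skR$nodes <- apply_transform(sk$nodes, Rpre)
  srcR <- sk; srcR$nodes <- apply_transform(src$nodes, Rpre)
  T2 <- fine_register(srcR, skR, init = coarse_register(srcR, skR, seed = 1))
  # conjugation by the common rotation maps one recovery onto the other
  T2_conj <- compose_transform(invert_transform(Rpre),
                               compose_transform(T2, Rpre))
  err <- compose_transform(T2_conj, invert_transform(T1))
  expect_lt(rotation_err_deg(err$matrix[1:3, 1:3]), 1)
  expect_lt(sqrt(sum(err$matrix[1:3, 4]^2)), 0.02)
})

test_that("fuse_clouds concatenates with provenance and carried channels", {
  set.seed(26)
  lidar <- point_cloud(matrix(runif(30), 10), intensity = runif(10),
                       source = "lidar")
  drone <- point_cloud(matrix(runif(18), 6),
                       rgb = matrix(100L, 6, 3), source = "drone")
  fused <- fuse_clouds(lidar, drone, rigid_transform())
  expect_equal(npoints(fused), 16)     # N_out = N_lidar + N_drone
  expect_equal(fused$coords[1:10, ], lidar$coords, ignore_attr = TRUE)
  expect_equal(fused$coords[11:16, ], drone$coords, ignore_attr = TRUE)
  prov <- attr(fused, "provenance")
  expect_equal(prov, c(rep("lidar", 10), rep("drone", 6)))
  expect_true(all(is.na(fused$intensity[11:16])))
  expect_true(all(!is.na(fused$rgb[11:16, ])))
  expect_error(fuse_clouds(lidar, lidar, rigid_transform()), "two")

  # a known transform lands drone points at their true positions
  Tr <- rigid_transform(rot_axis(c(0, 0, 1), 0.4), c(1, 2, 0))
  moved_in <- apply_transform(drone, invert_transform(Tr))
  fused2 <- fuse_clouds(lidar, moved_in, Tr)
  expect_equal(fused2$coords[11:16, ], drone$coords, tolerance = 2e-2,
               ignore_attr = TRUE)
})
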