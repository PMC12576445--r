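test_that("blossom_mask keeps bright points and degenerates to all-retained", {
  n <- 200
  rgb <- rbind(matrix(rep(c(250, 248, 245), 100), ncol = 3, byrow = TRUE),
               matrix(rep(c(60, 120, 50), 100), ncol = 3, byrow = TRUE))
  pc <- point_cloud(matrix(runif(3 * n), n), rgb = rgb)
  got <- blossom_mask(pc)
  expect_setequal(got, 1:100)

  flat <- point_cloud(matrix(runif(30), 10),
                      rgb = matrix(128L, 10, 3))
  expect_length(blossom_mask(flat), 10)
  expect_error(blossom_mask(point_cloud(diag(3))), "rgb")

  # generated tree: labelled recall and precision
  tr <- fixture_tree()
  cand <- blossom_mask(tr$drone_view)
  truth <- which(tr$truth$drone_labels == "blossom")
  expect_gte(length(intersect(cand, truth)) / length(truth), 0.95)
  expect_gte(length(intersect(cand, truth)) / length(cand), 0.90)
})

test_that("remove_near_skeleton drops trunk-surface candidates and keeps far ones", {
  nodes <- cbind(0, 0, seq(0, 1, by = 0.05))
  skel <- structure(list(nodes = nodes, edges = NULL, source = "lidar",
                         base_idx = 1), class = "skeleton")
  pts <- point_cloud(rbind(c(0, 0.01, 0.5),     # on the trunk
                           c(0.15, 0, 0.5)))    # 3r away
  out <- remove_near_skeleton(pts, 1:2, skel, r = 0.05)
  expect_identical(out, 2L)
  empty <- structure(list(nodes = matrix(numeric(0), ncol = 3)),
                     class = "skeleton")
  expect_warning(keep <- remove_near_skeleton(pts, 1:2, empty, 0.05),
                 "empty")
  expect_identical(keep, 1:2)
})

test_that("stratify splits the crown span into thirds, bands closed above", {
  expect_identical(stratify(1, 1, 4), "lower")
  expect_identical(stratify(2.5, 1, 4), "middle")
  expect_identical(stratify(2, 1, 4), "lower")    # boundary -> band below
  expect_identical(stratify(3, 1, 4), "middle")
  expect_identical(stratify(4, 1, 4), "upper")
  expect_error(stratify(1, 2, 2), "apex_z")
})

test_that("DBSCAN clustering matches the brute-force oracle and the floor rule", {
  set.seed(50)
  b1 <- matrix(rnorm(300, sd = 0.01), 100) +
    matrix(rep(c(0, 0, 0), 100), ncol = 3, byrow = TRUE)
  b2 <- matrix(rnorm(300, sd = 0.01), 100) +
    matrix(rep(c(1, 0, 0), 100), ncol = 3, byrow = TRUE)
  cl <- cluster_blossoms(rbind(b1, b2), eps = 0.1, min_pts = 20)
  expect_length(cl, 2)

  expect_length(cluster_blossoms(matrix(runif(45), 15), eps = 0.1,
                                 min_pts = 20), 0)

  for (rep in 1:4) {
    pts <- matrix(runif(3 * 150), ncol = 3)
    eps <- runif(1, 0.1, 0.25)
    mine <- canopy3d:::dbscan_points(pts, eps, 5)
    orac <- oracle_dbscan(pts, eps, 5)
    # same partition up to label names: compare co-membership
    expect_equal(outer(mine, mine, "==") & mine > 0,
                 outer(orac, orac, "==") & orac > 0)
    expect_equal(mine == 0, orac == 0)
  }
})

test_that("cluster classification enforces the n<50 noise rule and separates sizes", {
  set.seed(51)
  # two planted populations: singles (n~80, ~4 cm) and multis (n~300, ~12 cm)
  mk_blob <- function(n, centre, sd) matrix(rnorm(3 * n, 0, sd), n) +
    matrix(centre, n, 3, byrow = TRUE)
  coords <- rbind(
    do.call(rbind, lapply(1:6, function(i) mk_blob(80, c(i, 0, 0), 0.01))),
    do.call(rbind, lapply(1:4, function(i) mk_blob(300, c(i, 2, 0), 0.03))),
    mk_blob(49, c(0, 4, 0), 0.01),
    mk_blob(50, c(2, 4, 0), 0.01))
  cl <- cluster_blossoms(coords, eps = 0.1, min_pts = 20)
  cl <- classify_clusters(cl, coords, seed = 1)
  ns <- vapply(cl, `[[`, 0, "n")
  cls <- vapply(cl, `[[`, "", "cls")
  expect_true(all(cls[ns < 50] == "noise"))
  expect_true(all(cls[ns == 50] != "noise"))   # boundary cluster eligible
  big <- ns >= 50
  truth <- ifelse(ns[big] > 200, "multi", "single")
  expect_gte(mean(cls[big] == truth), 0.95)
})

test_that("classification is deterministic and order-independent", {
  set.seed(52)
  mk_blob <- function(n, centre, sd) matrix(rnorm(3 * n, 0, sd), n) +
    matrix(centre, n, 3, byrow = TRUE)
  coords <- rbind(
    do.call(rbind, lapply(1:5, function(i) mk_blob(80, c(i, 0, 0), 0.01))),
    do.call(rbind, lapply(1:3, function(i) mk_blob(250, c(i, 2, 0), 0.03))))
  cl <- cluster_blossoms(coords, eps = 0.1, min_pts = 20)
  l1 <- vapply(classify_clusters(cl, coords, seed = 9), `[[`, "", "cls")
  l2 <- vapply(classify_clusters(cl, coords, seed = 9), `[[`, "", "cls")
  expect_identical(l1, l2)
  perm <- rev(seq_along(cl))
  lp <- vapply(classify_clusters(cl[perm], coords, seed = 9), `[[`, "",
               "cls")
  expect_identical(lp, l1[perm])
})

test_that("multi-flower splitting yields disjoint single subsets", {
  set.seed(53)
  mk_blob <- function(n, centre, sd) matrix(rnorm(3 * n, 0, sd), n) +
    matrix(centre, n, 3, byrow = TRUE)
  # two touching flowers plus reference singles for the classifier
  coords <- rbind(
    mk_blob(90, c(0, 0, 0), 0.01), mk_blob(90, c(0.06, 0, 0), 0.01),
    do.call(rbind, lapply(1:5, function(i) mk_blob(85, c(i + 2, 0, 0),
                                                   0.01))))
  cl <- cluster_blossoms(coords, eps = 0.04, min_pts = 20)
  cl <- classify_clusters(cl, coords, seed = 2)
  model <- attr(cl, "model")
  cls <- vapply(cl, `[[`, "", "cls")
  expect_equal(sum(cls == "multi"), 1)
  multi <- cl[[which(cls == "multi")]]
  pieces <- split_multiflower(multi, coords, eps = 0.04, model = model)
  expect_gte(length(pieces), 2)
  all_idx <- unlist(lapply(pieces, `[[`, "point_idx"))
  expect_equal(anyDuplicated(all_idx), 0)
  expect_true(all(all_idx %in% multi$point_idx))
  single <- cl[[which(cls == "single")[1]]]
  expect_error(split_multiflower(single, coords, 0.04, model), "multi")
})

test_that("cluster volumetrics match closed forms", {
  cube_idx <- 1:8
  coords <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  cl <- canopy3d:::new_blossom_cluster(cube_idx, coords)
  cl <- cluster_metrics(cl, coords)
  expect_equal(cl$volume_m3, 1)
  expect_equal(cl$surf_m2, 6)

  set.seed(54)
  v <- matrix(rnorm(1500), ncol = 3)
  v <- 0.02 * v / sqrt(rowSums(v^2))
  blob <- canopy3d:::new_blossom_cluster(1:500, v)
  blob <- cluster_metrics(blob, v)
  expect_equal(blob$volume_m3, 4 / 3 * pi * 0.02^3, tolerance = 0.15)
  expect_equal(blob$centroid, c(0, 0, 0), tolerance = 2e-3,
               ignore_attr = TRUE)
  expect_gt(blob$voxel_volume_m3, 0)
})

test_that("clusters are assigned to the nearest branch with a lower-index tie rule", {
  nodes <- rbind(cbind(0, 0, seq(0, 1, by = 0.1)),
                 cbind(seq(0.1, 0.5, by = 0.1), 0, 1),
                 cbind(-seq(0.1, 0.5, by = 0.1), 0, 1))
  bs <- structure(list(trunk_path = 1:11,
                       branches = list(c(11, 12:16), c(11, 17:21)),
                       num_branch = 2L, lengths = c(0.5, 0.5),
                       nodes = nodes), class = "branch_set")
  coords <- rbind(c(0.3, 0.02, 1),      # on branch 1's midpoint
                  c(0, 0.1, 1),         # equidistant to both branches
                  c(5, 5, 5))           # too far from everything
  cls <- lapply(1:3, function(i)
    canopy3d:::new_blossom_cluster(i, coords))
  out <- assign_to_branches(cls, bs, max_assign_dist = 0.5)
  expect_equal(out[[1]]$branch_id, 1L)
  expect_equal(out[[2]]$branch_id, 1L)   # tie -> lower index
  expect_true(is.na(out[[3]]$branch_id))
})

test_that("per-stratum cluster counts sum to the tree-level total", {
  tr <- fixture_tree()
  ch <- blossom_chain(tr)
  zs <- vapply(ch$finals, function(cl) cl$centroid[3], 0)
  strat <- stratify(zs, min(ch$coords[, 3]), max(ch$coords[, 3]) + 1e-9)
  expect_equal(sum(table(strat)), length(ch$finals))
})
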