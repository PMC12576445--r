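# Brute-force oracles, independent of the package's implementations.

# SOR oracle: full pairwise distances, no kd-tree.
oracle_sor_keep <- function(coords, k, std_ratio) {
  d <- as.matrix(stats::dist(coords))
  stat <- apply(d, 1, function(row) mean(sort(row)[2:(k + 1)]))
  unname(which(stat <= mean(stat) + std_ratio * stats::sd(stat)))
}

# DBSCAN oracle: O(n^2) label propagation with explicit semantics.
oracle_dbscan <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 0L) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] != 0L) next
      labels[j] <- cl
      if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
    }
  }
  labels
}

# 3D hull oracle for small point sets IN GENERAL POSITION (no 4 coplanar
# hull points, or facets would be double-counted): a triple is a hull facet
# iff all points lie on one side of its plane; volume by the divergence
# theorem over outward-oriented facets, area by summing triangle areas.
oracle_hull3d <- function(pts) {
  n <- nrow(pts)
  stopifnot(n <= 25)
  cen <- colMeans(pts)
  vol <- 0; area <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c_ <- pts[k, ]
    nrm <- c((b - a)[2] * (c_ - a)[3] - (b - a)[3] * (c_ - a)[2],
             (b - a)[3] * (c_ - a)[1] - (b - a)[1] * (c_ - a)[3],
             (b - a)[1] * (c_ - a)[2] - (b - a)[2] * (c_ - a)[1])
    if (sum(nrm^2) < 1e-24) next
    s <- pts %*% nrm - sum(nrm * a)
    tol <- 1e-9 * sqrt(sum(nrm^2))
    if (all(s <= tol) || all(s >= -tol)) {
      # orient the facet normal outward (away from the centroid), then
      # integrate flux of x/3 through the facet: V = sum (g . N_out) / 6
      if (sum(nrm * (cen - a)) > 0) nrm <- -nrm
      area <- area + sqrt(sum(nrm^2)) / 2
      g <- (a + b + c_) / 3
      vol <- vol + sum(g * nrm) / 6
    }
  }
  list(volume = abs(vol), area = area)
}

# rotation matrix about an arbitrary axis (Rodrigues)
rot_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

rotation_err_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

# uniform cylinder-surface sample (axis vertical through (cx, cy))
make_cylinder <- function(n, radius, height, cx = 0, cy = 0, z0 = 0,
                          sigma = 0) {
  th <- stats::runif(n, 0, 2 * pi)
  z <- stats::runif(n, z0, z0 + height)
  cbind(cx + radius * cos(th), cy + radius * sin(th), z) +
    matrix(stats::rnorm(3 * n, 0, sigma), n)
}

# cached synthetic fixtures shared across test files
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

fixture_tree <- function() fixture("tree", function()
  generate_tree(synthetic_tree_spec(seed = 7)))

fixture_support_tree <- function() fixture("support_tree", function()
  generate_tree(synthetic_tree_spec(support = "post+wire", seed = 5)))

fixture_tree_skeleton <- function() fixture("tree_skeleton", function()
  extract_skeleton(fixture_tree()$lidar_view))

# the full support-pruning chain used by the refinement tests and the
# acceptance suite: graph prune -> intensity prune -> screened gap fill
prune_chain <- function(tr, alpha = 1) {
  pc <- tr$lidar_view
  sk <- extract_skeleton(pc)
  r <- estimate_trunk_radius(pc)
  tg <- build_tree_graph(sk, 2 * r)
  pr <- graph_prune_supports(tg)
  removed <- sk$nodes[-attr(pr, "kept_idx"), , drop = FALSE]
  pr2 <- intensity_prune_supports(pr, pc, r = r, alpha = alpha)
  rm2 <- attr(pr2, "removed_nodes")
  if (!is.null(rm2)) removed <- rbind(removed, rm2)
  mask <- voxel_support_mask(pc, 0.02, removed, r = r)
  fg <- fill_gaps(pr2, pc, voxel = 0.02, removed_mask = mask)
  tg2 <- build_tree_graph(fg, 2 * r)
  final <- graph_prune_supports(tg2)
  list(skeleton = sk, final = final, removed = removed, r = r,
       added = attr(fg, "added_nodes"))
}

# branch-count chain mirroring the pipeline
branch_count_chain <- function(tr, denoise = FALSE) {
  pc <- tr$lidar_view
  if (denoise) pc <- sor_denoise(pc, 16, 2.5)
  sk <- extract_skeleton(pc)
  r <- estimate_trunk_radius(pc)
  pr <- graph_prune_supports(build_tree_graph(sk, 2 * r))
  removed <- sk$nodes[-attr(pr, "kept_idx"), , drop = FALSE]
  mask <- voxel_support_mask(pc, 0.02, removed, r = r)
  fg <- fill_gaps(pr, pc, voxel = 0.02, removed_mask = mask)
  pr2 <- graph_prune_supports(build_tree_graph(fg, 2 * r))
  count_branches(smooth_interpolate(pr2))$num_branch
}

# node labels by nearest original point
node_labels <- function(nodes, pc, labels) {
  labels[RANN::nn2(pc$coords, nodes, k = 1)$nn.idx[, 1]]
}

# blossom extraction chain on one generated tree (registration included)
blossom_chain <- function(tr, seed = 42) {
  pc <- tr$drone_view
  lsk <- extract_skeleton(tr$lidar_view)
  cand0 <- blossom_mask(pc)
  structure_pc <- pc_subset(pc, setdiff(seq_len(npoints(pc)), cand0))
  dsk <- extract_skeleton(structure_pc)
  Tf <- fine_register(dsk, lsk, init = coarse_register(dsk, lsk, seed = seed))
  fused <- apply_transform(pc, Tf)
  r <- estimate_trunk_radius(tr$lidar_view)
  cand <- remove_near_skeleton(fused, blossom_mask(fused), lsk, r = r)
  coords <- fused$coords[cand, , drop = FALSE]
  cl <- cluster_blossoms(coords, eps = r, min_pts = 20)
  cl <- classify_clusters(cl, coords, seed = seed)
  model <- attr(cl, "model")
  finals <- list()
  for (c_ in cl) {
    if (identical(c_$cls, "multi"))
      finals <- c(finals, split_multiflower(c_, coords, r, model))
    else finals <- c(finals, list(c_))
  }
  finals <- Filter(function(x) !identical(x$cls, "noise"), finals)
  list(finals = finals, coords = coords, clusters = cl, r = r,
       lidar_skeleton = lsk, cand = cand, fused = fused)
}
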