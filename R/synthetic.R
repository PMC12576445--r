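#' Specification for one synthetic tree
#'
#' The generator emulates an orchard fruit tree as sampled by two mapping
#' methods: a dense "lidar" view carrying normalised intensity (bud burst:
#' wood and supports only) and a sparser "drone" view carrying RGB colour
#' (bloom: wood, supports and near-white blossom blobs), related by a
#' random rigid transform recorded in the ground truth.
#'
#' @param height total tree height in metres (default 2.5).
#' @param trunk_radius trunk radius in metres (default 0.04).
#' @param trunk_top height of the clean trunk below the first branch
#'   junction (default 0.8).
#' @param n_branches number of first-order branches (default 8).
#' @param branch_lengths branch lengths in metres (recycled; default
#'   0.5--0.9 spread).
#' @param support `"none"`, `"post"` or `"post+wire"`.
#' @param support_intensity_offset mean intensity of support material
#'   relative to wood (default 0.6: wood 0.3, support 0.9).
#' @param n_blossom_clusters number of true single flowers (default 12).
#' @param cluster_sizes points per flower (recycled; default 80--120).
#' @param touching_pairs how many flower pairs are planted touching
#'   (centres 5 cm apart), exercising the multi-flower split path.
#' @param noise_outlier_frac fraction of extra uniform outlier points
#'   (default 0).
#' @param n_points structure points in the lidar view (default 6000).
#' @param drone_density drone-view structure density relative to the lidar
#'   view (default 0.4).
#' @param seed RNG seed (default 1).
#' @return a `synthetic_tree_spec` list.
#' @export
synthetic_tree_spec <- function(height = 2.5, trunk_radius = 0.04,
                                trunk_top = 0.8, n_branches = 8,
                                branch_lengths = NULL,
                                support = c("none", "post", "post+wire"),
                                support_intensity_offset = 0.6,
                                n_blossom_clusters = 12,
                                cluster_sizes = NULL,
                                touching_pairs = 0,
                                noise_outlier_frac = 0,
                                n_points = 6000, drone_density = 0.4,
                                seed = 1) {
  support <- match.arg(support)
  stopifnot(height > trunk_top, trunk_radius > 0, n_branches >= 0,
            touching_pairs * 2 <= n_blossom_clusters)
  if (is.null(branch_lengths))
    branch_lengths <- seq(0.5, 0.9, length.out = max(1, n_branches))
  branch_lengths <- rep_len(branch_lengths, max(1, n_branches))
  if (is.null(cluster_sizes) && n_blossom_clusters > 0)
    cluster_sizes <- round(seq(80, 120, length.out = n_blossom_clusters))
  structure(list(height = height, trunk_radius = trunk_radius,
                 trunk_top = trunk_top, n_branches = n_branches,
                 branch_lengths = branch_lengths, support = support,
                 support_intensity_offset = support_intensity_offset,
                 n_blossom_clusters = n_blossom_clusters,
                 cluster_sizes = cluster_sizes,
                 touching_pairs = touching_pairs,
                 noise_outlier_frac = noise_outlier_frac,
                 n_points = n_points, drone_density = drone_density,
                 seed = seed),
            class = "synthetic_tree_spec")
}

# sample points on a cylinder surface between two 3D endpoints
sample_tube <- function(n, p0, p1, radius, sigma = 0.005) {
  axis <- p1 - p0
  L <- sqrt(sum(axis^2))
  a <- axis / L
  # orthonormal frame around the axis
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * a) * a
  u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  t <- stats::runif(n, 0, L)
  th <- stats::runif(n, 0, 2 * pi)
  pts <- matrix(p0, n, 3, byrow = TRUE) + outer(t, a) +
    radius * (outer(cos(th), u) + outer(sin(th), v))
  pts + matrix(stats::rnorm(3 * n, 0, sigma), n, 3)
}

#' Generate one synthetic tree with ground truth
#'
#' The tree is a vertical trunk continuing into a central leader, with
#' `n_branches` lateral branch tubes attached at distinct heights (golden-
#' angle azimuths, ~40 degree elevation). Optional support structures are
#' a vertical post offset from the trunk and a horizontal wire through the
#' crown at the post top, with distinctly higher intensity. Blossom blobs
#' (3D Gaussians, near-white RGB) sit on the branches in the drone view.
#'
#' @param spec a [synthetic_tree_spec()].
#' @return list with `lidar_view` and `drone_view` ([point_cloud()]s; the
#'   drone view is expressed in its own frame, displaced by a random rigid
#'   transform), and `truth`: per-point labels for both views, true traits
#'   (`height`, `n_branches`, `n_flowers`, `cluster_centroids`,
#'   `trunk_top`, `trunk_radius`), branch polylines, and `view_transform`
#'   (the `rigid_transform` mapping drone-frame points back onto the lidar
#'   frame).
#' @export
generate_tree <- function(spec) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)

  h <- spec$height; tt <- spec$trunk_top; r <- spec$trunk_radius
  # point budget: trunk+leader ~30%, branches ~55%, support ~15%
  n <- spec$n_points
  n_sup <- if (spec$support == "none") 0 else round(0.15 * n)
  n_wood <- n - n_sup
  n_trunk <- round(0.30 * n_wood)
  n_branch_total <- n_wood - n_trunk

  parts <- list(); labels <- character(0)
  # trunk + leader: sampled from 0.02 m (ground vegetation hides the collar)
  leader_top <- c(0, 0, h)
  trunk_pts <- sample_tube(n_trunk, c(0, 0, 0.02), leader_top,
                           radius = r * 0.8)
  # taper: shrink radial offset above the trunk top
  zfrac <- pmax(0, trunk_pts[, 3] - tt) / (h - tt)
  trunk_pts[, 1:2] <- trunk_pts[, 1:2] * (1 - 0.6 * zfrac)
  parts$trunk <- trunk_pts
  labels <- c(labels, rep("trunk", n_trunk))

  # branches: junctions spread along the leader above the trunk top
  branch_poly <- list()
  if (spec$n_branches > 0) {
    # junctions kept low enough that the leader stays the apex
    jz <- seq(tt, tt + (h - tt) * 0.55, length.out = spec$n_branches)
    az <- (seq_len(spec$n_branches) - 1) * 2.399963  # golden angle
    elev <- 35 * pi / 180
    nb <- diff(round(seq(0, n_branch_total, length.out = spec$n_branches + 1)))
    bpts <- list()
    for (b in seq_len(spec$n_branches)) {
      L <- spec$branch_lengths[b]
      p0 <- c(0, 0, jz[b])
      dirv <- c(cos(az[b]) * cos(elev), sin(az[b]) * cos(elev), sin(elev))
      p1 <- p0 + L * dirv
      bpts[[b]] <- sample_tube(nb[b], p0, p1, radius = 0.012)
      branch_poly[[b]] <- rbind(p0, p1)
    }
    parts$branch <- do.call(rbind, bpts)
    labels <- c(labels, rep("branch", sum(nb)))
  }

  # supports: post offset from the trunk; wire through the crown
  if (n_sup > 0) {
    post_xy <- c(0.45, 0)
    wire_z <- min(h - 0.3, tt + 0.75 * (h - tt))
    if (spec$support == "post+wire") {
      n_post <- round(0.6 * n_sup); n_wire <- n_sup - n_post
      sup <- rbind(
        sample_tube(n_post, c(post_xy, 0), c(post_xy, wire_z + 0.1), 0.03),
        sample_tube(n_wire, c(post_xy[1], -1.0, wire_z),
                    c(post_xy[1], 1.0, wire_z), 0.004))
    } else {
      sup <- sample_tube(n_sup, c(post_xy, 0), c(post_xy, wire_z + 0.1),
                         0.03)
    }
    parts$support <- sup
    labels <- c(labels, rep("support", n_sup))
  }

  coords <- do.call(rbind, parts)

  # outliers in an inflated bounding box
  n_out <- round(spec$noise_outlier_frac * nrow(coords))
  if (n_out > 0) {
    bb <- apply(coords, 2, range)
    pad <- 0.5
    out <- cbind(stats::runif(n_out, bb[1, 1] - pad, bb[2, 1] + pad),
                 stats::runif(n_out, bb[1, 2] - pad, bb[2, 2] + pad),
                 stats::runif(n_out, bb[1, 3], bb[2, 3] + pad))
    coords <- rbind(coords, out)
    labels <- c(labels, rep("outlier", n_out))
  }

  # lidar intensity: wood ~ N(0.3, 0.05), support shifted up, clipped [0,1]
  base_i <- 0.3
  intensity <- stats::rnorm(nrow(coords), base_i, 0.05)
  intensity[labels == "support"] <-
    stats::rnorm(sum(labels == "support"),
                 base_i + spec$support_intensity_offset, 0.05)
  intensity <- pmin(1, pmax(0, intensity))
  lidar <- point_cloud(coords, intensity = intensity, source = "lidar")

  # drone view: thinned structure + blossom blobs, coloured, own frame
  keep <- which(stats::runif(nrow(coords)) < spec$drone_density)
  dcoords <- coords[keep, , drop = FALSE] +
    matrix(stats::rnorm(3 * length(keep), 0, 0.004), length(keep))
  dlabels <- labels[keep]

  cl_centroids <- NULL
  if (spec$n_blossom_clusters > 0) {
    flower_sigma <- 0.010
    centres <- place_flower_centres(spec, branch_poly)
    blos <- list()
    for (i in seq_len(nrow(centres))) {
      m <- spec$cluster_sizes[i]
      blos[[i]] <- matrix(stats::rnorm(3 * m, 0, flower_sigma), m, 3) +
        matrix(centres[i, ], m, 3, byrow = TRUE)
    }
    blos_pts <- do.call(rbind, blos)
    dcoords <- rbind(dcoords, blos_pts)
    dlabels <- c(dlabels, rep("blossom", nrow(blos_pts)))
    cl_centroids <- centres
  }

  rgb <- matrix(0L, length(dlabels), 3)
  col_of <- list(trunk = c(110, 80, 50), branch = c(60, 120, 50),
                 support = c(120, 120, 120), blossom = c(250, 248, 245),
                 outlier = c(90, 100, 70))
  for (lb in names(col_of)) {
    idx <- which(dlabels == lb)
    if (length(idx) > 0)
      rgb[idx, ] <- matrix(col_of[[lb]], length(idx), 3, byrow = TRUE) +
        matrix(round(stats::rnorm(3 * length(idx), 0, 10)), length(idx))
  }
  rgb[] <- pmin(255L, pmax(0L, rgb))

  # unknown rigid motion between the views (recorded in the truth)
  ang <- stats::runif(1, -25, 25) * pi / 180
  tilt <- stats::runif(2, -3, 3) * pi / 180
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(tilt[1]), sin(tilt[1]),
                 0, -sin(tilt[1]), cos(tilt[1])), 3)
  Rm <- Rz %*% Rx
  tv <- c(stats::runif(2, -0.5, 0.5), stats::runif(1, -0.1, 0.1))
  T_lidar_from_drone <- rigid_transform(Rm, tv)
  drone_frame <- apply_transform(dcoords, invert_transform(T_lidar_from_drone))

  drone <- point_cloud(drone_frame, rgb = rgb, source = "drone")

  truth <- list(
    lidar_labels = labels, drone_labels = dlabels,
    height = h - 0.02, n_branches = spec$n_branches,
    n_flowers = if (is.null(cl_centroids)) 0L else nrow(cl_centroids),
    cluster_centroids = cl_centroids,
    branch_polylines = branch_poly,
    trunk_top = tt, trunk_radius = r,
    view_transform = T_lidar_from_drone)
  list(lidar_view = lidar, drone_view = drone, truth = truth)
}

# flower centres on branch polylines, minimum separation enforced;
# touching pairs are planted 5 cm apart around a shared anchor
place_flower_centres <- function(spec, branch_poly) {
  n_single <- spec$n_blossom_clusters - 2 * spec$touching_pairs
  n_anchor <- n_single + spec$touching_pairs
  anchors <- matrix(0, 0, 3)
  guard <- 0
  while (nrow(anchors) < n_anchor && guard < 2000) {
    guard <- guard + 1
    b <- branch_poly[[sample.int(length(branch_poly), 1)]]
    t <- stats::runif(1, 0.35, 1)
    axis <- (b[2, ] - b[1, ]) / sqrt(sum((b[2, ] - b[1, ])^2))
    # blossoms hang off the branch on pedicels, ~5 cm from the axis
    off <- stats::rnorm(3); off <- off - sum(off * axis) * axis
    off <- off / sqrt(sum(off^2)) * 0.05
    p <- b[1, ] + t * (b[2, ] - b[1, ]) + off +
      stats::rnorm(3, 0, 0.005)
    if (nrow(anchors) == 0 ||
        min(sqrt(rowSums(sweep(anchors, 2, p)^2))) > 0.20)
      anchors <- rbind(anchors, p)
  }
  n_anchor <- nrow(anchors)       # may fall short on tiny trees
  n_pairs <- min(spec$touching_pairs, n_anchor)
  centres <- matrix(0, 0, 3)
  for (i in seq_len(n_anchor)) {
    if (i <= n_pairs) {
      d <- stats::rnorm(3); d <- 0.025 * d / sqrt(sum(d^2))
      centres <- rbind(centres, anchors[i, ] + d, anchors[i, ] - d)
    } else centres <- rbind(centres, anchors[i, ])
  }
  centres
}

#' Generate a synthetic orchard scene with ground truth
#'
#' Trees from [generate_tree()] placed on a planted grid over a sloped
#' ground plane, with designated empty slots (gaps). The scene cloud is
#' the lidar view of every tree plus terrain points, all carrying
#' intensity.
#'
#' @param rows,cols grid dimensions.
#' @param spacing numeric length-2 (tree spacing along x, row spacing
#'   along y) in metres (default `c(4.0, 3.5)` as in a pear planting).
#' @param slope_deg terrain slope along x in degrees (default 0).
#' @param gap_slots integer matrix / data frame of (row, col) slots left
#'   empty, or `NULL`.
#' @param tree_spec_fn function(row, col, seed) returning a
#'   [synthetic_tree_spec()]; the default uses `base_spec` with a
#'   per-slot seed.
#' @param base_spec template [synthetic_tree_spec()] for the default
#'   `tree_spec_fn`.
#' @param ground_density terrain points per square metre (default 150).
#' @param jitter planting jitter (sd, metres; default 0.10 — orchard rows
#'   are never perfectly straight).
#' @param seed scene RNG seed.
#' @return list with `scene` (lidar [point_cloud()] incl. ground),
#'   `scene_labels` (`ground` or `tree<k>:<label>` per point), `trees`
#'   (list with per-slot `row`, `col`, `status`, `origin`, the
#'   [generate_tree()] output for planted slots) and `layout`.
#' @export
generate_orchard <- function(rows, cols, spacing = c(4.0, 3.5),
                             slope_deg = 0, gap_slots = NULL,
                             tree_spec_fn = NULL, base_spec = NULL,
                             ground_density = 150, jitter = 0.10,
                             seed = 1) {
  stopifnot(rows >= 1, cols >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  if (is.null(base_spec)) base_spec <- synthetic_tree_spec()
  if (is.null(tree_spec_fn))
    tree_spec_fn <- function(row, col, seed) {
      s <- base_spec; s$seed <- seed; s
    }
  gap_key <- if (!is.null(gap_slots))
    paste(gap_slots[, 1], gap_slots[, 2]) else character(0)
  slope <- tan(slope_deg * pi / 180)
  terrain_z <- function(x) slope * x

  pad <- 2
  ext_x <- c(-pad, (cols - 1) * spacing[1] + pad)
  ext_y <- c(-pad, (rows - 1) * spacing[2] + pad)
  n_ground <- round(ground_density * diff(ext_x) * diff(ext_y))
  gx <- stats::runif(n_ground, ext_x[1], ext_x[2])
  gy <- stats::runif(n_ground, ext_y[1], ext_y[2])
  gz <- terrain_z(gx) + stats::rnorm(n_ground, 0, 0.005)
  scene_coords <- cbind(gx, gy, gz)
  scene_int <- pmin(1, pmax(0, stats::rnorm(n_ground, 0.5, 0.05)))
  scene_labels <- rep("ground", n_ground)

  trees <- list()
  k <- 0
  for (rr in seq_len(rows)) for (cc in seq_len(cols)) {
    k <- k + 1
    if (paste(rr, cc) %in% gap_key) {
      trees[[k]] <- list(row = rr, col = cc, status = "gap")
      next
    }
    ox <- (cc - 1) * spacing[1] + stats::rnorm(1, 0, jitter)
    oy <- (rr - 1) * spacing[2] + stats::rnorm(1, 0, jitter)
    oz <- terrain_z(ox)
    tr <- generate_tree(tree_spec_fn(rr, cc, seed * 1000 + k))
    world <- tr$lidar_view
    world$coords <- sweep(world$coords, 2, -c(ox, oy, oz))
    scene_coords <- rbind(scene_coords, world$coords)
    scene_int <- c(scene_int, world$intensity)
    scene_labels <- c(scene_labels,
                      paste0("tree", k, ":", tr$truth$lidar_labels))
    trees[[k]] <- list(row = rr, col = cc, status = "present",
                       origin = c(ox, oy, oz), tree = tr)
  }
  scene <- point_cloud(scene_coords, intensity = scene_int,
                       source = "lidar")
  list(scene = scene, scene_labels = scene_labels, trees = trees,
       layout = list(rows = rows, cols = cols, spacing = spacing,
                     slope_deg = slope_deg))
}
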