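#' 3D convex hull of a point set
#'
#' Quickhull-style incremental hull with outward-oriented triangular
#' facets; volume by the divergence theorem over facets, surface area by
#' facet integration.
#'
#' @param coords N x 3 numeric matrix (N >= 4, non-coplanar).
#' @return list with `faces` (F x 3 vertex indices), `vertices` (hull
#'   vertex indices), `volume` and `area`.
#' @export
convex_hull_3d <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  .hull3d_cpp(coords)
}

#' Split a tree into trunk and crown regions
#'
#' Clusters the cloud with DBSCAN, takes the cluster containing the lowest
#' point, restricts it to points within 2 x trunk radius of the trunk
#' axis, and calls its top the trunk top; everything above is the crown.
#'
#' @param tree a `tree_instance` or [point_cloud()].
#' @param r_trunk trunk radius in metres (see [estimate_trunk_radius()]).
#' @param eps DBSCAN radius (default 2 x `voxel`).
#' @param min_pts DBSCAN minimum neighbourhood size (default 10).
#' @param voxel reference voxel size for the default eps (default 0.02).
#' @return list with `trunk_idx`, `crown_idx`, `unassigned_idx` (a
#'   partition of the point indices) and `trunk_top_z` (metres).
#' @export
crown_region <- function(tree, r_trunk, eps = NULL, min_pts = 10,
                         voxel = 0.02) {
  pc <- if (inherits(tree, "tree_instance")) tree$points else tree
  n <- npoints(pc)
  if (n == 0) stop("empty tree")
  if (is.null(eps)) eps <- 2 * voxel
  base_i <- which.min(pc$coords[, 3])
  axis_xy <- trunk_axis_xy(pc)
  rad2 <- (pc$coords[, 1] - axis_xy[1])^2 + (pc$coords[, 2] - axis_xy[2])^2
  in_cyl <- rad2 <= (2 * r_trunk)^2
  # the trunk ends where material first appears outside its cylinder: a
  # central leader would otherwise extend the trunk cluster to the apex
  branch_floor <- if (any(!in_cyl)) min(pc$coords[!in_cyl, 3]) else Inf
  cyl_idx <- which(in_cyl)
  sub <- pc$coords[cyl_idx, , drop = FALSE]
  eps_eff <- max(eps, if (nrow(sub) > 1)
    3 * stats::median(FNN::get.knn(sub, k = 1)$nn.dist) else eps)
  labels <- dbscan_points(sub, eps_eff, min_pts)
  base_cl <- labels[which(cyl_idx == base_i)]
  if (length(base_cl) == 0 || base_cl == 0) {
    warning("no cluster at the tree base; trunk top set to base + 0.3 m")
    trunk_top_z <- min(pc$coords[base_i, 3] + 0.3, branch_floor)
    trunk_idx <- which(in_cyl & pc$coords[, 3] <= trunk_top_z)
  } else {
    trunk_idx <- cyl_idx[labels == base_cl]
    trunk_top_z <- min(max(pc$coords[trunk_idx, 3]), branch_floor)
    trunk_idx <- trunk_idx[pc$coords[trunk_idx, 3] <= trunk_top_z]
  }
  crown_idx <- which(pc$coords[, 3] > trunk_top_z)
  unassigned <- setdiff(seq_len(n), c(trunk_idx, crown_idx))
  list(trunk_idx = trunk_idx, crown_idx = crown_idx,
       unassigned_idx = unassigned, trunk_top_z = trunk_top_z)
}

# x-y centre of the bottom decile (the trunk axis proxy)
trunk_axis_xy <- function(pc) {
  m <- max(1L, ceiling(0.1 * npoints(pc)))
  idx <- order(pc$coords[, 3])[seq_len(m)]
  colMeans(pc$coords[idx, 1:2, drop = FALSE])
}

#' Maximum tree height
#'
#' Difference between the highest and the lowest point of the tree, in
#' centimetres.
#'
#' @param tree a `tree_instance` or [point_cloud()].
#' @return height in cm.
#' @export
height_max <- function(tree) {
  pc <- if (inherits(tree, "tree_instance")) tree$points else tree
  if (npoints(pc) < 2) stop("height_max needs at least 2 points")
  (max(pc$coords[, 3]) - min(pc$coords[, 3])) * 100
}

#' Crown hull morphometrics
#'
#' Volume and surface area from the 3D convex hull of the crown points,
#' projection area from the 2D hull of their x-y projection, and crown
#' diameter as the larger of the east-west (x) and north-south (y)
#' extents. Degenerate geometry turns the affected metric into `NA`
#' while the others are still computed.
#'
#' @param crown a [point_cloud()] (the crown region).
#' @return list with `volume_m3`, `surfarea_m2`, `projarea_m2`,
#'   `diameter_m`.
#' @export
crown_hull_metrics <- function(crown) {
  co <- if (inherits(crown, "point_cloud")) crown$coords else as.matrix(crown)
  n <- nrow(co)
  volume <- surf <- proj <- diam <- NA_real_
  if (n >= 1) {
    ext <- apply(co[, 1:2, drop = FALSE], 2, range)
    diam <- max(ext[2, ] - ext[1, ])
  }
  if (n >= 3) {
    xy <- unique(co[, 1:2, drop = FALSE])
    if (nrow(xy) >= 3) {
      a <- shoelace_area(xy[grDevices::chull(xy), , drop = FALSE])
      if (a > 0) proj <- a
    }
  }
  if (n >= 4) {
    h <- try(convex_hull_3d(co), silent = TRUE)
    if (!inherits(h, "try-error")) { volume <- h$volume; surf <- h$area }
  }
  list(volume_m3 = volume, surfarea_m2 = surf, projarea_m2 = proj,
       diameter_m = diam)
}

#' Compute the full canopy trait record for one tree
#'
#' Convenience wrapper chaining [estimate_trunk_radius()],
#' [crown_region()], [height_max()] and [crown_hull_metrics()].
#'
#' @param tree a `tree_instance` or [point_cloud()].
#' @param r_trunk optional trunk radius (estimated when `NULL`).
#' @param voxel voxel size driving the DBSCAN eps default.
#' @return list of traits: `height_max_cm`, `projarea_m2`, `volume_m3`,
#'   `surfarea_m2`, `diameter_m`, `crown_base_z`, `r_trunk`.
#' @export
canopy_traits <- function(tree, r_trunk = NULL, voxel = 0.02) {
  pc <- if (inherits(tree, "tree_instance")) tree$points else tree
  if (is.null(r_trunk)) r_trunk <- estimate_trunk_radius(pc)
  cr <- crown_region(pc, r_trunk, voxel = voxel)
  crown <- pc_subset(pc, cr$crown_idx)
  m <- if (npoints(crown) >= 3) crown_hull_metrics(crown)
       else list(volume_m3 = NA_real_, surfarea_m2 = NA_real_,
                 projarea_m2 = NA_real_, diameter_m = NA_real_)
  list(height_max_cm = height_max(pc),
       projarea_m2 = m$projarea_m2,
       volume_m3 = m$volume_m3,
       surfarea_m2 = m$surfarea_m2,
       diameter_m = m$diameter_m,
       crown_base_z = cr$trunk_top_z,
       r_trunk = r_trunk)
}
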