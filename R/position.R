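#' Trunk centroid from the bottommost points
#'
#' Projects the lowest `bottom_fraction` of a tree's points (by z) onto the
#' horizontal plane and returns their arithmetic-mean x-y position — the
#' trunk-anchored tree centroid used for grid positioning. Equal weights
#' are used; `weights_fn` exposes a hook for density weighting.
#'
#' @param tree a `tree_instance` (or a [point_cloud()]).
#' @param bottom_fraction fraction of lowest points to use (default 0.10).
#' @param weights_fn optional function(coords) returning per-point weights
#'   for the selected bottom points.
#' @return numeric length-2 (x, y) in metres.
#' @export
trunk_centroid <- function(tree, bottom_fraction = 0.10, weights_fn = NULL) {
  pc <- if (inherits(tree, "tree_instance")) tree$points else tree
  n <- npoints(pc)
  if (n < 10) stop("trunk_centroid needs at least 10 points")
  m <- ceiling(bottom_fraction * n)
  z <- pc$coords[, 3]
  # tie-inclusive: every point at the cutoff height participates, so flat
  # layers are used symmetrically
  zcut <- sort(z)[m]
  idx <- which(z <= zcut + 1e-12)
  xy <- pc$coords[idx, 1:2, drop = FALSE]
  if (is.null(weights_fn)) colMeans(xy)
  else {
    w <- weights_fn(pc$coords[idx, , drop = FALSE])
    colSums(xy * w) / sum(w)
  }
}

#' 2D convex hull of the canopy projection
#'
#' Convex hull of the overhead (x-y) projection of all points of a tree,
#' with its area by the shoelace formula — the canopy projection area.
#'
#' @param tree a `tree_instance` or [point_cloud()].
#' @return list with `polygon` (ordered vertex matrix, closed implicitly)
#'   and `area` in square metres.
#' @export
canopy_hull_xy <- function(tree) {
  pc <- if (inherits(tree, "tree_instance")) tree$points else tree
  xy <- unique(pc$coords[, 1:2, drop = FALSE])
  if (nrow(xy) < 3) stop("need at least 3 distinct projected points")
  h <- grDevices::chull(xy)
  poly <- xy[h, , drop = FALSE]
  area <- shoelace_area(poly)
  if (area <= 0) stop("projected points are collinear")
  list(polygon = poly, area = area)
}

#' Build the unified gridding system from two centroid sets
#'
#' Places the lidar- and drone-derived centroid of each tree in its
#' (row, col) grid cell and records the per-cell offset vector
#' (drone - lidar) for fusion quality control.
#'
#' @param lidar_centroids,drone_centroids data frames with columns
#'   `row`, `col`, `x`, `y`; either may omit trees (those cells get status
#'   `"gap"` for the missing side).
#' @param layout list with `rows`, `cols` and `spacing` (dx, dy metres).
#' @return a `grid_system`: list with `n_rows`, `n_cols`, `cell_size` and a
#'   data frame `cells` (row, col, lidar_x/y, drone_x/y, offset_x/y, geo_x/y,
#'   status).
#' @export
build_grid <- function(lidar_centroids, drone_centroids, layout) {
  cells <- expand.grid(row = seq_len(layout$rows),
                       col = seq_len(layout$cols))
  merge_src <- function(cells, src, prefix) {
    i <- match(paste(cells$row, cells$col), paste(src$row, src$col))
    cells[[paste0(prefix, "_x")]] <- src$x[i]
    cells[[paste0(prefix, "_y")]] <- src$y[i]
    cells
  }
  cells <- merge_src(cells, lidar_centroids, "lidar")
  cells <- merge_src(cells, drone_centroids, "drone")
  cells$offset_x <- cells$drone_x - cells$lidar_x
  cells$offset_y <- cells$drone_y - cells$lidar_y
  cells$geo_x <- NA_real_
  cells$geo_y <- NA_real_
  cells$status <- ifelse(is.na(cells$lidar_x) & is.na(cells$drone_x), "gap",
                         ifelse(is.na(cells$lidar_x) | is.na(cells$drone_x),
                                "partial", "present"))
  structure(list(n_rows = layout$rows, n_cols = layout$cols,
                 cell_size = layout$spacing, cells = cells),
            class = "grid_system")
}

#' @export
print.grid_system <- function(x, ...) {
  cat(sprintf("<grid_system> %d x %d cells (%.1f x %.1f m): %s\n",
              x$n_rows, x$n_cols, x$cell_size[1], x$cell_size[2],
              paste(names(table(x$cells$status)), table(x$cells$status),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Attach precise geo-coordinates to grid cells
#'
#' Cells covered by the reference table receive their surveyed coordinates
#' verbatim. Remaining cells are mapped through a least-squares 2D
#' similarity transform (rotation + uniform scale + translation) fitted from
#' local lidar centroids to the reference frame, which requires at least
#' two referenced cells.
#'
#' @param grid a `grid_system`.
#' @param reference data frame with columns `row`, `col`, `x`, `y` of
#'   surveyed positions.
#' @return the `grid_system` with `geo_x` / `geo_y` filled for present cells.
#' @export
assign_geo <- function(grid, reference) {
  key <- paste(reference$row, reference$col)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflicting <- vapply(unique(dup), function(k) {
      sub <- reference[key == k, ]
      any(stats::dist(cbind(sub$x, sub$y)) > 1e-9)
    }, TRUE)
    if (any(conflicting))
      stop("inconsistent duplicate reference rows for cell(s): ",
           paste(unique(dup)[conflicting], collapse = ", "))
    reference <- reference[!duplicated(key), ]
    key <- paste(reference$row, reference$col)
  }
  cells <- grid$cells
  ckey <- paste(cells$row, cells$col)
  i <- match(ckey, key)
  cells$geo_x <- reference$x[i]
  cells$geo_y <- reference$y[i]
  todo <- which(is.na(cells$geo_x) & !is.na(cells$lidar_x))
  if (length(todo) > 0) {
    ref_cells <- which(!is.na(cells$geo_x) & !is.na(cells$lidar_x))
    if (length(ref_cells) < 2)
      stop("need >= 2 referenced cells with lidar centroids to fit the ",
           "similarity transform")
    fit <- fit_similarity_2d(
      cbind(cells$lidar_x[ref_cells], cells$lidar_y[ref_cells]),
      cbind(cells$geo_x[ref_cells], cells$geo_y[ref_cells]))
    p <- cbind(cells$lidar_x[todo], cells$lidar_y[todo]) %*% t(fit$A)
    cells$geo_x[todo] <- p[, 1] + fit$t[1]
    cells$geo_y[todo] <- p[, 2] + fit$t[2]
  }
  grid$cells <- cells
  grid
}

# Least-squares 2D similarity transform src -> dst: dst ~ s R src + t.
fit_similarity_2d <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  x <- sweep(src, 2, cs); y <- sweep(dst, 2, cd)
  a <- sum(x * y)
  b <- sum(x[, 1] * y[, 2] - x[, 2] * y[, 1])
  denom <- sum(x^2)
  if (denom < 1e-12) stop("degenerate reference configuration")
  s_cos <- a / denom; s_sin <- b / denom
  A <- matrix(c(s_cos, s_sin, -s_sin, s_cos), 2, 2)
  t <- cd - as.vector(A %*% cs)
  list(A = A, t = t)
}
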