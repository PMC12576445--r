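#' Convert a CHM to an 8-bit greyscale image
#'
#' Linear map from \[0, max height\] to \[0, 255\]: the brighter a pixel,
#' the taller the canopy at that cell. No-data cells map to 0. Rounding is
#' half-down so that a half-maximum cell maps to 127.
#'
#' @param chm a `raster_chm`.
#' @return integer matrix (same shape as `chm$heights`) with values 0--255.
#' @export
chm_to_grey <- function(chm) {
  h <- chm$heights
  if (all(is.na(h))) stop("CHM contains no data")
  top <- max(h, na.rm = TRUE)
  g <- if (top > 0) ceiling(h / top * 255 - 0.5) else h * 0
  g[is.na(g)] <- 0
  storage.mode(g) <- "integer"
  g
}

#' Detect tree regions of interest in a greyscale CHM image
#'
#' Binarises the image with a local Otsu threshold (tiled windows with a
#' global-Otsu fallback for rasters smaller than the window), applies a
#' morphological opening with a disc kernel to remove speckle, and returns
#' the connected components as bounding boxes plus masks, sorted row-major
#' by centroid.
#'
#' @param grey integer matrix from [chm_to_grey()].
#' @param open_radius_px disc radius of the morphological open (default 2).
#' @param min_area_px minimum component area in pixels (default 25).
#' @param window_px local-Otsu tile size in pixels (default 65).
#' @param close_radius_px disc radius of a morphological closing applied
#'   before the opening (default 5): leaf-off canopies project as thin
#'   scattered branch returns, and the closing consolidates each crown
#'   into one component without bridging the inter-tree spacing.
#' @return list of components, each a list with `bbox`
#'   (xmin, xmax, ymin, ymax in cell indices), `mask` (logical matrix over
#'   the full raster) and `centroid` (cell-index coordinates). Empty list if
#'   nothing is detected.
#' @export
detect_tree_rois <- function(grey, open_radius_px = 2, min_area_px = 25,
                             window_px = 65, close_radius_px = 5) {
  img <- grey / 255
  bw <- local_otsu_binarise(img, window_px)
  if (close_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * close_radius_px + 1, shape = "disc")
    bw <- EBImage::closing(bw, brush) > 0.5
  }
  if (open_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * open_radius_px + 1, shape = "disc")
    bw <- EBImage::opening(bw, brush) > 0.5
  }
  lab <- EBImage::bwlabel(bw)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  out <- list()
  for (l in seq_len(nlab)) {
    mask <- lab == l
    if (sum(mask) < min_area_px) next
    w <- which(mask, arr.ind = TRUE)
    out[[length(out) + 1]] <- list(
      bbox = c(xmin = min(w[, 1]), xmax = max(w[, 1]),
               ymin = min(w[, 2]), ymax = max(w[, 2])),
      mask = mask,
      centroid = c(mean(w[, 1]), mean(w[, 2])))
  }
  if (length(out) == 0) return(list())
  cen <- t(vapply(out, `[[`, numeric(2), "centroid"))
  out[order(cen[, 2], cen[, 1])]
}

# Tile-wise Otsu binarisation; tiles with negligible contrast inherit the
# global threshold so flat background does not erupt into foreground.
local_otsu_binarise <- function(img, window_px) {
  d <- dim(img)
  glob <- otsu_threshold(as.vector(img))
  thr <- matrix(glob, d[1], d[2])
  if (all(d >= window_px)) {
    xs <- split(seq_len(d[1]), ceiling(seq_len(d[1]) / window_px))
    ys <- split(seq_len(d[2]), ceiling(seq_len(d[2]) / window_px))
    for (ix in xs) for (iy in ys) {
      tile <- img[ix, iy]
      if (stats::sd(tile) > 0.02)
        thr[ix, iy] <- otsu_threshold(as.vector(tile))
    }
  }
  img > thr
}

#' Crop per-tree point clouds using CHM-registered masks
#'
#' Every aboveground point falling inside a detection mask is assigned to
#' exactly one tree; points covered by several masks go to the mask with
#' the nearer centroid (ties to the lower tree id). Points outside all
#' masks are dropped.
#'
#' @param pc aboveground [point_cloud()].
#' @param rois list from [detect_tree_rois()] (masks registered to `chm`).
#' @param chm the `raster_chm` the masks were detected on.
#' @param min_points minimum live-tree point count (default 200); instances
#'   below it get status `"dead"`, empty masks get `"gap"`.
#' @return list of `tree_instance` objects (fields `tree_id`, `points`,
#'   `bbox`, `centroid_xy`, `status`), plus attribute `dropped_idx`.
#' @export
crop_trees <- function(pc, rois, chm, min_points = 200) {
  n <- npoints(pc)
  cs <- chm$cell_size
  dmn <- dim(chm$heights)
  ix <- pmin(dmn[1], pmax(1L, floor((pc$coords[, 1] - chm$origin[1]) / cs) + 1L))
  iy <- pmin(dmn[2], pmax(1L, floor((pc$coords[, 2] - chm$origin[2]) / cs) + 1L))
  lin <- cbind(ix, iy)
  assign <- integer(n)                  # 0 = unassigned
  bestd <- rep(Inf, n)
  for (t in seq_along(rois)) {
    inmask <- rois[[t]]$mask[lin]
    cen_xy <- chm$origin + (rois[[t]]$centroid - 0.5) * cs
    d <- (pc$coords[, 1] - cen_xy[1])^2 + (pc$coords[, 2] - cen_xy[2])^2
    take <- inmask & (d < bestd - 1e-12)   # strict: ties keep lower tree_id
    assign[take] <- t
    bestd[take] <- d[take]
  }
  out <- vector("list", length(rois))
  for (t in seq_along(rois)) {
    idx <- which(assign == t)
    pts <- pc_subset(pc, idx)
    status <- if (length(idx) == 0) "gap"
              else if (length(idx) < min_points) "dead" else "present"
    cen <- if (length(idx) > 0) colMeans(pts$coords[, 1:2, drop = FALSE])
           else chm$origin + (rois[[t]]$centroid - 0.5) * cs
    bbox <- if (length(idx) > 0) as.vector(apply(pts$coords, 2, range))
            else rep(NA_real_, 6)
    out[[t]] <- structure(list(tree_id = t, points = pts,
                               bbox = bbox, centroid_xy = unname(cen),
                               point_idx = idx, status = status),
                          class = "tree_instance")
  }
  attr(out, "dropped_idx") <- which(assign == 0)
  out
}

#' @export
print.tree_instance <- function(x, ...) {
  cat(sprintf("<tree_instance> id=%d status=%s n=%d centroid (%.2f, %.2f)\n",
              x$tree_id, x$status, npoints(x$points),
              x$centroid_xy[1], x$centroid_xy[2]))
  invisible(x)
}

#' Expected tree centroids along a planted row
#'
#' Evenly spaces `n_trees` positions on the segment from `start_xy` to
#' `end_xy`, endpoints included — the linear-interpolation rule used to
#' predict trunk positions in regularly planted rows with gaps.
#'
#' @param start_xy,end_xy numeric length-2 positions of the first and last
#'   tree of the row.
#' @param n_trees number of planting slots (>= 2).
#' @return n_trees x 2 matrix of expected centroids.
#' @export
interpolate_row <- function(start_xy, end_xy, n_trees) {
  if (n_trees < 2) stop("n_trees must be >= 2")
  if (all(abs(end_xy - start_xy) < 1e-12))
    stop("row endpoints are coincident")
  t <- seq(0, 1, length.out = n_trees)
  cbind(start_xy[1] + t * (end_xy[1] - start_xy[1]),
        start_xy[2] + t * (end_xy[2] - start_xy[2]))
}

#' Flag planting slots as present, gap or dead
#'
#' Matches detected tree instances to expected slot centroids. A slot with a
#' detection within `match_radius` is `"present"` (the nearer detection wins
#' if two compete; the loser is reported as an anomaly); an unmatched slot
#' is a `"gap"`; a matched instance whose point count is below `min_points`
#' is `"dead"`.
#'
#' @param expected n x 2 matrix of slot centroids (see [interpolate_row()]).
#' @param trees list of `tree_instance` from [crop_trees()].
#' @param match_radius matching radius in metres.
#' @param min_points live-tree minimum point count (default 200).
#' @return list with `status` (character per slot), `slot_tree` (tree index
#'   per slot, NA for gaps) and `anomalies` (tree indices matched to an
#'   already-taken slot).
#' @export
flag_gaps <- function(expected, trees, match_radius, min_points = 200) {
  stopifnot(match_radius > 0)
  ns <- nrow(expected)
  status <- rep("gap", ns)
  slot_tree <- rep(NA_integer_, ns)
  slot_d <- rep(Inf, ns)
  anomalies <- integer(0)
  for (t in seq_along(trees)) {
    if (trees[[t]]$status == "gap") next
    cen <- trees[[t]]$centroid_xy
    d <- sqrt((expected[, 1] - cen[1])^2 + (expected[, 2] - cen[2])^2)
    s <- which.min(d)
    if (d[s] > match_radius) { anomalies <- c(anomalies, t); next }
    if (d[s] < slot_d[s]) {
      if (!is.na(slot_tree[s])) anomalies <- c(anomalies, slot_tree[s])
      slot_tree[s] <- t
      slot_d[s] <- d[s]
    } else anomalies <- c(anomalies, t)
  }
  ok <- !is.na(slot_tree)
  status[ok] <- ifelse(
    vapply(trees[slot_tree[ok]], function(x) npoints(x$points), 0) <
      min_points, "dead", "present")
  list(status = status, slot_tree = slot_tree, anomalies = anomalies)
}
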