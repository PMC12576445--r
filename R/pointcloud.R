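#' Construct a point cloud
#'
#' The universal carrier for every pipeline stage: an N x 3 coordinate matrix
#' in metres (z up), with optional per-point LiDAR intensity (normalised to
#' \[0, 1\]) and/or 8-bit RGB colour.
#'
#' @param coords numeric N x 3 matrix of x, y, z coordinates in metres.
#' @param intensity optional numeric vector of length N; values are min-max
#'   normalised to \[0, 1\] on construction.
#' @param rgb optional integer N x 3 matrix, channels in 0--255.
#' @param crs optional coordinate-reference identifier (free-form string).
#' @param source one of `"lidar"`, `"drone"`, `"synthetic"`. If `NULL` it is
#'   inferred: colour implies drone, intensity implies lidar, else synthetic.
#'
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(coords, intensity = NULL, rgb = NULL, crs = NULL,
                        source = NULL) {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), ncol = 3)
  if (ncol(coords) != 3) stop("coords must have 3 columns (x, y, z)")
  storage.mode(coords) <- "double"
  if (nrow(coords) > 0 && !all(is.finite(coords)))
    stop("coords must be finite")
  colnames(coords) <- c("x", "y", "z")
  n <- nrow(coords)
  if (!is.null(intensity)) {
    intensity <- as.numeric(intensity)
    if (length(intensity) != n) stop("intensity length must match coords")
    intensity <- normalize01(intensity)
  }
  if (!is.null(rgb)) {
    rgb <- as.matrix(rgb)
    if (nrow(rgb) != n || ncol(rgb) != 3) stop("rgb must be N x 3")
    if (n > 0 && (min(rgb) < 0 || max(rgb) > 255))
      stop("rgb channels must be within [0, 255]")
    storage.mode(rgb) <- "integer"
  }
  if (is.null(source)) {
    source <- if (!is.null(rgb)) "drone" else if (!is.null(intensity)) "lidar"
              else "synthetic"
  }
  source <- match.arg(source, c("lidar", "drone", "synthetic"))
  structure(list(coords = coords, intensity = intensity, rgb = rgb,
                 crs = crs, source = source),
            class = "point_cloud")
}

# min-max to [0,1]; constant vectors map to 0. Idempotent by construction.
normalize01 <- function(x) {
  if (length(x) == 0) return(x)
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else rep(0, length(x))
}

#' Number of points in a cloud
#' @param pc a `point_cloud`.
#' @return integer count.
#' @export
npoints <- function(pc) nrow(pc$coords)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, source=%s%s%s%s\n",
              npoints(x), x$source,
              if (!is.null(x$intensity)) ", intensity" else "",
              if (!is.null(x$rgb)) ", rgb" else "",
              if (!is.null(x$crs)) paste0(", crs=", x$crs) else ""))
  if (npoints(x) > 0) {
    bb <- apply(x$coords, 2, range)
    cat(sprintf("  extent x [%.3f, %.3f] y [%.3f, %.3f] z [%.3f, %.3f] m\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(x)
}

#' Subset a point cloud by point index
#'
#' Keeps intensity/colour channels aligned with the retained coordinates.
#'
#' @param pc a `point_cloud`.
#' @param idx integer or logical index vector over points.
#' @return the subset `point_cloud`.
#' @export
pc_subset <- function(pc, idx) {
  structure(list(
    coords = pc$coords[idx, , drop = FALSE],
    intensity = if (!is.null(pc$intensity)) pc$intensity[idx],
    rgb = if (!is.null(pc$rgb)) pc$rgb[idx, , drop = FALSE],
    crs = pc$crs, source = pc$source), class = "point_cloud")
}

#' Concatenate point clouds
#'
#' Optional channels are kept only if present in every input; `source` is
#' taken from the first cloud unless they disagree, in which case the result
#' is tagged `synthetic` (mixed provenance is tracked by the fusion stage).
#'
#' @param ... `point_cloud` objects.
#' @return a single `point_cloud`.
#' @export
pc_bind <- function(...) {
  pcs <- list(...)
  coords <- do.call(rbind, lapply(pcs, `[[`, "coords"))
  ints <- lapply(pcs, `[[`, "intensity")
  rgbs <- lapply(pcs, `[[`, "rgb")
  src <- unique(vapply(pcs, `[[`, "", "source"))
  point_cloud(coords,
              intensity = if (!any(vapply(ints, is.null, TRUE)))
                unlist(ints),
              rgb = if (!any(vapply(rgbs, is.null, TRUE)))
                do.call(rbind, rgbs),
              crs = pcs[[1]]$crs,
              source = if (length(src) == 1) src else "synthetic")
}
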