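#' Statistical outlier removal
#'
#' Drops points whose mean distance to their `k` nearest neighbours exceeds
#' the global mean of that statistic by more than `std_ratio` standard
#' deviations. The order of the surviving points is preserved.
#'
#' @param pc a [point_cloud()].
#' @param k number of neighbours (default 16).
#' @param std_ratio standard-deviation multiplier (default 1.0).
#' @return the denoised `point_cloud`, with attribute `kept_idx` giving the
#'   indices of surviving points in the input.
#' @export
sor_denoise <- function(pc, k = 16, std_ratio = 1.0) {
  n <- npoints(pc)
  if (n <= k) stop("sor_denoise needs more than k = ", k, " points")
  d <- knn_mean_dist(pc$coords, k)
  keep <- which(d <= mean(d) + std_ratio * stats::sd(d))
  out <- pc_subset(pc, keep)
  attr(out, "kept_idx") <- keep
  out
}

#' Cloth-simulation-style ground filtering
#'
#' Splits a cloud into ground (digital terrain model) and aboveground
#' (digital surface model) points by settling a simulated cloth under the
#' cloud: a grid of cloth particles at `cloth_resolution` relaxes by
#' repeated neighbour averaging while being constrained from above by the
#' per-cell lowest point, converging onto the terrain while staying below
#' vegetation. Points within `class_threshold` of the settled cloth are
#' classified as ground.
#'
#' @param pc a [point_cloud()].
#' @param cloth_resolution cloth grid spacing in metres (default 0.5).
#' @param class_threshold ground classification distance in metres
#'   (default 0.05).
#' @param rigidity number of relaxation sweeps (higher = stiffer cloth).
#' @return list with `point_cloud` elements `ground` and `aboveground`, plus
#'   `ground_idx` / `aboveground_idx` index vectors into the input.
#' @export
csf_ground_filter <- function(pc, cloth_resolution = 0.5,
                              class_threshold = 0.05, rigidity = 150L) {
  xy <- pc$coords[, 1:2, drop = FALSE]
  z <- pc$coords[, 3]
  ext <- apply(xy, 2, range)
  span <- ext[2, ] - ext[1, ]
  if (any(span < 2 * cloth_resolution))
    stop("cloud horizontal extent must be at least 2 x cloth_resolution")
  nx <- max(2L, ceiling(span[1] / cloth_resolution) + 1L)
  ny <- max(2L, ceiling(span[2] / cloth_resolution) + 1L)
  ix <- pmin(nx, pmax(1L, floor((xy[, 1] - ext[1, 1]) / cloth_resolution) + 1L))
  iy <- pmin(ny, pmax(1L, floor((xy[, 2] - ext[1, 2]) / cloth_resolution) + 1L))
  cell <- (iy - 1L) * nx + ix
  # upper constraint: lowest point per cell (the surface the cloth rests on)
  zmin <- rep(Inf, nx * ny)
  zm <- tapply(z, cell, min)
  zmin[as.integer(names(zm))] <- zm
  cloth <- matrix(zmin, nx, ny)
  empty <- which(!is.finite(cloth))
  if (length(empty) > 0) {
    # unconstrained cells (outside the data footprint) start at the value
    # of the nearest constrained cell and then relax harmonically
    grid_ij <- cbind((seq_len(nx * ny) - 1) %% nx,
                     (seq_len(nx * ny) - 1) %/% nx)
    filled <- setdiff(seq_len(nx * ny), empty)
    nn <- RANN::nn2(grid_ij[filled, , drop = FALSE],
                    grid_ij[empty, , drop = FALSE], k = 1)
    cloth[empty] <- cloth[filled[nn$nn.idx[, 1]]]
  }
  constraint <- matrix(zmin, nx, ny)
  # the restoring rise only acts where points constrain the cloth; empty
  # cells are filled harmonically by the tension term alone
  rise <- ifelse(is.finite(constraint), 0.02, 0)
  for (iter in seq_len(rigidity)) {
    # 4-neighbour average with gradient-preserving (linearly extrapolated)
    # borders — replicated borders would flatten sloped terrain and drag
    # the cloth downhill — then re-impose the lowest-point constraint
    up <- rbind(2 * cloth[1, ] - cloth[2, ], cloth[seq_len(nx - 1), ])
    dn <- rbind(cloth[seq_len(nx - 1) + 1, ],
                2 * cloth[nx, ] - cloth[nx - 1, ])
    lf <- cbind(2 * cloth[, 1] - cloth[, 2], cloth[, seq_len(ny - 1)])
    rt <- cbind(cloth[, seq_len(ny - 1) + 1],
                2 * cloth[, ny] - cloth[, ny - 1])
    # tension (averaging) + a restoring rise towards the surface, clamped
    # from above by the lowest points: the cloth settles onto the terrain
    # instead of drifting below it
    cloth <- pmin((up + dn + lf + rt) / 4 + rise, constraint)
  }
  # bilinear cloth height under each point
  gz <- bilinear_grid(cloth, ext[1, 1:2], cloth_resolution, xy)
  is_ground <- abs(z - gz) <= class_threshold
  list(ground = pc_subset(pc, which(is_ground)),
       aboveground = pc_subset(pc, which(!is_ground)),
       ground_idx = which(is_ground),
       aboveground_idx = which(!is_ground))
}

# Bilinear interpolation of a node-registered grid (node (1,1) at `origin`,
# spacing `h`) at arbitrary x-y positions.
bilinear_grid <- function(grid, origin, h, xy) {
  nx <- nrow(grid); ny <- ncol(grid)
  u <- (xy[, 1] - origin[1]) / h
  v <- (xy[, 2] - origin[2]) / h
  i0 <- pmin(nx - 1L, pmax(1L, floor(u) + 1L))
  j0 <- pmin(ny - 1L, pmax(1L, floor(v) + 1L))
  fu <- pmin(1, pmax(0, u - (i0 - 1L)))
  fv <- pmin(1, pmax(0, v - (j0 - 1L)))
  g <- function(i, j) grid[cbind(i, j)]
  (1 - fu) * (1 - fv) * g(i0, j0) + fu * (1 - fv) * g(i0 + 1L, j0) +
    (1 - fu) * fv * g(i0, j0 + 1L) + fu * fv * g(i0 + 1L, j0 + 1L)
}

#' Construct a canopy height model raster
#'
#' Per cell, the CHM is the maximum aboveground height minus the terrain
#' height interpolated from ground points at the cell centre, clamped at
#' zero. Terrain interpolation is linear barycentric over the Delaunay
#' triangulation of the ground points with a nearest-neighbour fallback
#' outside the triangulation hull. Heights are reported in centimetres;
#' empty cells carry `NA`.
#'
#' @param ground ground-classified [point_cloud()].
#' @param aboveground aboveground [point_cloud()].
#' @param cell_size raster cell size in metres (default 0.05).
#' @return a `raster_chm` object: list with `heights` (R x C matrix, cm,
#'   rows indexing x, columns indexing y), `cell_size`, `origin` (x, y of
#'   the lower-left corner of cell (1,1)) and `crs`.
#' @export
build_chm <- function(ground, aboveground, cell_size = 0.05) {
  if (npoints(ground) == 0 || npoints(aboveground) == 0)
    stop("both ground and aboveground clouds must be non-empty")
  gext <- apply(ground$coords[, 1:2, drop = FALSE], 2, range)
  aext <- apply(aboveground$coords[, 1:2, drop = FALSE], 2, range)
  if (any(aext[1, ] > gext[2, ]) || any(aext[2, ] < gext[1, ]))
    stop("ground and aboveground clouds do not overlap in x-y extent")
  origin <- aext[1, ]
  nx <- max(1L, ceiling((aext[2, 1] - origin[1]) / cell_size))
  ny <- max(1L, ceiling((aext[2, 2] - origin[2]) / cell_size))
  ix <- pmin(nx, floor((aboveground$coords[, 1] - origin[1]) / cell_size) + 1L)
  iy <- pmin(ny, floor((aboveground$coords[, 2] - origin[2]) / cell_size) + 1L)
  cell <- (iy - 1L) * nx + ix
  zmax <- rep(NA_real_, nx * ny)
  zm <- tapply(aboveground$coords[, 3], cell, max)
  zmax[as.integer(names(zm))] <- zm
  occ <- which(!is.na(zmax))
  cx <- origin[1] + ((occ - 1L) %% nx + 0.5) * cell_size
  cy <- origin[2] + ((occ - 1L) %/% nx + 0.5) * cell_size
  dtm <- interpolate_dtm(ground$coords, cbind(cx, cy))
  heights <- matrix(NA_real_, nx, ny)
  heights[occ] <- pmax(0, zmax[occ] - dtm) * 100
  structure(list(heights = heights, cell_size = cell_size,
                 origin = unname(origin), crs = ground$crs),
            class = "raster_chm")
}

# Terrain height at query x-y positions: linear barycentric interpolation on
# the ground-point triangulation, nearest ground point outside the hull.
interpolate_dtm <- function(ground_coords, query_xy) {
  gx <- ground_coords[, 1]; gy <- ground_coords[, 2]; gz <- ground_coords[, 3]
  # collapse duplicate x-y locations (triangulation requires unique sites)
  key <- paste(signif(gx, 12), signif(gy, 12))
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    gz <- as.numeric(tapply(gz, factor(key, levels = key[keep]), mean))
    gx <- gx[keep]; gy <- gy[keep]
  }
  z <- rep(NA_real_, nrow(query_xy))
  if (length(gx) >= 3) {
    fit <- try(interp::interpp(gx, gy, gz, xo = query_xy[, 1],
                               yo = query_xy[, 2], linear = TRUE),
               silent = TRUE)
    if (!inherits(fit, "try-error")) z <- fit$z
  }
  miss <- which(is.na(z))
  if (length(miss) > 0) {
    nn <- RANN::nn2(cbind(gx, gy), query_xy[miss, , drop = FALSE], k = 1)
    z[miss] <- gz[nn$nn.idx[, 1]]
  }
  z
}

#' @export
print.raster_chm <- function(x, ...) {
  cat(sprintf("<raster_chm> %d x %d cells @ %.3f m, origin (%.2f, %.2f)\n",
              nrow(x$heights), ncol(x$heights), x$cell_size,
              x$origin[1], x$origin[2]))
  cat(sprintf("  height range [%.1f, %.1f] cm, %d empty cells\n",
              suppressWarnings(min(x$heights, na.rm = TRUE)),
              suppressWarnings(max(x$heights, na.rm = TRUE)),
              sum(is.na(x$heights))))
  invisible(x)
}

#' Export a CHM as an ESRI ASCII grid
#'
#' Plain-text raster interchange format readable by standard GIS tools.
#' Heights are written in centimetres; empty cells carry the no-data value.
#'
#' @param chm a `raster_chm`.
#' @param path destination `.asc` path.
#' @param nodata no-data sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_chm_asc <- function(chm, path, nodata = -9999) {
  h <- chm$heights
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", nrow(h)),
               paste("nrows", ncol(h)),
               paste("xllcorner", chm$origin[1]),
               paste("yllcorner", chm$origin[2]),
               paste("cellsize", chm$cell_size),
               paste("NODATA_value", nodata)), con)
  m <- t(h)[ncol(h):1, , drop = FALSE]   # rows top-down per the format
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
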