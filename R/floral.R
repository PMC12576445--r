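#' Candidate blossom points by greyscale thresholding
#'
#' Converts RGB to luma greyscale (0.299 R + 0.587 G + 0.114 B) and keeps
#' points at or above an adaptive global (Otsu) threshold chosen per tree —
#' blossom is much brighter than foliage or bark. If all colours are
#' identical the threshold degenerates and every point is retained.
#'
#' @param pc a [point_cloud()] with colour.
#' @return integer vector of candidate point indices.
#' @export
blossom_mask <- function(pc) {
  if (is.null(pc$rgb)) stop("blossom_mask needs a cloud with rgb")
  g <- 0.299 * pc$rgb[, 1] + 0.587 * pc$rgb[, 2] + 0.114 * pc$rgb[, 3]
  if (max(g) - min(g) < 1e-9) return(seq_len(npoints(pc)))
  thr <- otsu_threshold(g)
  which(g >= thr)
}

#' Remove candidates adjacent to the tree skeleton
#'
#' Bright points on branch or trunk surfaces (sun-lit bark) survive colour
#' thresholding; they are removed here by an R-NN screen against the
#' bud-burst skeleton, with the scanning radius set to the trunk radius.
#'
#' @param pc the candidate cloud's [point_cloud()].
#' @param candidates integer indices from [blossom_mask()].
#' @param skel a `skeleton` registered into the same frame.
#' @param r scanning radius in metres (the trunk radius by convention).
#' @return the surviving candidate indices.
#' @export
remove_near_skeleton <- function(pc, candidates, skel, r) {
  if (is.null(skel) || nrow(skel$nodes) == 0) {
    warning("empty skeleton; no candidates removed")
    return(candidates)
  }
  d <- RANN::nn2(skel$nodes, pc$coords[candidates, , drop = FALSE],
                 k = 1)$nn.dists[, 1]
  candidates[d > r]
}

#' Stratify points into crown thirds
#'
#' Splits the crown z-span into three equal bands — lower, middle, upper.
#' A point exactly on a band boundary goes to the band below it (bands are
#' closed above), so the crown base itself is `lower`.
#'
#' @param z numeric z coordinates (metres).
#' @param crown_base_z,apex_z crown span (apex_z > crown_base_z).
#' @return character vector of `"lower"`, `"middle"`, `"upper"`.
#' @export
stratify <- function(z, crown_base_z, apex_z) {
  stopifnot(apex_z > crown_base_z)
  h <- (apex_z - crown_base_z) / 3
  b1 <- crown_base_z + h
  b2 <- crown_base_z + 2 * h
  ifelse(z <= b1, "lower", ifelse(z <= b2, "middle", "upper"))
}

#' Cluster blossom points with DBSCAN
#'
#' Standard DBSCAN semantics with the neighbouring radius set to the trunk
#' radius and a specialist-derived minimum of 20 points per cluster;
#' DBSCAN noise points are discarded.
#'
#' @param coords N x 3 matrix of blossom point coordinates.
#' @param eps DBSCAN radius in metres (trunk radius by convention).
#' @param min_pts minimum cluster occupancy (default 20).
#' @return list of `blossom_cluster` objects (fields `point_idx`, `n`,
#'   `centroid`, `cls`, `stratum`, `branch_id`).
#' @export
cluster_blossoms <- function(coords, eps, min_pts = 20) {
  coords <- as.matrix(coords)
  if (nrow(coords) < min_pts) return(list())
  labels <- dbscan_points(coords, eps, min_pts)
  out <- list()
  for (l in setdiff(sort(unique(labels)), 0L)) {
    idx <- which(labels == l)
    out[[length(out) + 1]] <- new_blossom_cluster(idx, coords)
  }
  out
}

new_blossom_cluster <- function(idx, coords) {
  structure(list(point_idx = idx, n = length(idx),
                 centroid = colMeans(coords[idx, , drop = FALSE]),
                 cls = NA_character_, stratum = NA_character_,
                 branch_id = NA_integer_,
                 volume_m3 = NA_real_, surf_m2 = NA_real_,
                 projarea_m2 = NA_real_, voxel_volume_m3 = NA_real_,
                 geo = NULL),
            class = "blossom_cluster")
}

#' @export
print.blossom_cluster <- function(x, ...) {
  cat(sprintf("<blossom_cluster> n=%d cls=%s stratum=%s centroid (%.2f, %.2f, %.2f)\n",
              x$n, x$cls, x$stratum, x$centroid[1], x$centroid[2],
              x$centroid[3]))
  invisible(x)
}

# feature vector for the cluster classifier: count, hull volume, max PCA extent
cluster_features <- function(cluster, coords) {
  xyz <- coords[cluster$point_idx, , drop = FALSE]
  vol <- 0
  if (nrow(xyz) >= 4) {
    h <- try(convex_hull_3d(xyz), silent = TRUE)
    if (!inherits(h, "try-error")) vol <- h$volume
  }
  ext <- sqrt(max(stats::prcomp(xyz, center = TRUE)$sdev^2)) * 4
  c(n = cluster$n, volume = vol, extent = ext)
}

#' Classify blossom clusters into noise, single and multi flower
#'
#' Clusters with fewer than 50 points are forced to `noise` (a hard
#' specialist rule). The rest are split by K-means (k = 2, 10 restarts,
#' fixed seed) over z-scored size features — point count, hull volume and
#' maximum PCA extent — and the group with the smaller mean feature value
#' is labelled `single`, the other `multi`. Together with the rule-based
#' noise class this realises the three-group scheme.
#'
#' @param clusters list of `blossom_cluster`.
#' @param coords the blossom coordinate matrix the clusters index into.
#' @param noise_n noise threshold on cluster size (default 50).
#' @param seed K-means seed (default 42).
#' @return the clusters with `cls` set; attribute `model` carries the
#'   fitted feature scaler and centres for re-classifying split clusters.
#' @export
classify_clusters <- function(clusters, coords, noise_n = 50, seed = 42) {
  if (length(clusters) == 0) return(clusters)
  feats <- t(vapply(clusters, cluster_features, numeric(3), coords))
  small <- vapply(clusters, `[[`, 0, "n") < noise_n
  for (i in which(small)) clusters[[i]]$cls <- "noise"
  big <- which(!small)
  model <- NULL
  if (length(big) == 0) {
    warning("all clusters fall below the noise threshold")
  } else if (length(big) == 1) {
    clusters[[big]]$cls <- "single"
  } else {
    f <- feats[big, , drop = FALSE]
    mu <- colMeans(f)
    sdv <- pmax(apply(f, 2, stats::sd), 1e-9)
    z <- sweep(sweep(f, 2, mu), 2, sdv, "/")
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    km <- stats::kmeans(z, centers = min(2, nrow(unique(z))), nstart = 10)
    mean_n <- tapply(f[, 1], km$cluster, mean)
    if (length(km$size) == 1 ||
        max(mean_n) / max(min(mean_n), 1) < 1.5) {
      # the two candidate groups are not meaningfully different in size:
      # the population is homogeneous, nothing to call multi-flower
      for (i in big) clusters[[i]]$cls <- "single"
    } else {
      single_grp <- which.min(rowMeans(km$centers))
      lab <- ifelse(km$cluster == single_grp, "single", "multi")
      for (j in seq_along(big)) clusters[[big[j]]]$cls <- lab[j]
      model <- list(mu = mu, sd = sdv, centers = km$centers,
                    single_grp = single_grp, noise_n = noise_n)
    }
  }
  attr(clusters, "model") <- model
  clusters
}

# classify one cluster against a fitted model (NULL model: by size only)
predict_cluster_class <- function(cluster, coords, model, noise_n = 50) {
  if (cluster$n < noise_n) return("noise")
  if (is.null(model)) return("single")
  z <- (cluster_features(cluster, coords) - model$mu) / model$sd
  d <- rowSums(sweep(model$centers, 2, z)^2)
  if (which.min(d) == model$single_grp) "single" else "multi"
}

#' Iteratively split a multi-flower cluster into single flowers
#'
#' Re-clusters the member points with DBSCAN at half the radius per level
#' and re-classifies the pieces against the fitted cluster model, until
#' every leaf is single or noise or `max_depth` is reached (remaining
#' multi leaves are then forced single and flagged).
#'
#' @param cluster a `blossom_cluster` with `cls == "multi"`.
#' @param coords the blossom coordinate matrix.
#' @param eps the DBSCAN radius the cluster was found at.
#' @param model classifier model from [classify_clusters()].
#' @param min_pts DBSCAN minimum (default 20).
#' @param max_depth recursion cap (default 4).
#' @return list of `blossom_cluster` leaves (`cls` single or noise;
#'   forced-single leaves carry `depth_exhausted = TRUE`).
#' @export
split_multiflower <- function(cluster, coords, eps, model, min_pts = 20,
                              max_depth = 4) {
  if (!identical(cluster$cls, "multi"))
    stop("split_multiflower expects a multi-flower cluster")
  split_rec <- function(cl, eps, depth) {
    if (depth > max_depth) {
      cl$cls <- "single"
      cl$depth_exhausted <- TRUE
      return(list(cl))
    }
    sub <- coords[cl$point_idx, , drop = FALSE]
    labels <- dbscan_points(sub, eps / 2, min_pts)
    ids <- setdiff(sort(unique(labels)), 0L)
    if (length(ids) == 0) {           # dissolved entirely into noise
      cl$cls <- "single"
      cl$depth_exhausted <- TRUE
      return(list(cl))
    }
    out <- list()
    for (l in ids) {
      piece <- new_blossom_cluster(cl$point_idx[labels == l], coords)
      piece$cls <- predict_cluster_class(piece, coords, model,
                                         model$noise_n %||% 50)
      if (piece$cls == "multi")
        out <- c(out, split_rec(piece, eps / 2, depth + 1))
      else out <- c(out, list(piece))
    }
    if (length(out) == 0) {           # everything dissolved into noise
      cl$cls <- "single"
      cl$depth_exhausted <- TRUE
      out <- list(cl)
    }
    out
  }
  split_rec(cluster, eps, 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Blossom cluster volumetrics
#'
#' Hull-based volume, surface and projection area of one cluster, its
#' centroid, and an auxiliary voxel-occupancy volume
#' (occupied voxels x voxel^3). Degenerate clusters report `NA` metrics
#' but keep count and centroid.
#'
#' @param cluster a `blossom_cluster`.
#' @param coords the blossom coordinate matrix.
#' @param voxel voxel size for the occupancy volume (default 0.01).
#' @param geo_fn optional function(centroid) mapping to geo-coordinates.
#' @return the cluster with `volume_m3`, `surf_m2`, `projarea_m2`,
#'   `voxel_volume_m3` and `geo` filled.
#' @export
cluster_metrics <- function(cluster, coords, voxel = 0.01, geo_fn = NULL) {
  xyz <- coords[cluster$point_idx, , drop = FALSE]
  m <- crown_hull_metrics(xyz)
  cluster$volume_m3 <- m$volume_m3
  cluster$surf_m2 <- m$surfarea_m2
  cluster$projarea_m2 <- m$projarea_m2
  cluster$voxel_volume_m3 <-
    nrow(voxel_downsample(xyz, voxel)$centroids) * voxel^3
  cluster$centroid <- colMeans(xyz)
  if (!is.null(geo_fn)) cluster$geo <- geo_fn(cluster$centroid)
  cluster
}

#' Assign blossom clusters to branches
#'
#' Each cluster goes to the branch whose polyline is nearest to the cluster
#' centroid (ties to the lower branch index). Centroids farther than
#' `max_assign_dist` from every branch stay unassigned and count only at
#' tree level.
#'
#' @param clusters list of `blossom_cluster`.
#' @param branchset a `branch_set` from [count_branches()].
#' @param max_assign_dist assignment cap in metres (default 0.5).
#' @return the clusters with `branch_id` set (NA when unassigned).
#' @export
assign_to_branches <- function(clusters, branchset, max_assign_dist = 0.5) {
  if (branchset$num_branch == 0) stop("branch set is empty")
  polylines <- lapply(branchset$branches, function(b)
    branchset$nodes[b, , drop = FALSE])
  for (i in seq_along(clusters)) {
    d <- vapply(polylines, point_polyline_dist,
                0, p = clusters[[i]]$centroid)
    j <- which.min(d)      # which.min takes the first (lowest index) on ties
    clusters[[i]]$branch_id <- if (d[j] <= max_assign_dist) j else NA_integer_
  }
  clusters
}

# minimum distance from point p to a polyline given as an ordered vertex matrix
point_polyline_dist <- function(poly, p) {
  if (nrow(poly) == 1)
    return(sqrt(sum((poly[1, ] - p)^2)))
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  ap <- -sweep(a, 2, p)
  t <- rowSums(ap * ab) / pmax(rowSums(ab^2), 1e-12)
  t <- pmin(1, pmax(0, t))
  proj <- a + ab * t
  sqrt(min(rowSums(sweep(proj, 2, p)^2)))
}
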