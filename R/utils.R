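# Internal geometry / clustering helpers shared across stages.

# Indices of neighbours within `radius` for each query row (kd-tree backed).
# Returns a list of integer vectors; self matches are kept.
radius_search <- function(data, query, radius, max_k = 64L) {
  n <- nrow(data)
  k <- min(max_k, n)
  repeat {
    res <- RANN::nn2(data, query, k = k, searchtype = "radius",
                     radius = radius)
    # if any query saturated k within the radius, widen k and retry
    saturated <- k < n && any(res$nn.idx[, k] > 0)
    if (!saturated) break
    k <- min(n, k * 2L)
  }
  lapply(seq_len(nrow(query)), function(i) {
    idx <- res$nn.idx[i, ]
    idx[idx > 0]
  })
}

# Mean distance of each point to its k nearest neighbours (self excluded).
knn_mean_dist <- function(coords, k) {
  nn <- FNN::get.knn(coords, k = k)
  rowMeans(nn$nn.dist)
}

# Density-based clustering (DBSCAN semantics: core points have >= min_pts
# neighbours within eps, self included; border points join a core cluster;
# the rest are noise, label 0). No suitable implementation is installed, so
# this is a direct kd-tree-backed implementation.
dbscan_points <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  nb <- radius_search(coords, coords, eps)
  core <- lengths(nb) >= min_pts
  labels <- integer(n)   # 0 = noise/unvisited
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue) > 0) {
      j <- queue[[1]]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

# Voxel-grid downsampling: returns centroids of occupied voxels plus the
# voxel key of every input point (for provenance screens).
voxel_downsample <- function(coords, voxel) {
  stopifnot(voxel > 0)
  key <- floor(sweep(coords, 2, apply(coords, 2, min)) / voxel)
  id <- paste(key[, 1], key[, 2], key[, 3])
  fid <- factor(id, levels = unique(id))
  cent <- apply(coords, 2, function(v) tapply(v, fid, mean))
  if (is.null(dim(cent))) cent <- matrix(cent, nrow = 1)
  list(centroids = unname(cent), keys = levels(fid), point_key = id)
}

# Otsu's threshold on a numeric vector (maximises between-class variance
# over a fixed-bin histogram). Returns the threshold value.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-length(br)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# 2D polygon area by the shoelace formula (vertices in order).
shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}
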