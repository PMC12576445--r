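#' Construct a rigid transform
#'
#' @param R 3 x 3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation in metres.
#' @return a `rigid_transform` with fields `matrix` (4 x 4 homogeneous),
#'   and attributes carried by registration (`rmse`).
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    stop("R must be a proper rotation (orthonormal, det +1)")
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t
  structure(list(matrix = m), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$matrix[1:3, 1:3])
  cat(sprintf("<rigid_transform> rotation %.2f deg, translation (%.3f, %.3f, %.3f) m\n",
              ang, x$matrix[1, 4], x$matrix[2, 4], x$matrix[3, 4]))
  invisible(x)
}

#' Invert a rigid transform
#' @param T a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(T) {
  R <- T$matrix[1:3, 1:3]
  t <- T$matrix[1:3, 4]
  rigid_transform(t(R), -as.vector(t(R) %*% t))
}

#' Compose rigid transforms (a then b)
#' @param b,a `rigid_transform`s; the result applies `a` first, then `b`.
#' @return the composed `rigid_transform`.
#' @export
compose_transform <- function(b, a) {
  m <- b$matrix %*% a$matrix
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

# geodesic rotation angle in degrees
rotation_angle_deg <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(pmin(1, pmax(-1, c_))) * 180 / pi
}

#' Apply a rigid transform to a point cloud or matrix
#'
#' @param pc a [point_cloud()] or an N x 3 matrix.
#' @param T a `rigid_transform`.
#' @return object of the same type, rigidly moved.
#' @export
apply_transform <- function(pc, T) {
  if (!inherits(T, "rigid_transform")) stop("T must be a rigid_transform")
  R <- T$matrix[1:3, 1:3]
  t <- T$matrix[1:3, 4]
  if (is.matrix(pc)) return(sweep(pc %*% t(R), 2, -t))
  out <- pc
  out$coords <- sweep(pc$coords %*% t(R), 2, -t)
  colnames(out$coords) <- c("x", "y", "z")
  out
}

#' Extract a curve skeleton by Laplacian-style contraction
#'
#' Iteratively contracts the cloud by moving every point towards the
#' centroid of its k-nearest neighbourhood (a graph-Laplacian smoothing
#' step) blended with an attraction term to its original position, which
#' collapses tubular structures (trunks, branches) onto their centre
#' lines. The contracted points are then pooled into skeleton nodes on a
#' voxel grid and connected by a Euclidean minimum spanning tree
#' restricted to short edges.
#'
#' @param pc a [point_cloud()] with at least 100 points.
#' @param contraction_iters number of contraction sweeps (default 20).
#' @param attraction weight in \[0, 1\] pulling points back towards their
#'   original positions (default 0.05; smaller contracts harder).
#' @param contract_radius neighbourhood ball radius in metres (default
#'   0.06 — of the order of the thickest tube diameter so that the whole
#'   cross-section contributes to each Laplacian step).
#' @param node_spacing voxel size for node pooling in metres (default 0.03).
#' @param thin_voxel pre-contraction voxel thinning (default 0.02; `NULL`
#'   to contract the raw cloud).
#' @return a `skeleton`: list with `nodes` (M x 3), `edges` (E x 2 index
#'   pairs), `source`, `base_idx` (lowest-z node) and `origin_map` (list of
#'   contributing original point indices per node).
#' @export
extract_skeleton <- function(pc, contraction_iters = 20, attraction = 0.05,
                             contract_radius = 0.06, node_spacing = 0.03,
                             thin_voxel = 0.02) {
  n <- npoints(pc)
  if (n < 100) stop("extract_skeleton needs at least 100 points")
  if (!is.null(thin_voxel)) {
    vd0 <- voxel_downsample(pc$coords, thin_voxel)
    x0 <- vd0$centroids
    pt2work <- match(vd0$point_key, vd0$keys)   # original point -> work point
  } else {
    x0 <- pc$coords
    pt2work <- seq_len(n)
  }
  x <- x0
  nw <- nrow(x0)
  bb <- apply(x0, 2, range)
  for (it in seq_len(contraction_iters)) {
    nb <- radius_search(x, x, contract_radius)
    # contraction acts only across the local curve direction so points do
    # not slide along the structure and clump (projection done in C++)
    step <- .contract_step_cpp(x, nb)
    x <- x + (1 - attraction) * step + attraction * (x0 - x)
    if (any(x < matrix(bb[1, ] - 1, nw, 3, byrow = TRUE) |
            x > matrix(bb[2, ] + 1, nw, 3, byrow = TRUE)))
      stop("contraction diverged at iteration ", it)
  }
  vd <- voxel_downsample(x, node_spacing)
  nodes <- vd$centroids
  m <- nrow(nodes)
  if (m < 2) stop("contraction collapsed the cloud to fewer than 2 nodes")
  work2node <- match(vd$point_key, vd$keys)     # work point -> node
  origin_map <- split(seq_len(n), work2node[pt2work])
  edges <- mst_edges(nodes, max_edge = 6 * node_spacing)
  structure(list(nodes = nodes, edges = edges,
                 source = pc$source,
                 base_idx = which.min(nodes[, 3]),
                 origin_map = unname(origin_map)),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d nodes, %d edges, source=%s\n",
              nrow(x$nodes), nrow(x$edges), x$source))
  invisible(x)
}

# Euclidean MST over a kNN graph; edges longer than max_edge are cut
# afterwards (disconnected far components stay disconnected).
mst_edges <- function(nodes, max_edge = Inf, k = 10) {
  m <- nrow(nodes)
  if (m < 2) return(matrix(integer(0), ncol = 2))
  k <- min(k, m - 1)
  nn <- FNN::get.knn(nodes, k = k)
  from <- rep(seq_len(m), k)
  to <- as.vector(nn$nn.index)
  w <- as.vector(nn$nn.dist)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  mst <- igraph::mst(g)
  e <- igraph::as_edgelist(mst)
  keep <- igraph::E(mst)$weight <= max_edge
  matrix(as.integer(e[keep, , drop = FALSE]), ncol = 2)
}

# ---- FPFH features ---------------------------------------------------------

# Direction field for skeleton FPFH: the local curve tangent (principal
# eigenvector), sign-disambiguated toward +z. Skeletons are curve-like, so
# tangents are well defined where surface normals are not.
skeleton_directions <- function(pts, radius) {
  nb <- radius_search(pts, pts, radius)
  t(vapply(seq_len(nrow(pts)), function(i) {
    idx <- nb[[i]]
    if (length(idx) < 3) return(c(0, 0, 1))
    ev <- eigen(stats::cov(pts[idx, , drop = FALSE]), symmetric = TRUE)
    v <- ev$vectors[, 1]
    if (v[3] < 0) v <- -v
    v
  }, numeric(3)))
}

# Fast point feature histograms (11 bins per angular feature, 33-dim),
# computed as SPFH + distance-weighted neighbour SPFH mean.
fpfh_features <- function(pts, normals, radius) {
  n <- nrow(pts)
  nb <- radius_search(pts, pts, radius)
  bins <- 11L
  spfh <- matrix(0, n, 3 * bins)
  for (i in seq_len(n)) {
    idx <- setdiff(nb[[i]], i)
    if (length(idx) == 0) next
    d <- pts[idx, , drop = FALSE] -
      matrix(pts[i, ], length(idx), 3, byrow = TRUE)
    dn <- sqrt(rowSums(d^2))
    ok <- dn > 1e-12
    if (!any(ok)) next
    d <- d[ok, , drop = FALSE] / dn[ok]
    ni <- normals[i, ]
    nj <- normals[idx[ok], , drop = FALSE]
    # Darboux frame angles
    alpha_ <- rowSums(nj * cbind(ni[2] * d[, 3] - ni[3] * d[, 2],
                                 ni[3] * d[, 1] - ni[1] * d[, 3],
                                 ni[1] * d[, 2] - ni[2] * d[, 1]))
    phi_ <- as.vector(d %*% ni)
    theta_ <- atan2(rowSums(nj * d), as.vector(nj %*% ni))
    b1 <- pmin(bins, pmax(1, ceiling((alpha_ + 1) / 2 * bins)))
    b2 <- pmin(bins, pmax(1, ceiling((phi_ + 1) / 2 * bins)))
    b3 <- pmin(bins, pmax(1, ceiling((theta_ + pi) / (2 * pi) * bins)))
    spfh[i, ] <- c(tabulate(b1, bins), tabulate(b2, bins),
                   tabulate(b3, bins)) / sum(ok)
  }
  fpfh <- spfh
  for (i in seq_len(n)) {
    idx <- setdiff(nb[[i]], i)
    if (length(idx) == 0) next
    w <- 1 / pmax(1e-9, sqrt(rowSums((pts[idx, , drop = FALSE] -
      matrix(pts[i, ], length(idx), 3, byrow = TRUE))^2)))
    fpfh[i, ] <- spfh[i, ] +
      as.vector(w %*% spfh[idx, , drop = FALSE]) / sum(w)
  }
  fpfh
}

# Kabsch/Umeyama rigid fit dst ~ R src + t (no scale).
kabsch <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cd - as.vector(R %*% cs)
  rigid_transform(R, t)
}

#' Coarse global registration of two skeletons
#'
#' Feature-based global registration in the spirit of fast global
#' registration: FPFH descriptors are computed on both node sets, mutual
#' nearest-neighbour feature matches form candidate correspondences, and up
#' to `max_iters` random-sample consensus restarts over perturbed
#' correspondence subsets estimate rigid transforms, keeping the one with
#' the smallest inlier RMSE.
#'
#' @param src,dst `skeleton`s with at least 10 nodes; the result maps
#'   `src` nodes onto `dst`.
#' @param max_iters restart budget (default 50).
#' @param feature_radius FPFH radius; default 20 x mean node spacing — of
#'   the order of a branch length, so histograms see real structure.
#' @param seed RNG seed for the sampling (default 42).
#' @return a `rigid_transform` with attribute `rmse` (inlier RMSE, metres).
#' @export
coarse_register <- function(src, dst, max_iters = 50, feature_radius = NULL,
                            seed = 42) {
  s <- src$nodes; d <- dst$nodes
  if (nrow(s) < 10 || nrow(d) < 10)
    stop("coarse_register needs skeletons with >= 10 nodes")
  spacing <- mean(FNN::get.knn(d, k = 1)$nn.dist)
  if (is.null(feature_radius)) feature_radius <- 20 * spacing
  ns <- skeleton_directions(s, feature_radius / 2)
  nd <- skeleton_directions(d, feature_radius / 2)
  fs <- fpfh_features(s, ns, feature_radius)
  fd <- fpfh_features(d, nd, feature_radius)
  fwd <- FNN::get.knnx(fd, fs, k = 1)$nn.index[, 1]
  bwd <- FNN::get.knnx(fs, fd, k = 1)$nn.index[, 1]
  mutual <- which(bwd[fwd] == seq_len(nrow(s)))
  corr <- cbind(mutual, fwd[mutual])
  if (nrow(corr) < 4) corr <- cbind(seq_len(nrow(s)), fwd)
  if (nrow(corr) < 4)
    stop("no inlier correspondences; try a larger feature radius")
  inlier_thr <- 3 * spacing
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  best <- NULL; best_rmse <- Inf
  for (it in seq_len(max_iters)) {
    samp <- sample(nrow(corr), min(4, nrow(corr)))
    Tc <- try(kabsch(s[corr[samp, 1], , drop = FALSE],
                     d[corr[samp, 2], , drop = FALSE]), silent = TRUE)
    if (inherits(Tc, "try-error")) next
    moved <- apply_transform(s, Tc)
    r <- sqrt(rowSums((moved[corr[, 1], , drop = FALSE] -
                         d[corr[, 2], , drop = FALSE])^2))
    inl <- r <= inlier_thr
    if (sum(inl) >= 4) {
      Tc <- kabsch(s[corr[inl, 1], , drop = FALSE],
                   d[corr[inl, 2], , drop = FALSE])
      moved <- apply_transform(s, Tc)
      nnr <- FNN::get.knnx(d, moved, k = 1)$nn.dist[, 1]
      rmse <- sqrt(mean(pmin(nnr, inlier_thr)^2))
    } else rmse <- Inf
    if (rmse < best_rmse) { best_rmse <- rmse; best <- Tc }
  }
  if (is.null(best))
    stop("no inlier correspondences; try a larger feature radius")
  attr(best, "rmse") <- best_rmse
  best
}

#' Fine local registration (iterative closest point)
#'
#' Point-to-point ICP refining an initial alignment: alternate
#' nearest-neighbour correspondence search (capped at `max_corr_dist`) and
#' rigid least-squares fits until the correspondence RMSE improves by less
#' than `tol` relative, or `max_iters` is reached.
#'
#' @param src,dst `skeleton`s; the result maps `src` onto `dst`.
#' @param init initial `rigid_transform` (e.g. from [coarse_register()]).
#' @param max_corr_dist correspondence distance cap in metres (default 0.2).
#' @param max_iters iteration cap (default 100).
#' @param tol relative RMSE tolerance (default 1e-6).
#' @return a `rigid_transform` with attributes `rmse` and `converged`.
#' @export
fine_register <- function(src, dst, init = rigid_transform(),
                          max_corr_dist = 0.2, max_iters = 100, tol = 1e-6) {
  s <- src$nodes; d <- dst$nodes
  Tcur <- init
  moved <- apply_transform(s, Tcur)
  nn <- FNN::get.knnx(d, moved, k = 1)
  prev_rmse <- sqrt(mean(pmin(nn$nn.dist[, 1], max_corr_dist)^2))
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    keep <- nn$nn.dist[, 1] <= max_corr_dist
    if (sum(keep) < 4) break
    Tnew <- kabsch(s[keep, , drop = FALSE],
                   d[nn$nn.index[keep, 1], , drop = FALSE])
    moved_new <- apply_transform(s, Tnew)
    nn_new <- FNN::get.knnx(d, moved_new, k = 1)
    rmse <- sqrt(mean(pmin(nn_new$nn.dist[, 1], max_corr_dist)^2))
    if (rmse > prev_rmse + 1e-15) break   # objective must not increase
    Tcur <- Tnew; moved <- moved_new; nn <- nn_new
    if (prev_rmse - rmse < tol * max(prev_rmse, 1e-12)) {
      prev_rmse <- rmse; converged <- TRUE; break
    }
    prev_rmse <- rmse
  }
  if (!converged)
    warning("ICP stopped at the iteration cap; returning best-so-far")
  attr(Tcur, "rmse") <- prev_rmse
  attr(Tcur, "converged") <- converged
  Tcur
}

#' Fuse a lidar and a drone cloud through a registration transform
#'
#' Returns the union of the lidar cloud and the transformed drone cloud,
#' keeping colour from the drone points and intensity from the lidar points
#' and tagging per-point provenance.
#'
#' @param lidar_pc lidar-source [point_cloud()].
#' @param drone_pc drone-source [point_cloud()].
#' @param T `rigid_transform` mapping the drone frame onto the lidar frame
#'   (from the skeleton registration of the same tree).
#' @return a [point_cloud()] with attribute `provenance` (character vector,
#'   `"lidar"`/`"drone"` per point); intensity is carried on lidar points
#'   (NA on drone points) and colour on drone points.
#' @export
fuse_clouds <- function(lidar_pc, drone_pc, T) {
  if (identical(lidar_pc$source, drone_pc$source))
    stop("fuse_clouds needs one lidar and one drone cloud, got two '",
         lidar_pc$source, "'")
  moved <- apply_transform(drone_pc, T)
  n1 <- npoints(lidar_pc); n2 <- npoints(moved)
  out <- point_cloud(rbind(lidar_pc$coords, moved$coords),
                     crs = lidar_pc$crs, source = "synthetic")
  if (!is.null(lidar_pc$intensity))
    out$intensity <- c(lidar_pc$intensity, rep(NA_real_, n2))
  if (!is.null(moved$rgb)) {
    filler <- matrix(NA_integer_, n1, 3)
    out$rgb <- rbind(filler, moved$rgb)
  }
  attr(out, "provenance") <- c(rep("lidar", n1), rep("drone", n2))
  out
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
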