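#' Estimate trunk radius from a horizontal slab
#'
#' The median horizontal distance of slab points from their x-y centroid —
#' a robust radius estimate that tolerates moderate branch contamination.
#' The slab is expressed in metres above the lowest point of the tree.
#'
#' @param tree a `tree_instance` or [point_cloud()].
#' @param slab numeric length-2 (z_lo, z_hi) above the base
#'   (default `c(0.2, 0.4)`).
#' @param min_slab_points minimum slab occupancy before falling back to the
#'   full-cloud bottom decile (default 30).
#' @return trunk radius in metres, capped at 0.5.
#' @export
estimate_trunk_radius <- function(tree, slab = c(0.2, 0.4),
                                  min_slab_points = 30) {
  pc <- if (inherits(tree, "tree_instance")) tree$points else tree
  z0 <- min(pc$coords[, 3])
  zrel <- pc$coords[, 3] - z0
  idx <- which(zrel >= slab[1] & zrel <= slab[2])
  if (length(idx) < min_slab_points) {
    warning("too few slab points; falling back to the bottom decile")
    idx <- order(zrel)[seq_len(max(min_slab_points,
                                   ceiling(0.1 * npoints(pc))))]
  }
  xy <- pc$coords[idx, 1:2, drop = FALSE]
  # iteratively trimmed median so off-axis material in the slab (posts,
  # low branches) cannot inflate the estimate
  # centre seeded with the component-wise median (robust to a sizeable
  # off-axis cluster in the slab), then refined on the trimmed set
  cen <- apply(xy, 2, stats::median)
  d <- sqrt((xy[, 1] - cen[1])^2 + (xy[, 2] - cen[2])^2)
  keep <- which(d <= 2 * stats::median(d))
  for (it in 1:3) {
    cen <- colMeans(xy[keep, , drop = FALSE])
    d <- sqrt((xy[, 1] - cen[1])^2 + (xy[, 2] - cen[2])^2)
    keep <- which(d <= 2 * stats::median(d[keep]))
  }
  r <- stats::median(d[keep])
  min(max(r, 1e-4), 0.5)
}

#' Build the tree graph from a skeleton
#'
#' Radius-based nearest-neighbour graph over the skeleton nodes: vertices
#' are nodes, an edge joins every node pair within `radius`, with weight
#' equal to the squared Euclidean distance. The base is the node with the
#' lowest z; tips are degree-1 vertices plus vertices that are local maxima
#' of shortest-path distance from the base.
#'
#' @param skel a `skeleton`.
#' @param radius R-NN connection radius in metres (the pipeline derives it
#'   as 2 x trunk radius).
#' @return a `tree_graph`: list with `graph` (igraph, weighted), `nodes`,
#'   `base`, `tips`, `r_nn`.
#' @export
build_tree_graph <- function(skel, radius) {
  stopifnot(radius > 0)
  nodes <- skel$nodes
  m <- nrow(nodes)
  if (m < 2) stop("skeleton must have >= 2 nodes")
  nb <- radius_search(nodes, nodes, radius)
  from <- rep(seq_len(m), lengths(nb))
  to <- unlist(nb)
  keep <- from < to
  from <- from[keep]; to <- to[keep]
  if (length(from) == 0)
    stop("empty edge set; use a larger R-NN radius")
  w <- rowSums((nodes[from, , drop = FALSE] - nodes[to, , drop = FALSE])^2)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, m - igraph::vcount(g)))
  igraph::E(g)$weight <- pmax(w, 1e-12)
  # the base is the lowest vertex of the main (largest) component: a stray
  # contracted outlier below the trunk must not hijack the anchor
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  main <- which(comp == as.integer(names(sizes)[which.max(sizes)]))
  base <- main[which.min(nodes[main, 3])]
  # distances measured within each connected component from its own lowest
  # vertex, so disconnected (occlusion-broken) pieces still get tips
  dist_base <- rep(Inf, m)
  for (cc in unique(comp)) {
    verts <- which(comp == cc)
    lb <- if (base %in% verts) base else verts[which.min(nodes[verts, 3])]
    dist_base[verts] <- igraph::distances(g, v = lb, to = verts)[1, ]
  }
  deg <- igraph::degree(g)
  local_max <- vapply(seq_len(m), function(v) {
    nbv <- setdiff(nb[[v]], v)
    length(nbv) > 0 && all(dist_base[nbv] <= dist_base[v])
  }, TRUE)
  tips <- sort(unique(c(which(deg == 1), which(local_max))))
  tips <- setdiff(tips, base)
  structure(list(graph = g, nodes = nodes, base = base, tips = tips,
                 r_nn = radius, source = skel$source),
            class = "tree_graph")
}

#' @export
print.tree_graph <- function(x, ...) {
  cat(sprintf("<tree_graph> %d vertices, %d edges, base=%d, %d tips, r=%.3f m\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$base, length(x$tips), x$r_nn))
  invisible(x)
}

#' Prune support structures by shortest-path logic
#'
#' Retains exactly the vertices lying on some Dijkstra shortest path from
#' the trunk base to a tip; everything else — skeleton segments that no
#' base-to-tip route traverses, typically support structures hanging off
#' the side — is removed. Unreachable tips are reported and excluded.
#'
#' @param g a `tree_graph`.
#' @return a `skeleton` of the retained nodes, with attributes `kept_idx`
#'   (indices into the graph's nodes) and `unreachable_tips`.
#' @export
graph_prune_supports <- function(g) {
  dist_base <- igraph::distances(g$graph, v = g$base)[1, ]
  reach <- g$tips[is.finite(dist_base[g$tips])]
  unreachable <- setdiff(g$tips, reach)
  if (length(reach) == 0)
    stop("no tip is reachable from the base")
  keep <- integer(0)
  # path-union within each connected component, each from its own lowest
  # vertex: occlusion can break a branch off the main skeleton, and the
  # broken piece must survive here so voxel gap filling can re-anchor it
  comp <- igraph::components(g$graph)$membership
  for (cc in unique(comp)) {
    verts <- which(comp == cc)
    local_base <- if (g$base %in% verts) g$base
                  else verts[which.min(g$nodes[verts, 3])]
    local_tips <- intersect(g$tips, verts)
    local_tips <- setdiff(local_tips, local_base)
    if (length(local_tips) == 0) { keep <- c(keep, local_base); next }
    paths <- igraph::shortest_paths(g$graph, from = local_base,
                                    to = local_tips,
                                    output = "vpath")$vpath
    keep <- c(keep, local_base, unlist(lapply(paths, as.integer)))
  }
  keep <- sort(unique(keep))
  out <- subset_skeleton_nodes(g$nodes, keep, g$source)
  attr(out, "kept_idx") <- keep
  attr(out, "unreachable_tips") <- unreachable
  out
}

# rebuild a skeleton object from a node subset (edges via short-edge MST)
subset_skeleton_nodes <- function(nodes, keep, source,
                                  max_edge_factor = 6) {
  sub <- nodes[keep, , drop = FALSE]
  spacing <- if (nrow(sub) > 1) stats::median(FNN::get.knn(sub, k = 1)$nn.dist)
             else 0.05
  edges <- if (nrow(sub) > 1) mst_edges(sub, max_edge = max_edge_factor * spacing)
           else matrix(integer(0), ncol = 2)
  structure(list(nodes = sub, edges = edges, source = source,
                 base_idx = which.min(sub[, 3]), origin_map = NULL),
            class = "skeleton")
}

#' Prune support structures by LiDAR intensity
#'
#' Assigns each skeleton node the mean normalised intensity of the cloud
#' points within radius `r` (an R-NN transfer), then removes crown nodes
#' whose intensity exceeds the tree-level mean by more than `alpha`
#' standard deviations — support material (metal posts, wires) reflects
#' more strongly than bark. Removal is restricted to nodes above
#' `trunk_top_z` so the trunk itself is never pruned.
#'
#' @param skel a `skeleton`.
#' @param pc the source [point_cloud()] carrying intensity.
#' @param r R-NN transfer radius in metres (the trunk radius by default
#'   convention; required).
#' @param alpha threshold multiplier (default 1.0).
#' @param trunk_top_z crown floor in metres (default: base z + 0.3).
#' @return the pruned `skeleton`, with attributes `kept_idx`,
#'   `removed_nodes` (coordinates of removed nodes) and `node_intensity`.
#' @export
intensity_prune_supports <- function(skel, pc, r, alpha = 1.0,
                                     trunk_top_z = NULL) {
  if (is.null(pc$intensity)) {
    warning("cloud has no intensity channel; skipping intensity pruning")
    return(skel)
  }
  if (is.null(trunk_top_z)) trunk_top_z <- min(skel$nodes[, 3]) + 0.3
  nb <- radius_search(pc$coords, skel$nodes, r)
  node_int <- vapply(nb, function(idx)
    if (length(idx) > 0) mean(pc$intensity[idx]) else NA_real_, 0)
  mu <- mean(node_int, na.rm = TRUE)
  sdv <- stats::sd(node_int, na.rm = TRUE)
  if (!is.finite(sdv) || sdv == 0) sdv <- 0
  # the absolute margin keeps near-uniform reflectivity untouched: without
  # it, mean + alpha*sd clips the upper tail of any homogeneous material
  high <- !is.na(node_int) & node_int > mu + alpha * sdv &
    node_int > mu + 0.1
  remove <- high & skel$nodes[, 3] > trunk_top_z
  keep <- which(!remove)
  out <- subset_skeleton_nodes(skel$nodes, keep, skel$source)
  attr(out, "kept_idx") <- keep
  attr(out, "removed_nodes") <- skel$nodes[remove, , drop = FALSE]
  attr(out, "node_intensity") <- node_int
  out
}

#' Fill skeleton gaps from voxel-downsampled cloud points
#'
#' Voxel-downsamples the original cloud, discards voxels flagged as coming
#' from removed support structures, clusters the pruned skeleton into
#' connected components (Euclidean clustering), and reconnects every
#' broken component to the base component along Dijkstra shortest paths
#' whose intermediate vertices are drawn only from the admissible voxel
#' centroids. Components that cannot be bridged without touching removed
#' material are dropped.
#'
#' @param pruned a pruned `skeleton`.
#' @param pc the original [point_cloud()].
#' @param voxel voxel size in metres (default 0.02).
#' @param removed_mask logical vector over the downsampled voxels flagging
#'   those originating from removed supports (see [voxel_support_mask()]),
#'   or `NULL` for none.
#' @param tol Euclidean-clustering / bridging connection tolerance
#'   (default 2 x voxel... capped below by the skeleton node spacing).
#' @param max_added maximum number of bridging nodes added per tree
#'   (default 200).
#' @return a connected `skeleton`; attributes `added_nodes` (matrix of
#'   bridging node coordinates) and `dropped_components` (count).
#' @export
fill_gaps <- function(pruned, pc, voxel = 0.02, removed_mask = NULL,
                      tol = NULL, max_added = 200) {
  stopifnot(voxel > 0)
  vd <- voxel_downsample(pc$coords, voxel)
  vox <- vd$centroids
  if (!is.null(removed_mask)) {
    stopifnot(length(removed_mask) == nrow(vox))
    vox <- vox[!removed_mask, , drop = FALSE]
  }
  nodes <- pruned$nodes
  m <- nrow(nodes)
  spacing <- if (m > 1) stats::median(FNN::get.knn(nodes, k = 1)$nn.dist) else voxel
  if (is.null(tol)) tol <- max(2 * voxel, 2.5 * spacing)
  # components of the pruned skeleton under Euclidean clustering; the main
  # skeleton is the largest component (the lowest node may sit on a pruned
  # support stub, never on the trunk)
  comp <- dbscan_points(nodes, eps = tol, min_pts = 1)
  sizes <- table(comp)
  base_comp <- as.integer(names(sizes)[which.max(sizes)])
  if (all(comp == base_comp)) {
    attr(pruned, "added_nodes") <- matrix(numeric(0), ncol = 3)
    attr(pruned, "dropped_components") <- 0L
    return(pruned)
  }
  all_pts <- rbind(nodes, vox)
  nb <- radius_search(all_pts, all_pts, tol)
  from <- rep(seq_len(nrow(all_pts)), lengths(nb))
  to <- unlist(nb)
  keep <- from < to
  from <- from[keep]; to <- to[keep]
  w <- sqrt(rowSums((all_pts[from, , drop = FALSE] -
                       all_pts[to, , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(all_pts) - igraph::vcount(g)))
  igraph::E(g)$weight <- pmax(w, 1e-12)
  base_vertex <- which(comp == base_comp)[1]
  added <- integer(0)
  dropped <- 0L
  keep_comp <- rep(TRUE, m)
  for (cc in setdiff(unique(comp), base_comp)) {
    members <- which(comp == cc)
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = members[1], to = base_vertex,
                             output = "vpath"))$vpath[[1]]
    sp <- as.integer(sp)
    if (length(sp) == 0) { keep_comp[members] <- FALSE; dropped <- dropped + 1L; next }
    bridge <- sp[sp > m]
    if (length(added) + length(bridge) > max_added) {
      keep_comp[members] <- FALSE; dropped <- dropped + 1L; next
    }
    added <- unique(c(added, bridge))
  }
  new_nodes <- rbind(nodes[keep_comp, , drop = FALSE],
                     all_pts[added, , drop = FALSE])
  out <- subset_skeleton_nodes(new_nodes, seq_len(nrow(new_nodes)),
                               pruned$source)
  attr(out, "added_nodes") <- all_pts[added, , drop = FALSE]
  attr(out, "dropped_components") <- dropped
  out
}

#' Flag voxels originating from removed support structures
#'
#' Marks every voxel of `voxel_downsample(pc, voxel)` whose centroid lies
#' within `r` of a removed skeleton node, so gap filling can never
#' reintroduce pruned support material.
#'
#' @param pc the original [point_cloud()].
#' @param voxel voxel size used by [fill_gaps()].
#' @param removed_nodes matrix of removed node coordinates (possibly empty).
#' @param r screening radius in metres.
#' @return logical vector over the downsampled voxels.
#' @export
voxel_support_mask <- function(pc, voxel, removed_nodes, r) {
  vox <- voxel_downsample(pc$coords, voxel)$centroids
  if (is.null(removed_nodes) || nrow(removed_nodes) == 0)
    return(rep(FALSE, nrow(vox)))
  d <- RANN::nn2(removed_nodes, vox, k = 1)$nn.dists[, 1]
  d <= r
}

#' Smooth and uniformly resample a skeleton
#'
#' Decomposes the skeleton's edge graph into maximal paths between
#' junctions (degree >= 3) and endpoints, applies a moving-average smooth
#' of `window` nodes along each path (junction endpoints held fixed), and
#' linearly resamples each path to uniform node spacing. Junction count is
#' preserved.
#'
#' @param skel a connected `skeleton` with edges.
#' @param window moving-average window in nodes (default 5; clamped to the
#'   path length).
#' @param spacing target node spacing in metres (default: median input
#'   edge length).
#' @return the smoothed, resampled `skeleton`.
#' @export
smooth_interpolate <- function(skel, window = 5, spacing = NULL) {
  if (nrow(skel$edges) == 0) return(skel)
  paths <- decompose_paths(skel)
  if (is.null(spacing)) {
    el <- sqrt(rowSums((skel$nodes[skel$edges[, 1], , drop = FALSE] -
                          skel$nodes[skel$edges[, 2], , drop = FALSE])^2))
    spacing <- stats::median(el)
  }
  junctions <- unique(unlist(lapply(paths, function(p) p[c(1, length(p))])))
  jc <- skel$nodes[junctions, , drop = FALSE]
  new_nodes <- jc
  jidx <- seq_len(nrow(jc))
  names(jidx) <- junctions
  edges <- matrix(integer(0), ncol = 2)
  for (p in paths) {
    xyz <- skel$nodes[p, , drop = FALSE]
    np <- nrow(xyz)
    w <- min(window, np)
    if (w >= 3 && np >= 3) {
      sm <- apply(xyz, 2, function(v)
        stats::filter(v, rep(1 / w, w), sides = 2))
      inner <- 2:(np - 1)
      ok <- inner[!is.na(sm[inner, 1])]
      xyz[ok, ] <- sm[ok, ]
    }
    seg <- sqrt(rowSums(diff(xyz)^2))
    s <- c(0, cumsum(seg))
    L <- s[np]
    n_out <- max(2L, round(L / spacing) + 1L)
    si <- seq(0, L, length.out = n_out)
    ri <- cbind(stats::approx(s, xyz[, 1], si)$y,
                stats::approx(s, xyz[, 2], si)$y,
                stats::approx(s, xyz[, 3], si)$y)
    # endpoints snap to the shared junction vertices
    i_start <- jidx[[as.character(p[1])]]
    i_end <- jidx[[as.character(p[length(p)])]]
    inner_rows <- if (n_out > 2) ri[2:(n_out - 1), , drop = FALSE]
                  else matrix(numeric(0), ncol = 3)
    base_n <- nrow(new_nodes)
    new_nodes <- rbind(new_nodes, inner_rows)
    chain <- c(i_start, if (n_out > 2) base_n + seq_len(n_out - 2L), i_end)
    edges <- rbind(edges, cbind(chain[-length(chain)], chain[-1]))
  }
  structure(list(nodes = unname(new_nodes), edges = edges,
                 source = skel$source,
                 base_idx = which.min(new_nodes[, 3]), origin_map = NULL),
            class = "skeleton")
}

# maximal paths between junction/endpoint vertices of the skeleton's edges
decompose_paths <- function(skel) {
  g <- igraph::graph_from_edgelist(skel$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(skel$nodes) - igraph::vcount(g)))
  deg <- igraph::degree(g)
  stops <- which(deg != 2)
  visited <- matrix(FALSE, igraph::vcount(g), igraph::vcount(g))
  paths <- list()
  for (v in stops) {
    for (u in as.integer(igraph::neighbors(g, v))) {
      if (visited[v, u]) next
      p <- c(v, u)
      visited[v, u] <- visited[u, v] <- TRUE
      while (deg[p[length(p)]] == 2) {
        nxt <- setdiff(as.integer(igraph::neighbors(g, p[length(p)])),
                       p[length(p) - 1])
        if (length(nxt) == 0) break
        visited[p[length(p)], nxt[1]] <- visited[nxt[1], p[length(p)]] <- TRUE
        p <- c(p, nxt[1])
      }
      paths[[length(paths) + 1]] <- p
    }
  }
  # isolated cycles (all degree 2) are traversed from an arbitrary vertex
  if (length(stops) == 0 && igraph::vcount(g) > 0) {
    p <- as.integer(igraph::dfs(g, 1)$order)
    paths[[1]] <- c(p, p[1])
  }
  paths
}

#' Count first-order branches of a refined skeleton
#'
#' The trunk is the shortest path from the base to the highest tip. Every
#' other tip defines a candidate branch: the portion of its shortest path
#' back to the base that lies off the trunk, anchored at the trunk vertex
#' where it joins. Branches shorter than `min_len` are discarded.
#'
#' @param skel a connected, smoothed `skeleton`.
#' @param radius R-NN radius for the graph rebuild (default: 2.5 x median
#'   edge length).
#' @param min_len minimum branch length in metres (default 0.1).
#' @return a `branch_set`: list with `trunk_path` (vertex indices),
#'   `branches` (list of vertex paths, junction first), `num_branch`,
#'   `lengths` (metres) and `nodes` (the skeleton nodes).
#' @export
count_branches <- function(skel, radius = NULL, min_len = 0.1) {
  if (is.null(radius)) {
    if (nrow(skel$edges) > 0) {
      el <- sqrt(rowSums((skel$nodes[skel$edges[, 1], , drop = FALSE] -
                            skel$nodes[skel$edges[, 2], , drop = FALSE])^2))
      radius <- 2.5 * stats::median(el)
    } else radius <- 0.1
  }
  g <- build_tree_graph(skel, radius)
  dist_base <- igraph::distances(g$graph, v = g$base)[1, ]
  tips <- g$tips[is.finite(dist_base[g$tips])]
  if (length(tips) == 0)
    return(structure(list(trunk_path = g$base, branches = list(),
                          num_branch = 0L, lengths = numeric(0),
                          nodes = skel$nodes), class = "branch_set"))
  apex <- tips[which.max(skel$nodes[tips, 3])]
  trunk <- as.integer(igraph::shortest_paths(
    g$graph, from = g$base, to = apex, output = "vpath")$vpath[[1]])
  on_trunk <- rep(FALSE, nrow(skel$nodes))
  on_trunk[trunk] <- TRUE
  branches <- list()
  lengths <- numeric(0)
  for (tp in setdiff(tips, apex)) {
    p <- as.integer(igraph::shortest_paths(
      g$graph, from = g$base, to = tp, output = "vpath")$vpath[[1]])
    off <- which(!on_trunk[p])
    if (length(off) == 0) next
    start <- min(off)
    seg <- p[max(1, start - 1):length(p)]   # junction vertex first
    xyz <- skel$nodes[seg, , drop = FALSE]
    len <- sum(sqrt(rowSums(diff(xyz)^2)))
    if (len < min_len) next
    branches[[length(branches) + 1]] <- seg
    lengths <- c(lengths, len)
  }
  # several tips can sit on the same branch (local-maximum tip detection),
  # and contraction can leave a short strand running parallel to a branch:
  # drop any branch whose off-trunk vertices are contained in a longer one,
  # or that runs within `radius` of a longer branch for most of its length
  if (length(branches) > 1) {
    off_sets <- lapply(branches, function(b) setdiff(b, trunk))
    ord <- order(lengths, decreasing = TRUE)
    keep <- logical(length(branches))
    covered <- integer(0)
    kept_polys <- list()
    for (i in ord) {
      xyz <- skel$nodes[off_sets[[i]], , drop = FALSE]
      dup <- all(off_sets[[i]] %in% covered)
      if (!dup && length(kept_polys) > 0) {
        for (kp in kept_polys) {
          d <- apply(xyz, 1, function(q) point_polyline_dist(kp, q))
          if (mean(d <= radius) > 0.6) { dup <- TRUE; break }
        }
      }
      if (!dup) {
        keep[i] <- TRUE
        covered <- c(covered, off_sets[[i]])
        kept_polys[[length(kept_polys) + 1]] <-
          skel$nodes[branches[[i]], , drop = FALSE]
      }
    }
    branches <- branches[keep]
    lengths <- lengths[keep]
  }
  structure(list(trunk_path = trunk, branches = branches,
                 num_branch = length(branches), lengths = lengths,
                 nodes = skel$nodes),
            class = "branch_set")
}

#' @export
print.branch_set <- function(x, ...) {
  cat(sprintf("<branch_set> %d branches off a %d-vertex trunk\n",
              x$num_branch, length(x$trunk_path)))
  invisible(x)
}
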