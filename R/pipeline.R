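#' Default pipeline configuration
#'
#' Returns the full default configuration as a nested list. User configs
#' (YAML files or lists) are validated against this schema: unknown keys
#' are rejected, known keys override the defaults.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    input = list(type = "synthetic", preset = "pear-small",
                 rows = 4L, cols = 5L, spacing = c(4.0, 3.5),
                 slope_deg = 0, gap_slots = NULL, n_points = 6000L,
                 support = "none", n_blossom_clusters = 12L,
                 touching_pairs = 0L, noise_outlier_frac = 0,
                 lidar_path = NULL, drone_path = NULL,
                 reference_path = NULL),
    stages = c("preprocess", "segment", "position", "fuse", "skeleton",
               "traits", "bloom"),
    # scene-level ratio: whole-orchard clouds mix ground and canopy point
    # densities, so the outlier fence must sit well above 1 sd
    sor = list(k = 16L, std_ratio = 2.5),
    csf = list(cloth_resolution = 0.5, class_threshold = 0.05),
    chm = list(cell_size = 0.05),
    segmentation = list(open_radius_px = 2L, min_area_px = 25L,
                        window_px = 65L, min_points = 200L),
    skeleton = list(contraction_iters = 20L, attraction = 0.05,
                    node_spacing = 0.03),
    registration = list(max_iters = 50L, max_corr_dist = 0.2),
    prune = list(graph = TRUE, intensity = TRUE, alpha = 1.0,
                 voxel = 0.02, graph_radius_mult = 2.0),
    traits = list(voxel = 0.02, min_branch_len = 0.1),
    bloom = list(min_pts = 20L, noise_n = 50L, max_depth = 4L,
                 max_assign_dist = 0.5),
    seed = 42L,
    output_dir = NULL)
}

#' Load and validate a pipeline configuration
#'
#' @param config a YAML file path, a nested list of overrides, or `NULL`
#'   for the defaults.
#' @return the validated, fully resolved configuration list.
#' @export
pipeline_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  merge_validate(base, config, path = "")
}

merge_validate <- function(base, user, path) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                collapse = ", "))
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && !is.null(names(base[[k]])))
      merge_validate(base[[k]], user[[k]], paste0(path, ".", k))
    else user[[k]]
  }
  base
}

#' Derive per-tree stage parameters from the trunk radius
#'
#' Distance parameters scale with the measured trunk radius: the R-NN
#' graph radius is `graph_radius_mult` x trunk radius x 2 metres... the
#' documented multipliers are graph radius = 2 r_trunk, blossom DBSCAN
#' eps = r_trunk, skeleton-proximity removal radius = r_trunk. Explicit
#' values in `overrides` always win; a missing trunk estimate falls back
#' to global defaults with a warning.
#'
#' @param r_trunk trunk radius in metres (or `NA`).
#' @param config resolved configuration list.
#' @param overrides named list of explicit parameter values.
#' @return list with `graph_radius`, `blossom_eps`, `removal_radius`,
#'   `voxel`.
#' @export
derive_parameters <- function(r_trunk, config = pipeline_config(),
                              overrides = list()) {
  if (is.na(r_trunk) || is.null(r_trunk)) {
    warning("missing trunk radius; using global defaults")
    r_trunk <- 0.05
  }
  out <- list(graph_radius = config$prune$graph_radius_mult * r_trunk,
              blossom_eps = r_trunk,
              removal_radius = r_trunk,
              voxel = config$prune$voxel)
  for (k in names(overrides)) out[[k]] <- overrides[[k]]
  out
}

#' Run the orchard analysis pipeline
#'
#' Orchestrates the stages enabled in the configuration on a synthetic
#' orchard (or input clouds), producing per-tree canopy and floral trait
#' tables. A failure in one tree flags that tree and the run continues.
#' Deterministic given the configured seed.
#'
#' @param config a configuration for [pipeline_config()].
#' @return list with `traits` (canopy trait data frame), `floral` (floral
#'   trait data frame), `grid` (`grid_system`), `trees`, `branch_sets`,
#'   `log` (per-stage messages) and `scene` artefacts. If
#'   `config$output_dir` is set, writes `traits_canopy.csv`,
#'   `traits_floral.csv`, `branches.json`, `grid.geojson` and
#'   `resolved_config.yaml` there.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- pipeline_config(config)
  logline <- character(0)
  say <- function(...) logline <<- c(logline, sprintf(...))

  # ---- input -----------------------------------------------------------
  if (cfg$input$type == "synthetic") {
    base_spec <- synthetic_tree_spec(
      n_points = cfg$input$n_points, support = cfg$input$support,
      n_blossom_clusters = cfg$input$n_blossom_clusters,
      touching_pairs = cfg$input$touching_pairs,
      noise_outlier_frac = cfg$input$noise_outlier_frac)
    orch <- generate_orchard(cfg$input$rows, cfg$input$cols,
                             spacing = cfg$input$spacing,
                             slope_deg = cfg$input$slope_deg,
                             gap_slots = cfg$input$gap_slots,
                             base_spec = base_spec, seed = cfg$seed)
    scene <- orch$scene
    say("input: synthetic orchard %dx%d, %d points", cfg$input$rows,
        cfg$input$cols, npoints(scene))
  } else {
    scene <- read_cloud(cfg$input$lidar_path)
    orch <- NULL
    say("input: %s, %d points", cfg$input$lidar_path, npoints(scene))
  }

  out <- list(log = NULL, config = cfg)

  # ---- preprocess ------------------------------------------------------
  den <- sor_denoise(scene, cfg$sor$k, cfg$sor$std_ratio)
  gf <- csf_ground_filter(den, cfg$csf$cloth_resolution,
                          cfg$csf$class_threshold)
  chm <- build_chm(gf$ground, gf$aboveground, cfg$chm$cell_size)
  say("preprocess: %d -> %d denoised, %d ground / %d aboveground",
      npoints(scene), npoints(den), npoints(gf$ground),
      npoints(gf$aboveground))
  out$chm <- chm
  out$aboveground <- gf$aboveground
  if (!"segment" %in% cfg$stages) { out$log <- logline; return(out) }

  # ---- segment ---------------------------------------------------------
  grey <- chm_to_grey(chm)
  rois <- detect_tree_rois(grey, cfg$segmentation$open_radius_px,
                           cfg$segmentation$min_area_px,
                           cfg$segmentation$window_px)
  trees <- crop_trees(gf$aboveground, rois, chm,
                      cfg$segmentation$min_points)
  say("segment: %d ROIs, %d instances", length(rois), length(trees))
  out$trees <- trees
  if (!"position" %in% cfg$stages) { out$log <- logline; return(out) }

  # ---- position --------------------------------------------------------
  layout <- if (!is.null(orch))
    list(rows = orch$layout$rows, cols = orch$layout$cols,
         spacing = orch$layout$spacing)
  else list(rows = 1L, cols = length(trees), spacing = c(1, 1))
  slots <- expand.grid(col = seq_len(layout$cols),
                       row = seq_len(layout$rows))
  expected <- cbind((slots$col - 1) * layout$spacing[1],
                    (slots$row - 1) * layout$spacing[2])
  centroids <- lapply(trees, function(tr)
    if (tr$status == "present" && npoints(tr$points) >= 10)
      trunk_centroid(tr) else NULL)
  fg <- flag_gaps(expected, trees,
                  match_radius = min(layout$spacing) / 2,
                  min_points = cfg$segmentation$min_points)
  lidar_cent <- do.call(rbind, lapply(seq_len(nrow(slots)), function(s) {
    t <- fg$slot_tree[s]
    if (is.na(t) || is.null(centroids[[t]])) return(NULL)
    data.frame(row = slots$row[s], col = slots$col[s],
               x = centroids[[t]][1], y = centroids[[t]][2])
  }))
  grid <- build_grid(lidar_cent, lidar_cent,
                     list(rows = layout$rows, cols = layout$cols,
                          spacing = layout$spacing))
  grid$cells$status[match(paste(slots$row, slots$col),
                          paste(grid$cells$row, grid$cells$col))] <-
    ifelse(fg$status == "present", grid$cells$status[
      match(paste(slots$row, slots$col),
            paste(grid$cells$row, grid$cells$col))], fg$status)
  say("position: %d present, %d gaps",
      sum(fg$status == "present"), sum(fg$status == "gap"))
  out$grid <- grid
  out$slot_status <- fg
  out$slots <- slots

  # ---- per-tree analysis ----------------------------------------------
  do_fuse <- "fuse" %in% cfg$stages && !is.null(orch)
  do_skel <- "skeleton" %in% cfg$stages
  do_traits <- "traits" %in% cfg$stages
  do_bloom <- "bloom" %in% cfg$stages && !is.null(orch)

  records <- list()
  floral_rows <- list()
  branch_sets <- list()
  for (s in seq_len(nrow(slots))) {
    tix <- fg$slot_tree[s]
    rec <- list(tree_id = s, row = slots$row[s], col = slots$col[s],
                status = fg$status[s],
                geo_x = NA_real_, geo_y = NA_real_,
                height_max_cm = NA_real_, projarea_m2 = NA_real_,
                volume_m3 = NA_real_, surfarea_m2 = NA_real_,
                diameter_m = NA_real_, num_branch = NA_integer_,
                num_blossom = NA_integer_, flag = "")
    if (is.na(tix) || fg$status[s] != "present") {
      records[[s]] <- rec; next
    }
    tr <- trees[[tix]]
    rec$geo_x <- centroids[[tix]][1]
    rec$geo_y <- centroids[[tix]][2]
    res <- try({
      r_trunk <- estimate_trunk_radius(tr)
      pars <- derive_parameters(r_trunk, cfg)
      pruned_cloud <- tr$points
      bs <- NULL
      if (do_skel) {
        skel <- extract_skeleton(tr$points,
                                 cfg$skeleton$contraction_iters,
                                 cfg$skeleton$attraction,
                                 node_spacing = cfg$skeleton$node_spacing)
        removed <- matrix(numeric(0), ncol = 3)
        if (cfg$prune$graph) {
          tg <- build_tree_graph(skel, pars$graph_radius)
          pr <- graph_prune_supports(tg)
          removed <- rbind(removed,
                           skel$nodes[-attr(pr, "kept_idx"), , drop = FALSE])
          skel <- pr
        }
        if (cfg$prune$intensity) {
          pr <- intensity_prune_supports(skel, tr$points,
                                         r = pars$removal_radius,
                                         alpha = cfg$prune$alpha)
          rm2 <- attr(pr, "removed_nodes")
          if (!is.null(rm2)) removed <- rbind(removed, rm2)
          skel <- pr
        }
        mask <- voxel_support_mask(tr$points, pars$voxel, removed,
                                   r = pars$removal_radius)
        skel <- fill_gaps(skel, tr$points, voxel = pars$voxel,
                          removed_mask = mask)
        if (cfg$prune$graph) {
          # final path-union pass on the reconnected skeleton clears any
          # fragments the bridging step attached off the main paths
          tg2 <- build_tree_graph(skel, pars$graph_radius)
          skel <- graph_prune_supports(tg2)
        }
        skel <- smooth_interpolate(skel)
        bs <- count_branches(skel, min_len = cfg$traits$min_branch_len)
        rec$num_branch <- bs$num_branch
        branch_sets[[as.character(s)]] <- bs
        # support-pruned cloud for trait analysis
        if (nrow(removed) > 0) {
          d <- RANN::nn2(removed, tr$points$coords,
                         k = 1)$nn.dists[, 1]
          pruned_cloud <- pc_subset(tr$points, d > pars$removal_radius)
        }
      }
      if (do_traits) {
        ct <- canopy_traits(pruned_cloud, r_trunk = r_trunk,
                            voxel = cfg$traits$voxel)
        rec$height_max_cm <- ct$height_max_cm
        rec$projarea_m2 <- ct$projarea_m2
        rec$volume_m3 <- ct$volume_m3
        rec$surfarea_m2 <- ct$surfarea_m2
        rec$diameter_m <- ct$diameter_m
      }
      if (do_bloom && !is.null(bs) && bs$num_branch > 0) {
        fl <- bloom_for_slot(orch, s, tr, bs, skel, pars, cfg)
        rec$num_blossom <- fl$num_blossom
        floral_rows[[as.character(s)]] <- fl$rows
      }
      NULL
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      rec$flag <- paste("failed:", conditionMessage(attr(res, "condition")))
      say("tree %d failed: %s", s, rec$flag)
    }
    records[[s]] <- rec
  }
  traits <- do.call(rbind, lapply(records, as.data.frame))
  floral <- if (length(floral_rows) > 0) do.call(rbind, floral_rows)
            else empty_floral_frame()
  say("traits: %d rows; floral: %d rows", nrow(traits), nrow(floral))
  out$traits <- traits
  out$floral <- floral
  out$branch_sets <- branch_sets
  out$log <- logline

  if (!is.null(cfg$output_dir)) write_artifacts(out, cfg)
  out
}

# floral analysis for one planted slot: register the tree's drone view
# onto the lidar frame through the skeletons, then run the blossom chain
bloom_for_slot <- function(orch, s, tr, bs, lidar_skel, pars, cfg) {
  slot <- orch$trees[[s]]
  if (is.null(slot$tree))
    return(list(num_blossom = NA_integer_, rows = NULL))
  drone <- slot$tree$drone_view
  # skeletonize the drone structure (colour-masked to exclude blossom)
  cand <- blossom_mask(drone)
  structure_pc <- pc_subset(drone, setdiff(seq_len(npoints(drone)), cand))
  dsk <- extract_skeleton(structure_pc, cfg$skeleton$contraction_iters,
                          cfg$skeleton$attraction,
                          node_spacing = cfg$skeleton$node_spacing)
  # move the lidar skeleton into the tree's local registration problem:
  # drone view is in its own frame; register drone skeleton -> lidar skel
  lsk_world <- lidar_skel
  Tc <- coarse_register(dsk, lsk_world,
                        max_iters = cfg$registration$max_iters,
                        seed = cfg$seed)
  Tf <- fine_register(dsk, lsk_world, init = Tc,
                      max_corr_dist = cfg$registration$max_corr_dist)
  fused_drone <- apply_transform(drone, Tf)
  cand_pc_idx <- blossom_mask(fused_drone)
  cand_pc_idx <- remove_near_skeleton(fused_drone, cand_pc_idx,
                                      lsk_world, r = pars$removal_radius)
  coords <- fused_drone$coords[cand_pc_idx, , drop = FALSE]
  clusters <- cluster_blossoms(coords, eps = pars$blossom_eps,
                               min_pts = cfg$bloom$min_pts)
  clusters <- classify_clusters(clusters, coords,
                                noise_n = cfg$bloom$noise_n,
                                seed = cfg$seed)
  model <- attr(clusters, "model")
  finals <- list()
  for (cl in clusters) {
    if (identical(cl$cls, "multi"))
      finals <- c(finals, split_multiflower(cl, coords, pars$blossom_eps,
                                            model,
                                            min_pts = cfg$bloom$min_pts,
                                            max_depth = cfg$bloom$max_depth))
    else finals <- c(finals, list(cl))
  }
  finals <- Filter(function(cl) !identical(cl$cls, "noise"), finals)
  if (length(finals) == 0)
    return(list(num_blossom = 0L, rows = NULL))
  zs <- vapply(finals, function(cl) cl$centroid[3], 0)
  strat <- stratify(zs, min(coords[, 3]), max(coords[, 3]) + 1e-9)
  finals <- lapply(seq_along(finals), function(i) {
    cl <- cluster_metrics(finals[[i]], coords)
    cl$stratum <- strat[i]
    cl
  })
  finals <- assign_to_branches(finals, bs,
                               max_assign_dist = cfg$bloom$max_assign_dist)
  rows <- do.call(rbind, lapply(finals, function(cl)
    data.frame(tree_id = s, stratum = cl$stratum, cls = cl$cls,
               n = cl$n,
               centroid_x = cl$centroid[1], centroid_y = cl$centroid[2],
               centroid_z = cl$centroid[3],
               volume_m3 = cl$volume_m3, surf_m2 = cl$surf_m2,
               projarea_m2 = cl$projarea_m2,
               branch_id = cl$branch_id)))
  list(num_blossom = length(finals), rows = rows)
}

empty_floral_frame <- function() {
  data.frame(tree_id = integer(0), stratum = character(0),
             cls = character(0), n = integer(0),
             centroid_x = numeric(0), centroid_y = numeric(0),
             centroid_z = numeric(0), volume_m3 = numeric(0),
             surf_m2 = numeric(0), projarea_m2 = numeric(0),
             branch_id = integer(0))
}

write_artifacts <- function(out, cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$output_dir, f)
  utils::write.csv(format_num_df(out$traits), p("traits_canopy.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format_num_df(out$floral), p("traits_floral.csv"),
                   row.names = FALSE, quote = FALSE)
  bj <- lapply(names(out$branch_sets), function(k) {
    bs <- out$branch_sets[[k]]
    list(tree_id = as.integer(k), num_branch = bs$num_branch,
         lengths = round(bs$lengths, 4))
  })
  jsonlite::write_json(bj, p("branches.json"), auto_unbox = TRUE)
  if (!is.null(out$grid)) write_grid_geojson(out$grid, p("grid.geojson"))
  yaml::write_yaml(strip_null(out$config), p("resolved_config.yaml"))
  invisible(NULL)
}

format_num_df <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.6g", df[[j]])
  df
}

strip_null <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, TRUE)]
  lapply(x, strip_null)
}

#' Export a grid system as GeoJSON points
#'
#' One point feature per cell, at the lidar centroid (geo coordinates if
#' assigned), with row, col and status properties.
#'
#' @param grid a `grid_system`.
#' @param path destination `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_grid_geojson <- function(grid, path) {
  feats <- lapply(seq_len(nrow(grid$cells)), function(i) {
    c_ <- grid$cells[i, ]
    x <- if (!is.na(c_$geo_x)) c_$geo_x else c_$lidar_x
    y <- if (!is.na(c_$geo_y)) c_$geo_y else c_$lidar_y
    list(type = "Feature",
         geometry = if (!is.na(x))
           list(type = "Point", coordinates = c(x, y)) else NULL,
         properties = list(row = c_$row, col = c_$col,
                           status = c_$status))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, null = "null",
                       digits = 8)
  invisible(path)
}
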