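test_that("point cloud construction validates and normalises channels", {
  pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(npoints(pc), 3)
  expect_identical(pc$source, "synthetic")

  # intensity is min-max normalised on construction, and that map is
  # idempotent: a second construction leaves values unchanged
  pc <- point_cloud(matrix(runif(30), 10), intensity = seq(100, 500,
                                                           length.out = 10))
  expect_equal(range(pc$intensity), c(0, 1))
  pc2 <- point_cloud(pc$coords, intensity = pc$intensity)
  expect_equal(pc2$intensity, pc$intensity)

  expect_error(point_cloud(cbind(1, 2)), "3 columns")
  expect_error(point_cloud(rbind(c(0, 0, NA))), "finite")
  expect_error(point_cloud(rbind(c(0, 0, 0)), rgb = rbind(c(-1, 0, 300))),
               "\\[0, 255\\]")
  # source inference: colour implies drone, intensity implies lidar
  expect_identical(point_cloud(diag(3), rgb = matrix(10L, 3, 3))$source,
                   "drone")
  expect_identical(point_cloud(diag(3), intensity = 1:3)$source, "lidar")
})

test_that("csv, ply and las files round-trip coordinates and channels", {
  set.seed(1)
  pc <- point_cloud(matrix(runif(60, 0, 10), 20),
                    intensity = runif(20), source = "lidar")
  rgbpc <- point_cloud(matrix(runif(60, 0, 10), 20),
                       rgb = matrix(sample(0:255, 60, TRUE), 20),
                       source = "drone")
  dir <- withr::local_tempdir()

  f <- file.path(dir, "a.csv")
  write_cloud(pc, f)
  back <- read_cloud(f)
  expect_equal(back$coords, pc$coords, ignore_attr = TRUE)
  expect_equal(back$intensity, pc$intensity, tolerance = 1e-6)

  # ascii and binary PLY round-trip within float32 precision
  for (bin in c(FALSE, TRUE)) {
    f <- file.path(dir, paste0("b", bin, ".ply"))
    write_cloud(pc, f, binary = bin)
    back <- read_cloud(f)
    expect_equal(back$coords, pc$coords, tolerance = 1e-6,
                 ignore_attr = TRUE)
    f2 <- file.path(dir, paste0("c", bin, ".ply"))
    write_cloud(rgbpc, f2, binary = bin)
    back2 <- read_cloud(f2)
    expect_equal(back2$rgb, rgbpc$rgb, ignore_attr = TRUE)
  }

  # LAS stores coordinates at 1 mm scale
  f <- file.path(dir, "d.las")
  write_cloud(pc, f)
  back <- read_cloud(f)
  expect_equal(back$coords, pc$coords, tolerance = 2e-3,
               ignore_attr = TRUE)
  expect_equal(back$intensity, pc$intensity, tolerance = 1e-3)
  f2 <- file.path(dir, "e.las")
  write_cloud(rgbpc, f2)
  expect_equal(read_cloud(f2)$rgb, rgbpc$rgb, ignore_attr = TRUE)

  expect_error(read_cloud(file.path(dir, "missing.las")), "not found")
  writeLines("x,q", file.path(dir, "bad.csv"))
  expect_error(read_cloud(file.path(dir, "bad.csv")), "missing coordinate")
})

test_that("sor_denoise drops isolated points and matches the brute-force oracle", {
  set.seed(42)
  dense <- matrix(runif(3000), 1000)
  pc <- point_cloud(rbind(dense, c(50, 50, 50)))
  out <- sor_denoise(pc, k = 8, std_ratio = 1.0)
  kept <- attr(out, "kept_idx")
  expect_false(1001 %in% kept)
  expect_gte(length(kept), 995)
  # order preserved and output is a subset of the input
  expect_true(all(diff(kept) > 0))
  expect_equal(out$coords, pc$coords[kept, ], ignore_attr = TRUE)

  # uniform grid with a forgiving ratio is untouched
  grid <- as.matrix(expand.grid(1:5, 1:5, 1:5))
  expect_equal(npoints(sor_denoise(point_cloud(grid), k = 6,
                                   std_ratio = 3)), 125)

  # two outliers symmetric about the blob: both removed, and the kept set
  # agrees exactly with the O(n^2) oracle
  set.seed(7)
  blob <- matrix(rnorm(600, sd = 0.1), 200)
  pts <- rbind(blob, c(5, 0, 0), c(-5, 0, 0))
  out <- sor_denoise(point_cloud(pts), k = 8, std_ratio = 1.0)
  expect_identical(attr(out, "kept_idx"),
                   oracle_sor_keep(pts, 8, 1.0))
  expect_false(any(c(201, 202) %in% attr(out, "kept_idx")))

  expect_error(sor_denoise(point_cloud(diag(3)), k = 8), "more than k")
})

test_that("cloth ground filter separates terrain from canopy", {
  set.seed(3)
  plane <- cbind(runif(4000, 0, 10), runif(4000, 0, 10),
                 rnorm(4000, 0, 0.004))
  cyl <- make_cylinder(800, 0.5, 1.5, cx = 5, cy = 5, z0 = 0.5)
  pc <- point_cloud(rbind(plane, cyl))
  gf <- csf_ground_filter(pc)
  truth <- c(rep("g", 4000), rep("a", 800))
  expect_gte(mean(truth[gf$ground_idx] == "g"), 0.99)
  expect_gte(mean(truth[gf$aboveground_idx] == "a"), 0.99)
  # the split is a partition of the input
  expect_setequal(c(gf$ground_idx, gf$aboveground_idx), seq_len(4800))

  # entirely flat cloud: nothing is aboveground
  flat <- point_cloud(cbind(runif(2000, 0, 5), runif(2000, 0, 5), 0))
  expect_equal(npoints(csf_ground_filter(flat)$aboveground), 0)

  expect_error(csf_ground_filter(point_cloud(cbind(0.01 * runif(100),
                                                   0.01 * runif(100),
                                                   runif(100)))),
               "extent")
})

test_that("CHM heights are terrain-corrected and reported in cm", {
  set.seed(4)
  g <- point_cloud(cbind(runif(3000, 0, 4), runif(3000, 0, 4), 0))
  a <- point_cloud(rbind(c(2, 2, 2.5), c(0.1, 0.1, 1)))
  chm <- build_chm(g, a, cell_size = 0.5)
  expect_equal(max(chm$heights, na.rm = TRUE), 250, tolerance = 1e-6)
  expect_true(any(is.na(chm$heights)))   # cells with no canopy: no-data

  # sloped terrain: a canopy sheet 2 m above a 10% ramp reads 200 cm
  gx <- runif(5000, 0, 8); gy <- runif(5000, 0, 8)
  gs <- point_cloud(cbind(gx, gy, 0.1 * gx))
  ax <- runif(2000, 1, 7); ay <- runif(2000, 1, 7)
  as_ <- point_cloud(cbind(ax, ay, 0.1 * ax + 2))
  chm <- build_chm(gs, as_, cell_size = 0.1)
  h <- chm$heights[!is.na(chm$heights)]
  expect_lt(max(abs(h - 200)), 0.1 * 10 * 2)  # 2x cell interpolation tol

  expect_error(build_chm(g, point_cloud(rbind(c(50, 50, 1)))), "overlap")
})

test_that("CHM is invariant to adding a planar ramp to ground and canopy", {
  set.seed(5)
  gx <- runif(4000, 0, 6); gy <- runif(4000, 0, 6)
  ax <- runif(1500, 1, 5); ay <- runif(1500, 1, 5)
  az <- 1.5 + 0.3 * sin(ax)
  flat <- build_chm(point_cloud(cbind(gx, gy, 0)),
                    point_cloud(cbind(ax, ay, az)), 0.1)
  ramp <- function(x, y) 0.08 * x + 0.05 * y
  tilted <- build_chm(point_cloud(cbind(gx, gy, ramp(gx, gy))),
                      point_cloud(cbind(ax, ay, az + ramp(ax, ay))), 0.1)
  both <- !is.na(flat$heights) & !is.na(tilted$heights)
  dif <- abs(flat$heights[both] - tilted$heights[both])
  expect_lt(stats::quantile(dif, 0.99), 2 * 0.1 * 100 * 0.1)
})
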