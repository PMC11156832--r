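test_that("vessel tree generation is deterministic and minimal trees work", {
  t1 <- build_vessel_tree(seed = 7, n_branch_levels = 4)
  t2 <- build_vessel_tree(seed = 7, n_branch_levels = 4)
  expect_identical(t1$segments, t2$segments)

  minimal <- build_vessel_tree(seed = 1, n_branch_levels = 1)
  expect_true(all(minimal$segments$caliber_class == "large"))
  expect_true(all(minimal$segments$radius == minimal$segments$radius[1]))

  expect_error(build_vessel_tree(seed = 1, n_branch_levels = 0),
               "positive")
})

test_that("every child segment starts on its parent (point-to-segment oracle)", {
  tree <- build_vessel_tree(seed = 7, n_branch_levels = 4)
  s <- tree$segments
  # brute-force point-to-segment distance, independent of package internals
  seg_dist <- function(p, a, b) {
    ab <- b - a
    tt <- sum((p - a) * ab) / sum(ab^2)
    tt <- min(max(tt, 0), 1)
    sqrt(sum((p - (a + tt * ab))^2))
  }
  for (i in which(s$parent > 0)) {
    par <- s[s$parent[i], ]
    d <- seg_dist(c(s$x0[i], s$y0[i], s$z0[i]),
                  c(par$x0, par$y0, par$z0), c(par$x1, par$y1, par$z1))
    expect_lt(d, 1e-9)
  }
})

test_that("trees span all caliber classes with approximately halving radii", {
  tree <- build_vessel_tree(seed = 2, n_branch_levels = 5)
  expect_setequal(unique(tree$segments$caliber_class),
                  c("large", "medium", "small", "perforator"))
  by_level <- tapply(tree$segments$radius, tree$segments$level, unique)
  ratios <- unlist(by_level[-1]) / unlist(by_level[-length(by_level)])
  expect_true(all(ratios > 0.4 & ratios < 0.6))
})

test_that("rasterize puts exact intensities inside and outside tubes", {
  # single thick straight tube along z through the grid centre
  tree <- build_vessel_tree(seed = 1, n_branch_levels = 1, trunk_radius = 2)
  seg <- tree$segments[1, ]
  spec <- phantom_spec(grid_shape = c(48, 48, 48),
                       voxel_size = c(0.4, 0.4, 0.4), noise_sigma = 0)
  vol <- rasterize(tree, spec)
  # a voxel at the segment midpoint is deep inside the tube
  mid <- (c(seg$x0, seg$y0, seg$z0) + c(seg$x1, seg$y1, seg$z1)) / 2
  idx <- round(world_to_voxel(vol, matrix(mid, 1))) + 1
  expect_identical(vol$data[idx[1], idx[2], idx[3]], 300)
  # far corner is pure background
  expect_identical(vol$data[1, 1, 1], 60)

  # zero contrast collapses to a constant volume
  spec0 <- phantom_spec(grid_shape = c(24, 24, 24), voxel_size = rep(0.4, 3),
                        vessel_intensity = 60 + 1e-9,
                        background_intensity = 60)
  vol0 <- rasterize(tree, spec0)
  expect_lt(diff(range(vol0$data)), 1e-8)
})

test_that("partial-volume fractions match a dense independent subsampling", {
  # straight tube of radius 1 mm along z at 0.2 mm isotropic voxels; the
  # oracle computes per-(x,y) in-tube area fractions by dense 2-D sampling
  tree <- build_vessel_tree(seed = 1, n_branch_levels = 1, trunk_radius = 1,
                            extent = c(8, 8, 8))
  seg <- tree$segments[1, ]
  spec <- phantom_spec(grid_shape = c(40, 40, 40), voxel_size = rep(0.2, 3))
  vol <- rasterize(tree, spec)
  frac <- (vol$data - 60) / (300 - 60)
  n_pkg <- sum(frac[, , 20] >= 0.5)

  a <- c(seg$x0, seg$y0, seg$z0); b <- c(seg$x1, seg$y1, seg$z1)
  dirv <- (b - a) / sqrt(sum((b - a)^2))
  z_mid <- voxel_to_world(vol, matrix(c(0, 0, 19), 1))[3]
  # axis point at this z (tube is nearly axial)
  tpar <- (z_mid - a[3]) / dirv[3]
  cxy <- (a + tpar * dirv)[1:2]
  ss <- (seq_len(20) - 0.5) / 20 - 0.5
  n_oracle <- 0L
  for (i in 1:40) for (j in 1:40) {
    ctr <- voxel_to_world(vol, matrix(c(i - 1, j - 1, 19), 1))[1:2]
    pts_x <- ctr[1] + ss * 0.2
    pts_y <- ctr[2] + ss * 0.2
    d2 <- outer((pts_x - cxy[1])^2, (pts_y - cxy[2])^2, "+")
    if (mean(d2 <= 1) >= 0.5) n_oracle <- n_oracle + 1L
  }
  expect_lt(abs(n_pkg - n_oracle) / n_oracle, 0.01)
})

test_that("sub-voxel tubes trigger a partial-volume warning", {
  tree <- build_vessel_tree(seed = 1, n_branch_levels = 1, trunk_radius = 0.1)
  spec <- phantom_spec(grid_shape = c(16, 16, 16), voxel_size = rep(0.4, 3))
  expect_warning(rasterize(tree, spec), "partial-volume")
})

test_that("add_noise is seeded, unbiased and independent across seeds", {
  vol <- volume3d(array(100, c(58, 58, 60)), rep(0.2, 3))
  expect_identical(add_noise(vol, 0, 1)$data, vol$data)
  n1 <- add_noise(vol, 10, 5)
  n1b <- add_noise(vol, 10, 5)
  expect_identical(n1$data, n1b$data)
  # moment check at ~200k voxels
  expect_lt(abs(sd(n1$data - vol$data) - 10) / 10, 0.01)
  n2 <- add_noise(vol, 10, 6)
  expect_gt(sd(n1$data - n2$data), 0)
  expect_error(add_noise(vol, -1, 1), ">= 0")
})

test_that("acquisition pairs have the difference-method variance structure", {
  clean <- volume3d(array(100, c(30, 30, 30)), rep(0.3, 3))
  # identity misalignment, zero noise: bit-identical volumes
  p0 <- make_pair(clean, 0, 1, 2)
  expect_identical(p0$volume_a$data, p0$volume_b$data)
  # sd(A - B) converges to sqrt(2) * sigma
  p1 <- make_pair(clean, 8, 3, 4)
  expect_lt(abs(sd(p1$volume_a$data - p1$volume_b$data) - sqrt(2) * 8) /
              (sqrt(2) * 8), 0.01)
  expect_error(make_pair(clean, 8, 5, 5), "differ")
})

test_that("a one-voxel translation shifts the B acquisition exactly", {
  set.seed(4)
  clean <- volume3d(array(runif(27000), c(30, 30, 30)), rep(0.3, 3))
  mis <- rigid_transform(c(0, 0, 0), c(0.3, 0, 0)) # one voxel along x
  p <- make_pair(clean, 0, 1, 2, misalignment = mis)
  expect_lt(max(abs(p$volume_b$data[5:25, 5:25, 5:25] -
                      clean$data[4:24, 5:25, 5:25])), 1e-9)
})

test_that("DSA-like projection reduces to the plain MIP when unperturbed", {
  vol <- reg_volume()
  plain <- mip(vol, "axial")
  dsa <- project_dsa_like(vol, "axial", rotation_deg = 0, blur_sigma_px = 0,
                          intensity_gamma = 1, noise_sigma = 0)
  rng <- range(plain$data)
  expect_lt(max(abs(dsa$data - (plain$data - rng[1]) / diff(rng))), 1e-12)
})

test_that("gamma remapping preserves pixel ranks and 180-degree rotation is involutive", {
  vol <- reg_volume()
  g1 <- project_dsa_like(vol, "axial", intensity_gamma = 1,
                         noise_sigma = 0.01, seed = 3)
  g2 <- project_dsa_like(vol, "axial", intensity_gamma = 2,
                         noise_sigma = 0.01, seed = 3)
  expect_gt(cor(rank(g1$data), rank(g2$data)), 0.9999)

  r1 <- project_dsa_like(vol, "axial", rotation_deg = 180)
  r2 <- project_dsa_like(volume3d(r1$data[, , drop = FALSE] |>
                                    array(c(dim(r1$data), 1)),
                                  c(r1$pixel_size, 1)),
                         "axial", rotation_deg = 180)
  r0 <- project_dsa_like(vol, "axial", rotation_deg = 0)
  interior <- 5:(nrow(r0$data) - 5)
  expect_lt(max(abs(r2$data[interior, interior] -
                      r0$data[interior, interior])), 1e-6)
})

test_that("the default tree rasterized at 0.2 mm covers calibers 0.3-4 mm", {
  tree <- build_vessel_tree(seed = 1)
  spec <- phantom_spec(grid_shape = c(96, 96, 96),
                       voxel_size = c(0.2, 0.2, 0.2))
  vol <- suppressWarnings(rasterize(tree, spec))
  mask <- (vol$data - 60) / 240 >= 0.5
  # brute-force caliber measurement: cross-section width of the trunk and
  # detectability of the thinnest vessels
  expect_gte(max(tree$segments$radius) * 2, 4)   # 4 mm trunk by design
  trunk <- tree$segments[1, ]
  mid <- (c(trunk$x0, trunk$y0, trunk$z0) + c(trunk$x1, trunk$y1, trunk$z1)) / 2
  k <- round(world_to_voxel(vol, matrix(mid, 1)))[3] + 1
  sl <- mask[, , k]
  widths <- range(which(rowSums(sl) > 0))
  expect_gte(diff(widths) * 0.2, 3.5) # trunk cross-section close to 4 mm
  expect_lte(min(tree$segments$radius) * 2, 0.3) # perforators at/below 0.3 mm
})

test_that("vessel trees serialize to JSON and back", {
  tree <- build_vessel_tree(seed = 12, n_branch_levels = 3)
  f <- tempfile(fileext = ".json")
  tree_to_json(tree, f)
  back <- tree_from_json(f)
  expect_equal(back$segments$radius, tree$segments$radius)
  expect_lt(max(abs(as.matrix(back$segments[, 1:6]) -
                      as.matrix(tree$segments[, 1:6]))), 1e-9)
})

test_that("transform_tree moves segment end points rigidly", {
  tree <- build_vessel_tree(seed = 12, n_branch_levels = 3)
  tr <- rigid_transform(c(3, -2, 5), c(1, 2, -1))
  tt <- transform_tree(tree, tr)
  back <- transform_tree(tt, invert(tr))
  expect_lt(max(abs(as.matrix(back$segments[, 1:6]) -
                      as.matrix(tree$segments[, 1:6]))), 1e-9)
  # lengths are preserved
  len <- function(s) sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2 + (s$z1 - s$z0)^2)
  expect_equal(len(tt$segments), len(tree$segments), tolerance = 1e-12)
})
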