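# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

fix_cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# mid-sized phantom used by registration tests: tree well inside the FOV so
# +-5 mm / 5 degree motions never clip vessels out of the field
reg_tree <- function() fix_cached("reg_tree",
  build_vessel_tree(seed = 7, n_branch_levels = 4, extent = c(12, 12, 12)))

reg_spec <- function() phantom_spec(grid_shape = c(60, 60, 60),
                                    voxel_size = c(0.4, 0.4, 0.4))

reg_volume <- function() fix_cached("reg_volume",
  suppressWarnings(rasterize(reg_tree(), reg_spec())))

# high-resolution MIP for similarity tests
mip_fixture <- function() fix_cached("mip_fixture", {
  spec <- phantom_spec(grid_shape = c(256, 256, 64),
                       voxel_size = c(0.2, 0.2, 0.3))
  tree <- build_vessel_tree(seed = 3, extent = c(48, 48, 17))
  mip(suppressWarnings(rasterize(tree, spec)), "axial")
})

# integer-pixel shift with background fill
shift_image <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(min(m), nr, nc)
  out[(1 + max(0, dr)):(nr + min(0, dr)), (1 + max(0, dc)):(nc + min(0, dc))] <-
    m[(1 - min(0, dr)):(nr - max(0, dr)), (1 - min(0, dc)):(nc - max(0, dc))]
  out
}

random_rigid <- function() {
  rigid_transform(stats::runif(3, -5, 5), stats::runif(3, -5, 5), c(0, 0, 0))
}

pose_errors <- function(est, truth) {
  c(angle = max(abs(transform_angles(est) - transform_angles(truth))),
    translation = max(abs(est$translation - truth$translation)))
}
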