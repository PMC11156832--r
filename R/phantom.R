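#' Digital vascular phantom
#'
#' The phantom emulates the structure a TOF-MRA quality analysis assumes:
#' bright tubular vessels of graded caliber on a suppressed background,
#' repeat acquisitions differing only by independent additive noise, several
#' voxel-size regimes, small rigid inter-acquisition misalignments, and a
#' geometrically perturbed 2-D projection standing in for DSA. Vessel
#' calibers span the intracranial taxonomy: large (carotid-siphon-like,
#' radius >= 1.4 mm), medium (0.7-1.4 mm), small (0.3-0.7 mm) and
#' perforator (< 0.3 mm).
#'
#' @name phantom
NULL

CALIBER_BREAKS <- c(large = 1.4, medium = 0.7, small = 0.3)

caliber_class_for_radius <- function(r) {
  ifelse(r >= CALIBER_BREAKS["large"], "large",
         ifelse(r >= CALIBER_BREAKS["medium"], "medium",
                ifelse(r >= CALIBER_BREAKS["small"], "small", "perforator")))
}

#' Acquisition / phantom geometry specification
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param voxel_size mm triple, e.g. `c(0.2, 0.2, 0.3)` for the finest
#'   7-T regime or `c(0.4, 0.4, 0.5)` for a clinical 3-T regime.
#' @param vessel_intensity,background_intensity arbitrary units; vessel must
#'   exceed background. Defaults (300 vs 60) put the default-noise CNR in the
#'   single digits, the range typical of in vivo TOF-MRA.
#' @param noise_sigma standard deviation of the additive acquisition noise.
#' @param seed integer controlling every stochastic step downstream.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         voxel_size = c(0.2, 0.2, 0.3),
                         vessel_intensity = 300,
                         background_intensity = 60,
                         noise_sigma = 10,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  abort_if(length(grid_shape) != 3L || any(grid_shape < 1L),
           "`grid_shape` must be 3 positive integers")
  abort_if(any(as.numeric(voxel_size) <= 0), "`voxel_size` must be positive")
  abort_if(!(vessel_intensity > background_intensity),
           "`vessel_intensity` must exceed `background_intensity`")
  abort_if(background_intensity < 0, "`background_intensity` must be >= 0")
  abort_if(noise_sigma < 0, "`noise_sigma` must be >= 0")
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 vessel_intensity = vessel_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a branching vessel tree
#'
#' Builds a piecewise-linear tree of tubes (hemispherical caps) whose radii
#' halve at each branching level, so that with `n_branch_levels >= 4` the
#' tree contains every caliber class from large trunk (radius 2 mm, i.e.
#' 4 mm diameter) down to perforators. Every child segment starts at its
#' parent's end point, so the tree is connected by construction. The
#' generator is deterministic for a fixed seed.
#'
#' @param seed integer RNG seed.
#' @param n_branch_levels number of branching generations (>= 1); the default
#'   5 spans calibers 4 mm down to 0.25 mm diameter.
#' @param extent length-3 bounding box (mm) centred on the origin that the
#'   tree is kept inside.
#' @param trunk_radius radius of the root segment in mm.
#' @return object of class `vessel_tree`: a data frame of segments
#'   (`x0,y0,z0,x1,y1,z1,radius,caliber_class,parent`) plus the seed.
#' @export
build_vessel_tree <- function(seed = 1L, n_branch_levels = 5L,
                              extent = c(18, 18, 18), trunk_radius = 2) {
  abort_if(!is.numeric(n_branch_levels) || n_branch_levels < 1,
           "`n_branch_levels` must be a positive integer")
  n_branch_levels <- as.integer(n_branch_levels)
  half <- as.numeric(extent) / 2
  clamp_box <- function(p) pmin(pmax(p, -half * 0.95), half * 0.95)

  segs <- with_seed(seed, {
    rows <- list()
    add_seg <- function(a, b, radius, level, parent) {
      rows[[length(rows) + 1L]] <<- data.frame(
        x0 = a[1], y0 = a[2], z0 = a[3], x1 = b[1], y1 = b[2], z1 = b[3],
        radius = radius, level = level, parent = parent)
      length(rows)
    }
    perp_frame <- function(dir) {
      up <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- up - sum(up * dir) * dir; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
              dir[3] * e1[1] - dir[1] * e1[3],
              dir[1] * e1[2] - dir[2] * e1[1])
      cbind(e1, e2)
    }
    bend <- function(dir, ang_deg, az) {
      fr <- perp_frame(dir)
      a <- ang_deg * pi / 180
      d <- cos(a) * dir + sin(a) * (cos(az) * fr[, 1] + sin(az) * fr[, 2])
      d / sqrt(sum(d^2))
    }
    # curved branch: polyline of `nsub` chained tubes with gentle kinks, so
    # the phantom is not rotationally ambiguous about any straight axis
    add_branch <- function(p0, dir, len, radius, level, parent, nsub = 2L,
                           kink = 12) {
      a <- p0
      pid <- parent
      for (s in seq_len(nsub)) {
        b <- clamp_box(a + dir * len / nsub)
        pid <- add_seg(a, b, radius, level, pid)
        a <- b
        dir <- bend(dir, stats::runif(1, 0.3, 1) * kink,
                    stats::runif(1, 0, 2 * pi))
      }
      list(end = a, dir = dir, id = pid)
    }
    trunk_dir <- c(0.2, -0.12, 1)
    trunk_dir <- trunk_dir / sqrt(sum(trunk_dir^2))
    p0 <- c(-half[1] * 0.2, half[2] * 0.15, -half[3] * 0.85)
    trunk <- add_branch(p0, trunk_dir, 0.75 * (2 * half[3]), trunk_radius,
                        1L, 0L, nsub = 3L, kink = 14)
    frontier <- list(trunk)
    for (lev in seq_len(n_branch_levels - 1L) + 1L) {
      radius <- trunk_radius * 0.5^(lev - 1)
      new_frontier <- list()
      for (br in frontier) {
        len <- stats::runif(1, 0.5, 0.7) *
          sqrt(sum((br$end - p0)^2 + 1e-9)) * 0.6 + 2
        az0 <- stats::runif(1, 0, 2 * pi)
        for (child in 1:2) {
          # opposite-ish azimuths with jitter and varied branching angles
          ang <- stats::runif(1, 20, 55)
          az <- az0 + (child - 1) * pi + stats::runif(1, -0.6, 0.6)
          d <- bend(br$dir, ang, az)
          new_frontier[[length(new_frontier) + 1L]] <-
            add_branch(br$end, d, len, radius, lev, br$id, nsub = 2L,
                       kink = 10)
        }
      }
      frontier <- new_frontier
    }
    do.call(rbind, rows)
  })
  segs$caliber_class <- caliber_class_for_radius(segs$radius)
  structure(list(segments = segs, seed = as.integer(seed)),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d segments, radii %.3g-%.3g mm (%s)\n",
              nrow(x$segments), min(x$segments$radius), max(x$segments$radius),
              paste(unique(x$segments$caliber_class), collapse = ", ")))
  invisible(x)
}

#' Rigidly transform a vessel tree
#'
#' Applies a [rigid_transform()] to every segment end point, yielding the
#' same continuous vascular object in a new pose. Rasterizing the
#' transformed tree emulates re-acquiring a moved subject exactly — with
#' partial-volume sampling but no interpolation smoothing, unlike
#' resampling an already-discretized volume.
#'
#' @param tree a [build_vessel_tree()] result.
#' @param transform a [rigid_transform()].
#' @return a `vessel_tree` in the new pose.
#' @export
transform_tree <- function(tree, transform) {
  s <- tree$segments
  a <- apply_transform(transform, as.matrix(s[, c("x0", "y0", "z0")]))
  b <- apply_transform(transform, as.matrix(s[, c("x1", "y1", "z1")]))
  s[, c("x0", "y0", "z0")] <- a
  s[, c("x1", "y1", "z1")] <- b
  structure(list(segments = s, seed = tree$seed), class = "vessel_tree")
}

#' Serialize / deserialize a vessel tree as JSON
#' @param tree a [build_vessel_tree()] result.
#' @param path file path.
#' @export
tree_to_json <- function(tree, path) {
  jsonlite::write_json(list(seed = tree$seed, segments = tree$segments),
                       path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- as.data.frame(j$segments)
  structure(list(segments = segs, seed = as.integer(j$seed)),
            class = "vessel_tree")
}

# distance from points (n x 3) to one segment, with hemispherical caps
point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(rowSums(sweep(pts, 2, a)^2)))
  t <- (sweep(pts, 2, a) %*% ab) / len2
  t <- pmin(pmax(t, 0), 1)
  proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2], a[3] + t * ab[3])
  sqrt(rowSums((pts - proj)^2))
}

#' Rasterize a vessel tree onto a voxel grid
#'
#' Voxels fully inside a tube receive `vessel_intensity`, voxels fully
#' outside receive `background_intensity`, and boundary voxels receive a
#' partial-volume blend proportional to their in-tube fraction, estimated by
#' subdividing the voxel into `subsample^3` points (default 8^3 = 512-fold,
#' well beyond the 8-fold minimum needed for a stable fraction). No noise is
#' added here. Tubes thinner than half the largest voxel dimension are
#' permitted but trigger a partial-volume warning.
#'
#' @param tree a [build_vessel_tree()] result.
#' @param spec a [phantom_spec()].
#' @param subsample per-axis subdivision for boundary voxels (>= 2).
#' @return a noise-free [volume3d()].
#' @export
rasterize <- function(tree, spec, subsample = 8L) {
  abort_if(nrow(tree$segments) == 0L, "`tree` has no segments")
  abort_if(subsample < 2L, "`subsample` must be >= 2")
  if (any(tree$segments$radius < max(spec$voxel_size) / 2)) {
    warning("tube radius below half the largest voxel dimension: ",
            "partial-volume effects dominate sub-voxel vessels",
            call. = FALSE)
  }
  dims <- spec$grid_shape
  vol <- volume3d(array(0, dims), spec$voxel_size)
  vs <- spec$voxel_size
  rv <- sqrt(sum((vs / 2)^2)) # voxel half-diagonal
  frac <- array(0, dims)

  # subvoxel offsets (voxel units, centred), shared across segments
  s <- (seq_len(subsample) - 0.5) / subsample - 0.5
  offs <- as.matrix(expand.grid(s * vs[1], s * vs[2], s * vs[3]))

  origin <- vol$affine[1:3, 4]
  for (i in seq_len(nrow(tree$segments))) {
    seg <- tree$segments[i, ]
    a <- c(seg$x0, seg$y0, seg$z0); b <- c(seg$x1, seg$y1, seg$z1)
    r <- seg$radius
    lo <- pmin(a, b) - r - rv; hi <- pmax(a, b) + r + rv
    ilo <- pmax(floor((lo - origin) / vs), 0)
    ihi <- pmin(ceiling((hi - origin) / vs), dims - 1)
    if (any(ilo > ihi)) next
    idx <- as.matrix(expand.grid(ilo[1]:ihi[1], ilo[2]:ihi[2], ilo[3]:ihi[3]))
    ctr <- sweep(idx, 2, vs, "*")
    ctr <- sweep(ctr, 2, origin, "+")
    d <- point_segment_distance(ctr, a, b)
    inside <- d <= r - rv
    boundary <- !inside & d < r + rv
    lin <- 1L + idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3])
    if (any(inside)) frac[lin[inside]] <- pmax(frac[lin[inside]], 1)
    if (any(boundary)) {
      bc <- ctr[boundary, , drop = FALSE]
      nb <- nrow(bc)
      # all subsample points for all boundary voxels of this segment at once
      pts <- bc[rep(seq_len(nb), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nb), , drop = FALSE]
      din <- point_segment_distance(pts, a, b) <= r
      f <- colMeans(matrix(din, nrow = nrow(offs)))
      frac[lin[boundary]] <- pmax(frac[lin[boundary]], f)
    }
  }
  vol$data <- spec$background_intensity +
    (spec$vessel_intensity - spec$background_intensity) * frac
  vol
}

#' Add independent Gaussian acquisition noise
#'
#' Zero-mean i.i.d. Gaussian noise of standard deviation `sigma` is added to
#' every voxel; the operation is deterministic for a fixed seed and is a
#' no-op for `sigma = 0`. Gaussian (rather than Rician) noise keeps the
#' difference-method SNR oracle closed-form; see the methods vignette for
#' the resulting limitation.
#'
#' @param volume a [volume3d()].
#' @param sigma noise standard deviation (>= 0), image units.
#' @param seed integer seed.
#' @export
add_noise <- function(volume, sigma, seed = 1L) {
  abort_if(!is.numeric(sigma) || sigma < 0, "`sigma` must be >= 0")
  if (sigma == 0) return(volume)
  volume$data <- volume$data +
    with_seed(seed, array(stats::rnorm(length(volume$data), 0, sigma),
                          dim(volume$data)))
  volume
}

#' Simulate a repeat-acquisition pair
#'
#' Produces the (A, B) couple the difference method requires: two
#' acquisitions of the same object differing only by independent noise
#' realizations, optionally with a small rigid misalignment of B relative to
#' A (as when the subject moves between back-to-back scans).
#' `volume_b` is the clean volume pushed through `misalignment` (linear
#' interpolation) plus noise seeded by `seed_b`.
#'
#' @param clean noise-free [volume3d()].
#' @param sigma noise standard deviation applied to both acquisitions.
#' @param seed_a,seed_b distinct integer seeds (equal seeds would violate
#'   noise independence and are rejected).
#' @param misalignment [rigid_transform()] mapping A-space content into
#'   B-space; identity by default.
#' @return object of class `acquisition_pair` with `volume_a`, `volume_b`,
#'   `true_misalignment`.
#' @export
make_pair <- function(clean, sigma, seed_a, seed_b,
                      misalignment = identity_transform()) {
  abort_if(seed_a == seed_b,
           "`seed_a` and `seed_b` must differ (noise independence)")
  is_ident <- max(abs(transform_matrix(misalignment) - diag(4))) < 1e-12
  base_b <- if (is_ident) clean else
    resample_volume(clean, misalignment, clean, interpolation = "linear")
  structure(list(volume_a = add_noise(clean, sigma, seed_a),
                 volume_b = add_noise(base_b, sigma, seed_b),
                 true_misalignment = misalignment),
            class = "acquisition_pair")
}

#' @export
print.acquisition_pair <- function(x, ...) {
  cat("<acquisition_pair>\n  A: "); print(x$volume_a)
  cat("  B: "); print(x$volume_b)
  invisible(x)
}

#' Render a DSA-like 2-D projection of a volume
#'
#' Produces a "same vessels, different modality rendering" partner image for
#' cross-modality similarity testing: maximum-intensity projection along an
#' anatomical axis, in-plane rotation, Gaussian blur, intensity
#' normalization to [0, 1], mild additive noise, then gamma remapping.
#'
#' @param volume a [volume3d()].
#' @param axis projection axis: `"axial"`, `"coronal"` or `"sagittal"`.
#' @param rotation_deg in-plane rotation in degrees.
#' @param blur_sigma_px Gaussian blur standard deviation in pixels (>= 0).
#' @param intensity_gamma gamma exponent (> 0) applied to the normalized
#'   intensities.
#' @param noise_sigma additive noise SD on the [0, 1] scale.
#' @param seed integer seed for the noise.
#' @return an [image2d()].
#' @export
project_dsa_like <- function(volume, axis = "axial", rotation_deg = 0,
                             blur_sigma_px = 0, intensity_gamma = 1,
                             noise_sigma = 0, seed = 1L) {
  abort_if(blur_sigma_px < 0, "`blur_sigma_px` must be >= 0")
  abort_if(intensity_gamma <= 0, "`intensity_gamma` must be > 0")
  img <- mip(volume, axis)
  m <- img$data
  if (rotation_deg != 0) m <- rotate_image(m, rotation_deg)
  if (blur_sigma_px > 0) m <- gaussian_smooth(m, blur_sigma_px)
  rng <- range(m)
  m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  if (noise_sigma > 0) {
    m <- m + with_seed(seed, matrix(stats::rnorm(length(m), 0, noise_sigma),
                                    nrow(m)))
    m <- pmin(pmax(m, 0), 1)
  }
  image2d(m^intensity_gamma, img$pixel_size)
}

# in-plane rotation about the image centre, bilinear interpolation,
# outside-of-field pixels set to 0
rotate_image <- function(m, deg) {
  th <- deg * pi / 180
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  dr <- g$r - cr; dc <- g$c - cc
  # inverse mapping
  sr <- cos(th) * dr + sin(th) * dc + cr
  sc <- -sin(th) * dr + cos(th) * dc + cc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r))
    v[ok] <- m[cbind(r[ok], c[ok])]
    v
  }
  out <- get(r0, c0) * (1 - fr) * (1 - fc) + get(r0 + 1, c0) * fr * (1 - fc) +
    get(r0, c0 + 1) * (1 - fr) * fc + get(r0 + 1, c0 + 1) * fr * fc
  matrix(out, nr, nc)
}
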