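#' Resample a volume through a rigid transform onto a reference grid
#'
#' For every voxel centre of `reference`, the world point is pulled back
#' through `transform^-1` and `source` is sampled there. `transform` is the
#' transform mapping `source`-space content into `reference` space (the
#' convention [estimate_rigid()] returns). Out-of-field voxels are set to 0.
#'
#' With `interpolation = "nearest"` every output value is an exact member of
#' the source's value set — no new values are created — which is what label
#' volumes and final ROI propagation require to avoid interpolation
#' smoothing. Registration-internal resampling uses `"linear"`.
#'
#' @param source,reference [volume3d()] objects.
#' @param transform a [rigid_transform()].
#' @param interpolation `"linear"` or `"nearest"`.
#' @return a [volume3d()] on the reference grid.
#' @export
resample_volume <- function(source, transform, reference,
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  dims <- dim(reference$data)
  idx <- as.matrix(expand.grid(0:(dims[1] - 1), 0:(dims[2] - 1),
                               0:(dims[3] - 1)))
  # voxel(ref) -> world -> inverse transform -> voxel(src), one 4x4 product
  M <- solve(source$affine) %*% transform_matrix(invert(transform)) %*%
    reference$affine
  v <- cbind(idx, 1) %*% t(M)
  vals <- interp_volume(source$data, v[, 1], v[, 2], v[, 3], interpolation)
  out <- reference
  out$data <- array(vals, dims)
  out
}

#' @rdname resample_volume
#' @export
resample_nn <- function(source, transform, reference) {
  resample_volume(source, transform, reference, interpolation = "nearest")
}

# sample a 3-D array at continuous 0-based voxel coordinates; out-of-field
# points yield 0. Linear-index gathers keep this fast enough for use inside
# the registration metric loop.
interp_volume <- function(a, x, y, z, interpolation = "linear") {
  d <- dim(a)
  eps <- 1e-7 # tolerate float dust at the field-of-view boundary
  inside <- x >= -eps & x <= d[1] - 1 + eps & y >= -eps & y <= d[2] - 1 + eps &
    z >= -eps & z <= d[3] - 1 + eps
  if (interpolation == "nearest") {
    i <- pmin(pmax(round(x), 0), d[1] - 1)
    j <- pmin(pmax(round(y), 0), d[2] - 1)
    k <- pmin(pmax(round(z), 0), d[3] - 1)
    v <- a[1 + i + d[1] * (j + d[2] * k)]
    v[!inside] <- 0
    return(v)
  }
  x0 <- pmin(pmax(floor(x), 0), d[1] - 2); fx <- pmin(pmax(x - x0, 0), 1)
  y0 <- pmin(pmax(floor(y), 0), d[2] - 2); fy <- pmin(pmax(y - y0, 0), 1)
  z0 <- pmin(pmax(floor(z), 0), d[3] - 2); fz <- pmin(pmax(z - z0, 0), 1)
  base <- 1 + x0 + d[1] * (y0 + d[2] * z0)
  dy <- d[1]; dz <- d[1] * d[2]
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  v <- (a[base] * gx + a[base + 1] * fx) * gy * gz +
    (a[base + dy] * gx + a[base + dy + 1] * fx) * fy * gz +
    (a[base + dz] * gx + a[base + dz + 1] * fx) * gy * fz +
    (a[base + dy + dz] * gx + a[base + dy + dz + 1] * fx) * fy * fz
  v[!inside] <- 0
  v
}

# block-mean downsampling by an integer factor per axis; the affine is
# shifted so new voxel centres sit at the centre of each block
downsample_volume <- function(vol, factor) {
  if (factor == 1L) return(vol)
  d <- dim(vol$data)
  nd <- d %/% factor
  a <- vol$data[1:(nd[1] * factor), 1:(nd[2] * factor), 1:(nd[3] * factor)]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  small <- apply(a, c(2, 4, 6), mean)
  aff <- vol$affine
  shift <- aff[1:3, 1:3] %*% rep((factor - 1) / 2, 3)
  aff[1:3, 4] <- aff[1:3, 4] + shift
  aff[1:3, 1:3] <- aff[1:3, 1:3] * factor
  volume3d(small, vol$voxel_size * factor, aff)
}

# mutual information from a 32-bin joint histogram with linear
# partial-volume weighting of the (continuously valued) moving samples.
# `fixed_bins` are precomputed 0-based bins of the fixed image (they do not
# change while the pose is optimized).
mutual_information <- function(fixed_bins, moving_vals, m_range,
                               nbins = 32L) {
  mb_cont <- pmin(pmax((moving_vals - m_range[1]) / diff(m_range) * nbins
                       - 0.5, 0), nbins - 1)
  mb0 <- floor(mb_cont)
  w1 <- mb_cont - mb0
  mb1 <- pmin(mb0 + 1, nbins - 1)
  idx <- c(fixed_bins * nbins + mb0 + 1, fixed_bins * nbins + mb1 + 1)
  t0 <- rowsum(c(1 - w1, w1), idx)
  h <- numeric(nbins * nbins)
  h[as.integer(rownames(t0))] <- t0
  p <- h / sum(h)
  pj <- matrix(p, nbins, nbins, byrow = TRUE) # row = fixed bin
  pf <- rowSums(pj); pm <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (pf[row(pj)[nz]] * pm[col(pj)[nz]])))
}

# 0-based histogram bins of a vector over a fixed range
intensity_bins <- function(v, rng, nbins = 32L) {
  pmin(pmax(floor((v - rng[1]) / diff(rng) * nbins), 0), nbins - 1)
}

# cyclic coordinate descent with Brent line searches and shrinking
# brackets; robust on the long monotone slopes where a simplex stalls
cyclic_brent <- function(f, par, widths, cycles = 5L, shrink = 0.5) {
  best <- f(par)
  for (cy in seq_len(cycles)) {
    for (i in seq_along(par)) {
      g <- function(v) {
        p <- par; p[i] <- v; f(p)
      }
      o <- stats::optimize(g, c(par[i] - widths[i], par[i] + widths[i]),
                           tol = max(widths[i] * 1e-3, 1e-6))
      if (o$objective < best) {
        par[i] <- o$minimum
        best <- o$objective
      }
    }
    widths <- widths * shrink
  }
  list(par = par, value = best)
}

# intensity-weighted centroid (mm) of a volume above its background floor
volume_centroid <- function(vol) {
  w <- as.vector(vol$data) - min(vol$data)
  d <- dim(vol$data)
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  x <- voxel_to_world(vol, idx)
  colSums(x * w) / sum(w)
}

# separable 3-D Gaussian blur with edge-clamp padding (voxel units)
blur3d <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  rad <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-rad:rad)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  for (ax in 1:3) {
    n <- dim(a)[ax]
    acc <- array(0, dim(a))
    for (t in -rad:rad) {
      sel <- pmin(pmax(seq_len(n) + t, 1L), n)
      acc <- acc + k[t + rad + 1L] *
        switch(ax, a[sel, , , drop = FALSE], a[, sel, , drop = FALSE],
               a[, , sel, drop = FALSE])
    }
    a <- acc
  }
  a
}

#' Estimate a rigid transform by multiscale mutual-information registration
#'
#' Coarse-to-fine rigid registration of `moving` onto `fixed` over the 6
#' pose parameters (3 Euler angles in degrees, 3 translations in mm,
#' rotation centred on the fixed volume's world centre). The final stage
#' maximizes the mutual information of a 32-bin joint histogram with linear
#' partial-volume weighting on the raw volumes; the earlier capture stages
#' run on Gaussian-blurred, block-averaged copies (scale space) and use
#' intensity correlation, whose basin around the true pose is wide and
#' smooth where a sparse thin-vessel histogram is not. Each stage combines
#' a deterministic rotation-grid scan (capture only), cyclic Brent line
#' searches with shrinking brackets, and a Nelder-Mead simplex for
#' parameter coupling. Translation is initialized from the intensity
#' centroids. Registration-internal image resampling is linear; only final
#' label resampling elsewhere is nearest-neighbour.
#'
#' @param moving,fixed [volume3d()] objects with overlapping fields of view.
#' @param n_levels number of stages (1 = raw-volume mutual-information
#'   refinement only, 3 = full capture + refine + precision schedule).
#' @param init optional initial [rigid_transform()]; by default translation
#'   starts at the centroid difference.
#' @param max_iter simplex evaluation budget per stage.
#' @return the [rigid_transform()] mapping `moving` into `fixed` space, with
#'   attributes `metric` (final mutual information), `converged` (logical)
#'   and `diagnostics` (per-stage metric values). Non-convergence is flagged
#'   in the returned object, never silently ignored.
#' @export
estimate_rigid <- function(moving, fixed, n_levels = 3L, init = NULL,
                           max_iter = 1200L) {
  abort_if(n_levels < 1L, "`n_levels` must be >= 1")
  ctr <- as.numeric(voxel_to_world(fixed, matrix((dim(fixed$data) - 1) / 2, 1)))
  if (is.null(init)) {
    # translation capture from intensity centroids (rotation starts at 0)
    t0 <- volume_centroid(fixed) - volume_centroid(moving)
    init <- rigid_transform(c(0, 0, 0), t0, ctr)
  }
  par <- c(transform_angles(init), init$translation)
  f_range <- range(fixed$data) + c(0, 1e-9)
  m_range <- range(moving$data) + c(0, 1e-9)
  diagnostics <- numeric(0)
  conv_ok <- TRUE
  vox <- max(fixed$voxel_size)
  schedule <- list(
    list(factor = 2L, blur = 1.5, metric = "ncc", role = "capture"),
    list(factor = 1L, blur = 0.7, metric = "ncc", role = "refine"),
    list(factor = 1L, blur = 0.0, metric = "mi", role = "precision"))
  schedule <- schedule[seq(max(1L, 4L - n_levels), 3L)]
  n_samples_max <- 40000L
  for (st in schedule) {
    fx <- downsample_volume(fixed, st$factor)
    mv <- downsample_volume(moving, st$factor)
    if (st$blur > 0) {
      fx$data <- blur3d(fx$data, st$blur)
      mv$data <- blur3d(mv$data, st$blur)
    }
    dims <- dim(fx$data)
    idx <- as.matrix(expand.grid(0:(dims[1] - 1), 0:(dims[2] - 1),
                                 0:(dims[3] - 1)))
    fvals <- as.vector(fx$data)
    if (nrow(idx) > n_samples_max) {
      # foreground-prioritized deterministic subsample: vessel and boundary
      # voxels carry essentially all the pose information, and dropping any
      # of them makes the metric ripple as the sampled subset shifts with
      # the pose; background is represented by a sparse uniform stride
      fg <- which(abs(fvals - stats::median(fvals)) > 0.01 * diff(f_range))
      cap_fg <- (n_samples_max * 3L) %/% 4L
      if (length(fg) > cap_fg) {
        fg <- fg[seq(1L, length(fg), by = ceiling(length(fg) / cap_fg))]
      }
      bg <- setdiff(seq_along(fvals), fg)
      n_bg <- min(length(bg), max(n_samples_max - length(fg),
                                  n_samples_max %/% 4L))
      bg <- bg[unique(as.integer(seq(1L, length(bg), length.out = n_bg)))]
      sel <- sort(c(fg, bg))
      idx <- idx[sel, , drop = FALSE]
      fvals <- fvals[sel]
    }
    idx_h <- cbind(idx, 1)
    fbins <- intensity_bins(fvals, f_range)
    A_pre <- solve(mv$affine)
    A_ref <- fx$affine
    moving_at <- function(p) {
      tr <- rigid_transform(p[1:3], p[4:6], ctr)
      M <- A_pre %*% transform_matrix(invert(tr)) %*% A_ref
      v <- idx_h %*% t(M)
      # out-of-field samples keep their zero fill, penalizing poses that
      # rotate content out of the field of view
      interp_volume(mv$data, v[, 1], v[, 2], v[, 3], "linear")
    }
    negf <- if (st$metric == "mi") {
      function(p) -mutual_information(fbins, moving_at(p), m_range)
    } else {
      function(p) -stats::cor(fvals, moving_at(p))
    }
    step <- c(rep(2, 3), rep(vox, 3))
    if (st$role == "capture") {
      # rotation capture: scan a deterministic rotation grid around the
      # centroid-initialized pose, then line searches + simplex
      rot_grid <- as.matrix(expand.grid(seq(-6, 6, by = 3),
                                        seq(-6, 6, by = 3),
                                        seq(-6, 6, by = 3)))
      vals <- apply(rot_grid, 1, function(d) negf(par + c(d, 0, 0, 0)))
      par <- par + c(rot_grid[which.min(vals), ], 0, 0, 0)
      cb <- cyclic_brent(negf, par, widths = c(rep(2.5, 3), rep(2, 3)),
                         cycles = 5L)
      par <- cb$par
      par_before <- par
      last_val <- cb$value
    } else if (st$role == "refine") {
      # cheap gap-shaver: the correlation optimum on blurred volumes is
      # biased by a fraction of a degree, so no simplex polish is spent here
      cb <- cyclic_brent(negf, par,
                         widths = c(rep(2.5, 3), rep(2.5 * vox, 3)),
                         cycles = 4L)
      par <- cb$par
      par_before <- par
      last_val <- cb$value
    } else {
      # precision on the raw-volume histogram metric, whose optimum
      # coincides with the true pose; brackets wide enough to absorb the
      # blurred-stage bias, then a small simplex, then a narrow final pass
      cb <- cyclic_brent(negf, par,
                         widths = c(rep(1.5, 3), rep(1.2 * vox, 3)),
                         cycles = 3L)
      # second, re-centred round: repeated rounds track the coupled
      # rotation-translation valley better than one shrinking pass
      cb <- cyclic_brent(negf, cb$par,
                         widths = c(rep(0.8, 3), rep(0.6 * vox, 3)),
                         cycles = 3L)
      o <- stats::optim(cb$par, negf, method = "Nelder-Mead",
                        control = list(maxit = max_iter %/% 5,
                                       reltol = 1e-10, parscale = step / 15))
      par_before <- o$par
      cb <- cyclic_brent(negf, o$par,
                         widths = c(rep(0.15, 3), rep(0.2 * vox, 3)),
                         cycles = 2L)
      par <- cb$par
      last_val <- cb$value
      # convergence check: the precision pass should barely move the pose
      if (max(abs(par - par_before)) > 0.1) conv_ok <- FALSE
    }
    diagnostics <- c(diagnostics, -last_val)
  }
  out <- rigid_transform(par[1:3], par[4:6], ctr)
  attr(out, "metric") <- diagnostics[length(diagnostics)]
  attr(out, "converged") <- conv_ok
  attr(out, "diagnostics") <- diagnostics
  if (!conv_ok) {
    warning("estimate_rigid: optimizer hit its iteration budget before ",
            "convergence; inspect attr(result, 'diagnostics')", call. = FALSE)
  }
  out
}

#' Paired vessel/parenchyma region-of-interest set
#'
#' A `roi_set` couples an integer label volume (aligned to a reference grid)
#' with a label table and a vessel-to-parenchyma pairing: each vessel ROI has
#' an adjacent parenchymal partner of identical voxel count, as the paired
#' CNR estimator requires.
#'
#' @param label_volume a [volume3d()] whose data are integer labels (0 =
#'   unlabelled).
#' @param labels data frame with columns `label`, `name`, `caliber_class`,
#'   `kind` (`"vessel"` or `"parenchyma"`).
#' @param pairing named integer vector: vessel label -> parenchyma label.
#' @export
roi_set <- function(label_volume, labels, pairing) {
  abort_if(!inherits(label_volume, "volume3d"), "`label_volume` must be a volume3d")
  abort_if(!all(label_volume$data == round(label_volume$data)),
           "`label_volume` must hold integer labels")
  abort_if(!all(c("label", "name", "caliber_class", "kind") %in% names(labels)),
           "`labels` must have columns label, name, caliber_class, kind")
  for (v in names(pairing)) {
    nv <- sum(label_volume$data == as.integer(v))
    np <- sum(label_volume$data == pairing[[v]])
    abort_if(nv != np, sprintf(
      "vessel ROI %s (%d voxels) and its parenchymal partner %d (%d voxels) differ in size",
      v, nv, pairing[[v]], np))
  }
  structure(list(label_volume = label_volume, labels = labels,
                 pairing = pairing), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d vessel + %d parenchymal ROIs on a %s grid\n",
              sum(x$labels$kind == "vessel"),
              sum(x$labels$kind == "parenchyma"),
              paste(dim(x$label_volume$data), collapse = "x")))
  invisible(x)
}

#' Voxel indices of one ROI label
#' @param rois a [roi_set()].
#' @param label integer label.
#' @return integer vector of linear voxel indices.
#' @export
roi_voxels <- function(rois, label) which(rois$label_volume$data == label)

#' Place the default paired ROI configuration on a phantom
#'
#' Samples `n_vessel` (default 17, the configuration used throughout the
#' analyses) sphere-shaped vessel ROIs along the tree's segments, spanning
#' all caliber classes, with sphere diameter about 0.8 of the local vessel
#' diameter. Each vessel ROI's parenchymal partner is the same voxel-offset
#' set translated by an integer-voxel offset perpendicular to the segment
#' into background — guaranteeing identical voxel counts. Segments too thin
#' to contain a voxel-resolvable sphere still contribute their nearest
#' voxel, so small-caliber classes are represented.
#'
#' @param tree a [build_vessel_tree()] result.
#' @param volume the noise-free rasterized [volume3d()] the ROIs refer to.
#' @param n_vessel number of vessel ROIs.
#' @param clearance_vox background clearance (voxels) between a vessel
#'   surface and its parenchymal partner.
#' @return a [roi_set()] with vessel labels `1..n_vessel` paired to
#'   parenchyma labels `101..(100 + n_vessel)`.
#' @export
default_roi_set <- function(tree, volume, n_vessel = 17L, clearance_vox = 2) {
  segs <- tree$segments
  dims <- dim(volume$data)
  vs <- volume$voxel_size
  origin <- volume$affine[1:3, 4]
  lab <- array(0L, dims)
  # cycle through segments ordered by decreasing radius so every caliber
  # class is visited before labels run out
  ord <- order(-segs$radius)
  cand_queue <- rep(ord, 4L) # revisit segments if a placement fails
  qpos <- 0L
  frac_at <- function(pt) {
    # nearest voxel index (0-based)
    pmin(pmax(round((pt - origin) / vs), 0), dims - 1)
  }
  rows <- list()
  pairing <- integer(0)
  bg <- min(volume$data)
  for (j in seq_len(n_vessel)) {
    placed <- FALSE
    tries <- 0L
    while (!placed && tries < length(cand_queue)) {
    qpos <- qpos %% length(cand_queue) + 1L
    tries <- tries + 1L
    seg <- segs[cand_queue[qpos], ]
    a <- c(seg$x0, seg$y0, seg$z0); b <- c(seg$x1, seg$y1, seg$z1)
    dirv <- (b - a) / sqrt(sum((b - a)^2))
    up <- if (abs(dirv[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- up - sum(up * dirv) * dirv; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(dirv[2] * e1[3] - dirv[3] * e1[2],
            dirv[3] * e1[1] - dirv[1] * e1[3],
            dirv[1] * e1[2] - dirv[2] * e1[1])
    placed <- FALSE
    for (shrink in c(1, 0.75, 0.5)) {
      # floor: an ROI must span a few voxels on its grid, or ROI statistics
      # (standard deviations for the difference method) degenerate
      r_roi <- max(0.8 * seg$radius * shrink, max(vs) * 1.05)
      # candidate voxel offsets of a sphere of radius r_roi
      nmax <- ceiling(r_roi / vs)
      og <- as.matrix(expand.grid(-nmax[1]:nmax[1], -nmax[2]:nmax[2],
                                  -nmax[3]:nmax[3]))
      keep <- sqrt(rowSums(sweep(og, 2, vs, "*")^2)) <= r_roi
      og <- og[keep, , drop = FALSE]
      if (nrow(og) == 0) og <- matrix(0L, 1, 3)
      for (tpos in c(0.3 + 0.4 * ((j - 1) %% 3) / 2, 0.25, 0.5, 0.75)) {
        ctr <- a + tpos * (b - a)
        cvox <- frac_at(ctr)
        vidx <- sweep(og, 2, cvox, "+")
        inb <- vidx[, 1] >= 0 & vidx[, 1] <= dims[1] - 1 &
          vidx[, 2] >= 0 & vidx[, 2] <= dims[2] - 1 &
          vidx[, 3] >= 0 & vidx[, 3] <= dims[3] - 1
        if (!all(inb)) next
        vlin <- 1L + vidx[, 1] + dims[1] * (vidx[, 2] + dims[2] * vidx[, 3])
        if (any(lab[vlin] != 0L)) next
        # parenchymal partner: translate the same voxel-offset set
        # perpendicular to the segment until all voxels are background
        for (phi in seq(0, 2 * pi - 0.05, by = pi / 8)) {
          dirp <- cos(phi) * e1 + sin(phi) * e2
          for (mult in seq(1, 6, by = 0.5)) {
            dist_mm <- seg$radius + r_roi + clearance_vox * max(vs) * mult
            off <- round(dirp * dist_mm / vs)
            pidx <- sweep(vidx, 2, off, "+")
            if (any(pidx < 0) || any(sweep(pidx, 2, dims - 1) > 0)) next
            plin <- 1L + pidx[, 1] + dims[1] * (pidx[, 2] + dims[2] * pidx[, 3])
            if (all(abs(volume$data[plin] - bg) < 1e-9) &&
                all(lab[plin] == 0L)) {
              lab[vlin] <- j
              lab[plin] <- 100L + j
              placed <- TRUE
              break
            }
          }
          if (placed) break
        }
        if (placed) break
      }
      if (placed) break
    }
    } # candidate-segment loop
    abort_if(!placed, sprintf("could not place parenchymal partner for ROI %d", j))
    rows[[j]] <- data.frame(
      label = c(j, 100L + j),
      name = c(sprintf("vessel_%02d", j), sprintf("parenchyma_%02d", j)),
      caliber_class = seg$caliber_class,
      kind = c("vessel", "parenchyma"))
    pairing[as.character(j)] <- 100L + j
  }
  lv <- volume
  lv$data <- lab
  roi_set(lv, do.call(rbind, rows), pairing)
}

#' Propagate ROIs through a rigid transform onto another grid
#'
#' Nearest-neighbour resampling of the label volume (so no new label values
#' are created) onto `reference`'s grid; pairing metadata is preserved, and
#' the per-label voxel counts after propagation are reported via `message()`.
#' A label vanishing entirely is an error naming the label, never a silent
#' drop.
#'
#' @param rois a [roi_set()] aligned to the space `transform` maps from.
#' @param transform [rigid_transform()] into the reference space.
#' @param reference [volume3d()] defining the target grid.
#' @return a [roi_set()] on the reference grid.
#' @export
propagate_rois <- function(rois, transform, reference) {
  lv <- resample_nn(rois$label_volume, transform, reference)
  lv$data <- array(as.integer(round(lv$data)), dim(lv$data))
  counts <- table(lv$data[lv$data != 0])
  for (l in rois$labels$label) {
    n <- sum(lv$data == l)
    abort_if(n == 0L, sprintf(
      "label %d ('%s') vanished during propagation onto the coarser grid",
      l, rois$labels$name[rois$labels$label == l]))
  }
  message("propagate_rois voxel counts: ",
          paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                collapse = ", "))
  structure(list(label_volume = lv, labels = rois$labels,
                 pairing = rois$pairing), class = "roi_set")
}
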