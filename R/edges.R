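#' Maximum intensity projection
#'
#' Per-pixel maximum along one anatomical axis over an optional slab.
#' Axis mapping for a volume indexed (x, y, z): `"axial"` projects along z
#' (image in the x-y plane), `"coronal"` along y, `"sagittal"` along x.
#' Pixel size is inherited from the in-plane voxel size.
#'
#' @param volume a [volume3d()].
#' @param axis `"axial"`, `"coronal"` or `"sagittal"`.
#' @param slab optional integer range of slices (1-based, within bounds)
#'   along the projection axis; full extent if `NULL`.
#' @return an [image2d()].
#' @export
mip <- function(volume, axis = c("axial", "coronal", "sagittal"),
                slab = NULL) {
  axis <- match.arg(axis)
  ax <- switch(axis, axial = 3L, coronal = 2L, sagittal = 1L)
  d <- dim(volume$data)
  if (is.null(slab)) slab <- seq_len(d[ax])
  abort_if(length(slab) == 0L, "empty slab")
  abort_if(any(slab < 1L) || any(slab > d[ax]), "slab out of bounds")
  a <- switch(axis,
              axial = volume$data[, , slab, drop = FALSE],
              coronal = volume$data[, slab, , drop = FALSE],
              sagittal = volume$data[slab, , , drop = FALSE])
  keep <- setdiff(1:3, ax)
  m <- apply(a, keep, max)
  image2d(m, volume$voxel_size[keep])
}

# separable Gaussian smoothing with replicate (edge-clamp) padding
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(x, along_rows) {
    n <- if (along_rows) nrow(x) else ncol(x)
    acc <- 0
    for (t in -rad:rad) {
      sel <- pmin(pmax(seq_len(n) + t, 1L), n) # replicate padding
      shifted <- if (along_rows) x[sel, , drop = FALSE]
                 else x[, sel, drop = FALSE]
      acc <- acc + k[t + rad + 1L] * shifted
    }
    acc
  }
  conv1(conv1(m, TRUE), FALSE)
}

# 3x3 Sobel gradients; replicate padding
sobel_gradients <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[pmax(seq_len(nr) - 1L, 1L), , drop = FALSE]
  dn <- m[pmin(seq_len(nr) + 1L, nr), , drop = FALSE]
  sh <- function(x, t) x[, pmin(pmax(seq_len(nc) + t, 1L), nc), drop = FALSE]
  gx <- (sh(up, 1) + 2 * sh(m, 1) + sh(dn, 1)) -
    (sh(up, -1) + 2 * sh(m, -1) + sh(dn, -1)) # d/dcol
  gy <- (sh(dn, -1) + 2 * dn + sh(dn, 1)) -
    (sh(up, -1) + 2 * up + sh(up, 1)) # d/drow
  list(gx = gx, gy = gy)
}

#' Canny edge detection
#'
#' Full Canny pipeline: Gaussian smoothing, Sobel gradient magnitude and
#' direction, non-maximum suppression along the gradient direction, and
#' double-threshold hysteresis with 8-connectivity.
#' Thresholds are specified as fractions of the maximum gradient magnitude,
#' so the edge map is invariant to positive rescaling of the image
#' intensities. A constant image yields an empty edge map. Edges come out as
#' 1-pixel-wide ridges.
#'
#' @param image an [image2d()].
#' @param gaussian_sigma smoothing SD in pixels (>= 0; default 1.4).
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude, `0 <= low < high <= 1` (defaults 0.1 / 0.2).
#' @param nms non-maximum suppression flavour: `"interpolated"` (default)
#'   compares each pixel against bilinearly interpolated magnitudes one
#'   unit step along the exact gradient direction, yielding strictly
#'   1-px-wide ridges; `"quantized"` compares against the nearest of the 8
#'   neighbours, which can leave double ridges where a curved edge crosses
#'   a direction-sector boundary.
#' @return object of class `edge_map`: logical matrix `data` plus the
#'   `parameters` recorded for provenance.
#' @export
canny <- function(image, gaussian_sigma = 1.4, low = 0.1, high = 0.2,
                  nms = c("interpolated", "quantized")) {
  nms <- match.arg(nms)
  abort_if(gaussian_sigma < 0, "`gaussian_sigma` must be >= 0")
  abort_if(!(low >= 0 && low < high && high <= 1),
           "need 0 <= low < high <= 1")
  m <- gaussian_smooth(image$data, gaussian_sigma)
  g <- sobel_gradients(m)
  mag <- sqrt(g$gx^2 + g$gy^2)
  gmax <- max(mag)
  params <- list(gaussian_sigma = gaussian_sigma, low_threshold = low,
                 high_threshold = high, nms = nms)
  if (gmax == 0) {
    return(structure(list(data = matrix(FALSE, nrow(m), ncol(m)),
                          parameters = params), class = "edge_map"))
  }
  nr <- nrow(m); nc <- ncol(m)
  if (nms == "quantized") {
    # quantize gradient direction to the nearest of the 4 axes (8
    # neighbours) and keep local ridge maxima along it
    ang <- atan2(g$gy, g$gx) # direction of intensity increase
    sector <- (round(ang / (pi / 4)) %% 4) # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
    shift2 <- function(x, dr, dc) {
      x[pmin(pmax(seq_len(nr) + dr, 1L), nr),
        pmin(pmax(seq_len(nc) + dc, 1L), nc), drop = FALSE]
    }
    # rows index the first array dim; gx is d/dcol, gy is d/drow
    nb <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(-1, 1))
    keep <- matrix(FALSE, nr, nc)
    for (s in 0:3) {
      d <- nb[[as.character(s)]]
      fwd <- shift2(mag, d[1], d[2])
      bwd <- shift2(mag, -d[1], -d[2])
      keep <- keep | (sector == s & mag >= bwd & mag > fwd)
    }
  } else {
    # compare against bilinearly interpolated magnitudes one unit step
    # along the exact gradient direction (and its opposite)
    safe_mag <- pmax(mag, .Machine$double.xmin)
    ur <- g$gy / safe_mag # row step component
    uc <- g$gx / safe_mag # col step component
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    sample_mag <- function(r, c) {
      r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
      r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
      fr <- r - r0; fc <- c - c0
      mag[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
        mag[cbind(r0 + 1, c0)] * fr * (1 - fc) +
        mag[cbind(r0, c0 + 1)] * (1 - fr) * fc +
        mag[cbind(r0 + 1, c0 + 1)] * fr * fc
    }
    fwd <- matrix(sample_mag(as.vector(rows + ur), as.vector(cols + uc)),
                  nr, nc)
    bwd <- matrix(sample_mag(as.vector(rows - ur), as.vector(cols - uc)),
                  nr, nc)
    keep <- mag >= bwd & mag > fwd
  }
  supp <- mag * keep
  strong <- supp >= high * gmax
  weak <- supp >= low * gmax
  if (!any(strong)) {
    return(structure(list(data = matrix(FALSE, nr, nc), parameters = params),
                     class = "edge_map"))
  }
  # hysteresis: keep 8-connected weak components that contain a strong pixel
  lab <- EBImage::bwlabel(weak)
  good <- unique(lab[strong])
  edges <- weak & matrix(lab %in% good, nr, nc)
  structure(list(data = edges, parameters = params), class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map> %s px, %d edge pixels (sigma %.2g, low %.2g, high %.2g)\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              x$parameters$gaussian_sigma, x$parameters$low_threshold,
              x$parameters$high_threshold))
  invisible(x)
}

#' Count edge pixels, optionally inside a box
#'
#' @param edge_map a [canny()] result.
#' @param box optional inclusive pixel rectangle `c(r0, c0, r1, c1)`
#'   (1-based row/col bounds) within the image.
#' @return integer edge-pixel count.
#' @export
count_edges <- function(edge_map, box = NULL) {
  m <- edge_map$data
  if (is.null(box)) return(sum(m))
  abort_if(length(box) != 4L, "`box` must be c(r0, c0, r1, c1)")
  abort_if(box[1] < 1 || box[2] < 1 || box[3] > nrow(m) || box[4] > ncol(m) ||
             box[1] > box[3] || box[2] > box[4], "`box` out of image bounds")
  sum(m[box[1]:box[3], box[2]:box[4]])
}

#' Write an edge map as a 0/255 PNG with a JSON parameter sidecar
#' @param edge_map a [canny()] result.
#' @param path output `.png` path; the sidecar is `path` + `.json`.
#' @export
write_edge_map <- function(edge_map, path) {
  png::writePNG(edge_map$data * 1.0, target = path)
  jsonlite::write_json(edge_map$parameters, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
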