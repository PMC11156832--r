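#' 3-D image volume with physical voxel geometry
#'
#' A `volume3d` couples a numeric 3-D array with its physical voxel size (mm)
#' and a 4x4 voxel-to-world affine. Voxel indices are 0-based with a
#' voxel-centre convention: world = affine %*% c(i, j, k, 1) places the centre
#' of voxel (i, j, k), RAS-like axes. This is the unit all 3-D stages of the
#' pipeline exchange.
#'
#' @param data numeric 3-D array of voxel values (finite everywhere).
#' @param voxel_size numeric length-3, voxel edge lengths in mm (all > 0).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `voxel_size` with the grid centred on the world origin.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_size, affine = NULL) {
  abort_if(!is.array(data) || length(dim(data)) != 3L,
           "`data` must be a 3-D array")
  abort_if(!all(is.finite(data)), "`data` must be finite everywhere")
  voxel_size <- as.numeric(voxel_size)
  abort_if(length(voxel_size) != 3L || any(voxel_size <= 0),
           "`voxel_size` must be 3 positive lengths in mm")
  if (is.null(affine)) {
    origin <- -(dim(data) - 1) / 2 * voxel_size
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- origin
  }
  affine <- as.matrix(affine)
  abort_if(!all(dim(affine) == c(4L, 4L)), "`affine` must be 4x4")
  abort_if(abs(det(affine)) < .Machine$double.eps * 100,
           "`affine` must be invertible")
  structure(list(data = data, voxel_size = voxel_size, affine = affine),
            class = "volume3d")
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, voxel size %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Map 0-based voxel indices to world coordinates (mm)
#'
#' @param volume a [volume3d()].
#' @param idx numeric matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(volume, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  h <- cbind(idx, 1) %*% t(volume$affine)
  h[, 1:3, drop = FALSE]
}

#' Map world coordinates (mm) to continuous 0-based voxel indices
#'
#' @inheritParams voxel_to_world
#' @param pts numeric matrix (n x 3) of world coordinates in mm.
#' @export
world_to_voxel <- function(volume, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  h <- cbind(pts, 1) %*% t(solve(volume$affine))
  h[, 1:3, drop = FALSE]
}

#' Read / write a volume as NIfTI-1
#'
#' The NIfTI sform carries the voxel-to-world affine; voxel sizes are taken
#' from the header pixdim.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return [volume3d()] for `read_volume`; invisibly `path` for `write_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  volume3d(array(as.numeric(img), dim = dim(img)),
           voxel_size = RNifti::pixdim(img)[1:3],
           affine = aff)
}

#' @rdname read_volume
#' @param volume a [volume3d()] to write.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$voxel_size # before sform: it rescales xforms
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' 2-D image with physical pixel size
#'
#' @param data numeric matrix of pixel values (finite).
#' @param pixel_size numeric length-2 pixel size in mm.
#' @return an object of class `image2d`.
#' @export
image2d <- function(data, pixel_size = c(1, 1)) {
  abort_if(!is.matrix(data), "`data` must be a matrix")
  abort_if(!all(is.finite(data)), "`data` must be finite")
  pixel_size <- as.numeric(pixel_size)
  abort_if(length(pixel_size) != 2L || any(pixel_size <= 0),
           "`pixel_size` must be 2 positive lengths in mm")
  structure(list(data = data, pixel_size = pixel_size), class = "image2d")
}

#' @export
dim.image2d <- function(x) dim(x$data)

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %s px, pixel size %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$pixel_size), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Write a 2-D image as grayscale PNG or 16-bit TIFF
#'
#' Intensities are rescaled to the full dynamic range unless the image is
#' constant, in which case a zero image is written. PNG output is 8-bit;
#' use `write_image_tiff()` when 16-bit depth matters.
#' @param image an [image2d()].
#' @param path output path.
#' @export
write_image_png <- function(image, path) {
  m <- image$data
  rng <- range(m)
  m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  png::writePNG(m, target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
write_image_tiff <- function(image, path) {
  abort_if(!requireNamespace("tiff", quietly = TRUE),
           "the 'tiff' package is required for TIFF output")
  m <- image$data
  rng <- range(m)
  m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale PNG as an image2d
#'
#' @param path `.png` path.
#' @param pixel_size physical pixel size in mm.
#' @export
read_image_png <- function(path, pixel_size = c(1, 1)) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  image2d(a, pixel_size)
}
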