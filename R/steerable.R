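#' Complex steerable pyramid
#'
#' An FFT-domain complex wavelet transform: raised-cosine radial filters
#' split the spectrum into octave bands, `cos^(K-1)` angular filters split
#' each band into K oriented half-plane (analytic, hence complex-valued)
#' sub-bands, and each band is decimated dyadically by cropping its
#' spectrum. The filters form a tight frame, so the transform is exactly
#' invertible and energy-preserving, and — because each sub-band is
#' bandlimited within its decimated grid — near shift-invariant: a small
#' image translation appears as a smooth phase ramp on the coefficients
#' rather than a change of their magnitudes. These are precisely the
#' properties the complex-wavelet structural similarity index relies on.
#'
#' @name steerable-pyramid
NULL

fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((nr %/% 2 + 1):nr, 1:(nr %/% 2)), c((nc %/% 2 + 1):nc, 1:(nc %/% 2))]
}

ifftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((nr - nr %/% 2 + 1):nr, 1:(nr - nr %/% 2)),
    c((nc - nc %/% 2 + 1):nc, 1:(nc - nc %/% 2))]
}

# crop the centred block of a full (unshifted) spectrum down to size s
crop_spectrum <- function(X, s) {
  nr <- nrow(X); nc <- ncol(X)
  Xs <- fftshift2(X)
  r0 <- nr %/% 2 + 1 - s[1] %/% 2
  c0 <- nc %/% 2 + 1 - s[2] %/% 2
  ifftshift2(Xs[r0:(r0 + s[1] - 1), c0:(c0 + s[2] - 1), drop = FALSE])
}

# inverse of crop_spectrum: zero-pad a small spectrum back to full size
pad_spectrum <- function(Y, full) {
  s <- dim(Y)
  Xs <- matrix(0 + 0i, full[1], full[2])
  r0 <- full[1] %/% 2 + 1 - s[1] %/% 2
  c0 <- full[2] %/% 2 + 1 - s[2] %/% 2
  Xs[r0:(r0 + s[1] - 1), c0:(c0 + s[2] - 1)] <- fftshift2(Y)
  ifftshift2(Xs)
}

# raised-cosine lowpass profile over one octave below `cutoff` (rad/px)
radial_lowpass <- function(r, cutoff) {
  v <- numeric(length(r))
  v[r <= cutoff / 2] <- 1
  t <- r > cutoff / 2 & r < cutoff
  v[t] <- cos(pi / 2 * log2(2 * r[t] / cutoff))
  v
}

# frequency-domain masks for every pyramid element, all at full resolution
csp_masks <- function(nr, nc, n_levels, n_orientations) {
  wr <- 2 * pi * c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  wc <- 2 * pi * c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  wr <- wr[1:nr]; wc <- wc[1:nc]
  R <- sqrt(outer(wr^2, wc^2, "+"))
  TH <- atan2(outer(wr, rep(1, nc)), outer(rep(1, nr), wc))
  K <- n_orientations
  # angular cos^(K-1) filters over half-planes; normalization computed
  # numerically so that the 2K mirrored copies tile the circle exactly
  const <- sum(pmax(cos(0 - (0:(2 * K - 1)) * pi / K), 0)^(2 * (K - 1)))
  ang <- function(theta0) {
    d <- (TH - theta0 + pi) %% (2 * pi) - pi
    g <- matrix(0, nr, nc)
    s <- abs(d) < pi / 2
    g[s] <- cos(d[s])^(K - 1) / sqrt(const)
    g
  }
  L0 <- matrix(radial_lowpass(R, pi), nr, nc)
  H0 <- sqrt(pmax(0, 1 - L0^2))
  P <- L0
  bands <- list()
  for (l in seq_len(n_levels)) {
    cut <- pi / 2^l
    Hl <- matrix(sqrt(pmax(0, 1 - radial_lowpass(R, cut)^2)), nr, nc)
    for (k in seq_len(K)) {
      bands[[sprintf("l%d_o%d", l, k)]] <- P * Hl * ang((k - 1) * pi / K)
    }
    P <- P * matrix(radial_lowpass(R, cut), nr, nc)
  }
  list(H0 = H0, P_low = P, bands = bands)
}

#' Forward complex wavelet transform
#'
#' Decomposes an image into `n_levels x n_orientations` complex oriented
#' sub-bands (grids shrinking dyadically with scale) plus real highpass and
#' lowpass residuals.
#'
#' @param image an [image2d()] or plain numeric matrix whose dimensions are
#'   multiples of `2^n_levels` and at least `2^n_levels`.
#' @param config a [similarity_config()] supplying `n_levels` and
#'   `n_orientations`.
#' @return object of class `subband_set`: `bands` (named list of complex
#'   matrices, names `l<scale>_o<orientation>`), `highpass`, `lowpass`,
#'   `source_shape`, `transform_config`.
#' @export
cwt_forward <- function(image, config = similarity_config()) {
  m <- if (inherits(image, "image2d")) image$data else image
  nr <- nrow(m); nc <- ncol(m)
  L <- config$n_levels
  abort_if(min(nr, nc) < 2^L,
           sprintf("image (%dx%d) too small for %d levels", nr, nc, L))
  abort_if(nr %% 2^L != 0 || nc %% 2^L != 0,
           sprintf("image dimensions (%dx%d) must be multiples of 2^%d; crop first",
                   nr, nc, L))
  masks <- csp_masks(nr, nc, L, config$n_orientations)
  X <- stats::fft(m)
  full_n <- nr * nc
  bands <- lapply(names(masks$bands), function(nm) {
    l <- as.integer(sub("l(\\d+)_o.*", "\\1", nm))
    s <- c(nr, nc) %/% 2^(l - 1)
    Y <- crop_spectrum(X * masks$bands[[nm]], s)
    stats::fft(Y, inverse = TRUE) / prod(s) * sqrt(prod(s) / full_n)
  })
  names(bands) <- names(masks$bands)
  s_low <- c(nr, nc) %/% 2^L
  Ylow <- crop_spectrum(X * masks$P_low, s_low)
  lowpass <- Re(stats::fft(Ylow, inverse = TRUE) / prod(s_low) *
                  sqrt(prod(s_low) / full_n))
  highpass <- Re(stats::fft(X * masks$H0, inverse = TRUE) / full_n)
  structure(list(bands = bands, highpass = highpass, lowpass = lowpass,
                 source_shape = c(nr, nc),
                 transform_config = list(
                   n_levels = L, n_orientations = config$n_orientations,
                   wavelet_family_id = "complex_steerable_pyramid")),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set> %d levels x %d orientations on %s px (%s)\n",
              x$transform_config$n_levels, x$transform_config$n_orientations,
              paste(x$source_shape, collapse = "x"),
              x$transform_config$wavelet_family_id))
  invisible(x)
}

#' Inverse complex wavelet transform
#'
#' Exact reconstruction from a [cwt_forward()] decomposition (tight-frame
#' property of the filters).
#' @param sb a `subband_set`.
#' @return numeric matrix of the reconstructed image.
#' @export
cwt_inverse <- function(sb) {
  full <- sb$source_shape
  full_n <- prod(full)
  L <- sb$transform_config$n_levels
  masks <- csp_masks(full[1], full[2], L, sb$transform_config$n_orientations)
  acc <- stats::fft(sb$highpass) * masks$H0
  s_low <- full %/% 2^L
  acc <- acc + pad_spectrum(
    stats::fft(sb$lowpass) / sqrt(prod(s_low) / full_n), full) * masks$P_low
  for (nm in names(sb$bands)) {
    l <- as.integer(sub("l(\\d+)_o.*", "\\1", nm))
    s <- full %/% 2^(l - 1)
    Y <- stats::fft(sb$bands[[nm]]) / sqrt(prod(s) / full_n)
    acc <- acc + 2 * pad_spectrum(Y, full) * masks$bands[[nm]]
  }
  Re(stats::fft(acc, inverse = TRUE) / full_n)
}

#' Total coefficient energy of a decomposition
#'
#' With the pyramid's tight-frame normalization this equals the input
#' image's energy `sum(x^2)`: each complex band counts twice (its mirrored
#' half-plane is implicit) plus the two real residuals.
#' @param sb a `subband_set`.
#' @export
cwt_energy <- function(sb) {
  2 * sum(vapply(sb$bands, function(b) sum(Mod(b)^2), numeric(1))) +
    sum(sb$highpass^2) + sum(sb$lowpass^2)
}
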