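#' Configuration for the complex-wavelet structural similarity index
#'
#' @param K stabilizing constant (> 0) added to numerator and denominator of
#'   each band score; `"auto"` (default) uses 1e-8 x the number of
#'   coefficients summed (whole band, or window for windowed aggregation) —
#'   a pure numerical guard so that a pair of empty bands scores 1 instead
#'   of 0/0. Larger K values damp low-energy bands toward 1 and inflate the
#'   index for dissimilar images, so K should stay far below typical band
#'   energies.
#' @param n_levels,n_orientations pyramid geometry (defaults 4 x 6).
#' @param aggregation `"windowed_mean"` (default): per-band scores from
#'   sliding `window_px` windows pooled with energy weights — the phase sum
#'   is unwrapped locally, making the index tolerant of the spatially
#'   varying displacements a small rotation induces, and empty background
#'   windows carry no weight; or `"global_per_band_mean"`: one score per
#'   sub-band from global sums. Both average over the included sub-bands and
#'   exclude the residual lowpass/highpass.
#' @param window_px sliding-window side for windowed aggregation.
#' @param binarize `"otsu_masks"` (default: compare Otsu-segmented binary
#'   masks, used by [compare_modality()]) or `"grayscale"`.
#' @param min_scale smallest pyramid scale included in the pooled index
#'   (default 2). Finest-scale coefficient envelopes decorrelate after a
#'   translation of only 1-2 px, so including scale 1 destroys the
#'   translation insensitivity the index exists for; set `min_scale = 1` to
#'   include it anyway.
#' @return object of class `similarity_config`.
#' @export
similarity_config <- function(K = "auto", n_levels = 4L, n_orientations = 6L,
                              aggregation = c("windowed_mean",
                                              "global_per_band_mean"),
                              window_px = 7L,
                              binarize = c("otsu_masks", "grayscale"),
                              min_scale = 2L) {
  aggregation <- match.arg(aggregation)
  binarize <- match.arg(binarize)
  if (!identical(K, "auto")) {
    abort_if(!is.numeric(K) || K <= 0, "`K` must be > 0 or \"auto\"")
  }
  abort_if(min_scale < 1L || min_scale > n_levels,
           "`min_scale` must lie in 1..n_levels")
  structure(list(K = K, n_levels = as.integer(n_levels),
                 n_orientations = as.integer(n_orientations),
                 aggregation = aggregation, window_px = as.integer(window_px),
                 binarize = binarize, min_scale = as.integer(min_scale)),
            class = "similarity_config")
}

#' Otsu threshold of an image
#'
#' Threshold maximizing the between-class variance over a 256-bin histogram
#' of the intensity range; ties are broken toward the lower threshold. The
#' returned intensity is the upper edge of the chosen bin, so
#' `image > threshold` is the foreground mask.
#'
#' @param image an [image2d()] (or matrix) with at least 2 distinct values.
#' @param n_bins histogram size (default 256).
#' @return the threshold intensity (scalar).
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- if (inherits(image, "image2d")) image$data else image
  rng <- range(v)
  abort_if(diff(rng) == 0, "constant image: Otsu threshold undefined")
  bin <- pmin(floor((v - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
  h <- tabulate(bin, n_bins)
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(n_bins))
  tot <- w[n_bins]; mu_t <- mu[n_bins]
  w0 <- w[1:(n_bins - 1)]
  mu0 <- mu[1:(n_bins - 1)]
  w1 <- tot - w0
  sb <- rep(-Inf, n_bins - 1)
  ok <- w0 > 0 & w1 > 0
  sb[ok] <- (mu0[ok] / w0[ok] - (mu_t - mu0[ok]) / w1[ok])^2 *
    w0[ok] * w1[ok]
  t_star <- which.max(sb) # first maximum = lower threshold on ties
  rng[1] + t_star * diff(rng) / n_bins
}

#' Binarize an image at a threshold
#' @param image an [image2d()].
#' @param threshold intensity cut; pixels strictly above are foreground.
#' @return an [image2d()] with values 0/1.
#' @export
binarize <- function(image, threshold = otsu_threshold(image)) {
  image2d((image$data > threshold) * 1.0, image$pixel_size)
}

#' Single-band complex-wavelet similarity score
#'
#' For two same-shape complex coefficient grids and stabilizer K:
#'
#'   (2 |sum(cx * Conj(cy))| + K) / (sum|cx|^2 + sum|cy|^2 + K)
#'
#' The value lies in (0, 1]; it equals 1 when `cy = cx`, and a rigid global
#' phase factor on `cy` (the signature of a small translation) leaves the
#' numerator's modulus unchanged.
#'
#' @param cx,cy complex matrices of identical shape.
#' @param K stabilizer (> 0).
#' @export
cwssi_band <- function(cx, cy, K) {
  abort_if(!all(dim(cx) == dim(cy)), "coefficient grids differ in shape")
  abort_if(!is.numeric(K) || K <= 0, "`K` must be > 0")
  (2 * Mod(sum(cx * Conj(cy))) + K) /
    (sum(Mod(cx)^2) + sum(Mod(cy)^2) + K)
}

#' Factored form of the single-band score
#'
#' The same index written as the product of a magnitude-agreement term and a
#' phase-consistency term:
#'
#'   [(2 sum|cx||cy| + K) / (sum|cx|^2 + sum|cy|^2 + K)] *
#'   [(2 |sum(cx Conj(cy))| + K) / (2 sum|cx Conj(cy)| + K)]
#'
#' Since `|cx * Conj(cy)| = |cx| |cy|` pointwise, the cross factors cancel
#' and this is algebraically identical to [cwssi_band()]; it is computed by
#' independent summation for cross-validation. The first factor alone is 1
#' whenever the coefficient magnitudes agree pointwise, regardless of
#' phases; the second measures how consistent the relative phases are —
#' which is why the index tolerates the coherent phase ramps produced by
#' small relative translations or rotations.
#'
#' @inheritParams cwssi_band
#' @export
cwssi_band_factored <- function(cx, cy, K) {
  abort_if(!all(dim(cx) == dim(cy)), "coefficient grids differ in shape")
  abort_if(!is.numeric(K) || K <= 0, "`K` must be > 0")
  mx <- Mod(cx); my <- Mod(cy)
  cross <- cx * Conj(cy)
  mag_term <- (2 * sum(mx * my) + K) / (sum(mx^2) + sum(my^2) + K)
  phase_term <- (2 * Mod(sum(cross)) + K) / (2 * sum(Mod(cross)) + K)
  mag_term * phase_term
}

# sums over all w x w windows (valid positions) via summed-area table
box_sums <- function(m, w) {
  cs <- apply(apply(m, 2, cumsum), 1, cumsum) # transposed SAT
  cs <- t(cs)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 1, nc + 1)
  pad[2:(nr + 1), 2:(nc + 1)] <- cs
  i <- 1:(nr - w + 1); j <- 1:(nc - w + 1)
  pad[i + w, j + w, drop = FALSE] - pad[i, j + w, drop = FALSE] -
    pad[i + w, j, drop = FALSE] + pad[i, j, drop = FALSE]
}

#' Complex-wavelet structural similarity index between two images
#'
#' Both images (already on a common grid) are min-max normalized to [0, 1],
#' centre-cropped to dimensions divisible by `2^n_levels`, decomposed with
#' the complex steerable pyramid, and compared band by band with
#' [cwssi_band()]; band scores are pooled according to the configured
#' aggregation (default: unweighted mean over all oriented sub-bands,
#' excluding the residual lowpass and highpass).
#'
#' @param image_x,image_y [image2d()] objects of identical dimensions.
#' @param config a [similarity_config()].
#' @return object of class `similarity_result`: `cwssi` in [0, 1],
#'   `per_band` named vector, `config`, `preprocessing_log`.
#' @export
cwssi <- function(image_x, image_y, config = similarity_config()) {
  abort_if(!all(dim(image_x$data) == dim(image_y$data)),
           "images must share dimensions; see compare_modality() for resampling")
  log <- character(0)
  norm01 <- function(m) {
    rng <- range(m)
    if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  }
  mx <- norm01(image_x$data)
  my <- norm01(image_y$data)
  log <- log_line(log, "min-max normalized both images to [0,1]")
  div <- 2^config$n_levels
  d <- dim(mx)
  target <- pmax((d %/% div) * div, div)
  abort_if(any(d < div), sprintf(
    "images (%dx%d) too small for %d pyramid levels", d[1], d[2],
    config$n_levels))
  if (any(target != d)) {
    r0 <- (d[1] - target[1]) %/% 2; c0 <- (d[2] - target[2]) %/% 2
    mx <- mx[(r0 + 1):(r0 + target[1]), (c0 + 1):(c0 + target[2])]
    my <- my[(r0 + 1):(r0 + target[1]), (c0 + 1):(c0 + target[2])]
    log <- log_line(log, sprintf("centre-cropped to %dx%d (multiple of 2^%d)",
                                 target[1], target[2], config$n_levels))
  }
  sx <- cwt_forward(mx, config)
  sy <- cwt_forward(my, config)
  log <- log_line(log, sprintf("complex steerable pyramid: %d levels x %d orientations",
                               config$n_levels, config$n_orientations))
  keep <- names(sx$bands)[as.integer(sub("l(\\d+)_o.*", "\\1",
                                         names(sx$bands))) >= config$min_scale]
  per_band <- vapply(keep, function(nm) {
    cx <- sx$bands[[nm]]; cy <- sy$bands[[nm]]
    if (config$aggregation == "global_per_band_mean") {
      K <- if (identical(config$K, "auto")) 1e-8 * length(cx) else config$K
      cwssi_band(cx, cy, K)
    } else {
      # windows pooled with energy weights: the phase sum is unwrapped
      # locally (insensitive to the spatially varying shifts a rotation
      # induces), while empty background windows — most of a sparse
      # angiogram — carry no weight and cannot dilute or inflate the score
      w <- min(config$window_px, dim(cx))
      K <- if (identical(config$K, "auto")) 1e-8 * w^2 else config$K
      cross <- cx * Conj(cy)
      num <- 2 * Mod(complex(real = box_sums(Re(cross), w),
                             imaginary = box_sums(Im(cross), w))) + K
      den <- box_sums(Mod(cx)^2, w) + box_sums(Mod(cy)^2, w) + K
      sum(num) / sum(den)
    }
  }, numeric(1))
  value <- mean(per_band)
  log <- log_line(log, sprintf("aggregation %s over %d sub-bands (K = %s)",
                               config$aggregation, length(per_band),
                               if (identical(config$K, "auto")) "auto"
                               else format(config$K)))
  structure(list(cwssi = value, per_band = per_band, config = config,
                 preprocessing_log = log),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> CW-SSI = %.4f over %d sub-bands (%s)\n",
              x$cwssi, length(x$per_band), x$config$aggregation))
  invisible(x)
}

# bilinear resampling of an image onto a target pixel grid
resample_image <- function(image, target_dim) {
  m <- image$data
  nr <- nrow(m); nc <- ncol(m)
  tr <- target_dim[1]; tc <- target_dim[2]
  # map target pixel centres onto the source grid proportionally
  sr <- (seq_len(tr) - 0.5) * nr / tr + 0.5
  sc <- (seq_len(tc) - 0.5) * nc / tc + 0.5
  r0 <- pmin(pmax(floor(sr), 1L), nr - 1L); fr <- pmin(pmax(sr - r0, 0), 1)
  c0 <- pmin(pmax(floor(sc), 1L), nc - 1L); fc <- pmin(pmax(sc - c0, 0), 1)
  a <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r0 + 1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[r0, c0 + 1, drop = FALSE] * outer(1 - fr, fc) +
    m[r0 + 1, c0 + 1, drop = FALSE] * outer(fr, fc)
  image2d(a, image$pixel_size * c(nr / tr, nc / tc))
}

#' Cross-modality similarity between an MRA MIP and a DSA(-like) image
#'
#' The full comparison pipeline: each image is intensity-normalized to
#' [0, 1] by 1st-99th percentile clipping, the larger image is bilinearly
#' resampled onto the smaller's grid, both are Otsu-segmented (binary masks
#' by default; `binarize = "grayscale"` skips segmentation for sensitivity
#' analysis), and the complex-wavelet similarity index is computed. Every
#' preprocessing step is recorded in the result's `preprocessing_log`.
#'
#' @param mra_mip,dsa_image [image2d()] objects covering approximately the
#'   same anatomy (coarse framing; no registration is assumed).
#' @param config a [similarity_config()].
#' @return a `similarity_result` (see [cwssi()]).
#' @export
compare_modality <- function(mra_mip, dsa_image,
                             config = similarity_config()) {
  log <- character(0)
  clip_norm <- function(m, nm) {
    lohi <- pctl(as.vector(m), c(0.01, 0.99))
    abort_if(diff(lohi) == 0 && diff(range(m)) == 0,
             sprintf("image '%s' is constant: cannot segment", nm))
    if (diff(lohi) == 0) lohi <- range(m)
    pmin(pmax((m - lohi[1]) / diff(lohi), 0), 1)
  }
  mx <- clip_norm(mra_mip$data, "mra_mip")
  my <- clip_norm(dsa_image$data, "dsa_image")
  log <- log_line(log, "clipped both images to their 1st-99th percentiles and scaled to [0,1]")
  ix <- image2d(mx, mra_mip$pixel_size)
  iy <- image2d(my, dsa_image$pixel_size)
  if (prod(dim(mx)) > prod(dim(my))) {
    ix <- resample_image(ix, dim(my))
    log <- log_line(log, sprintf("resampled mra_mip onto the %s grid (bilinear)",
                                 paste(dim(my), collapse = "x")))
  } else if (prod(dim(my)) > prod(dim(mx))) {
    iy <- resample_image(iy, dim(mx))
    log <- log_line(log, sprintf("resampled dsa_image onto the %s grid (bilinear)",
                                 paste(dim(mx), collapse = "x")))
  }
  if (config$binarize == "otsu_masks") {
    tx <- tryCatch(otsu_threshold(ix),
                   error = function(e) stop("Otsu segmentation failed for 'mra_mip': ",
                                            conditionMessage(e), call. = FALSE))
    ty <- tryCatch(otsu_threshold(iy),
                   error = function(e) stop("Otsu segmentation failed for 'dsa_image': ",
                                            conditionMessage(e), call. = FALSE))
    ix <- binarize(ix, tx)
    iy <- binarize(iy, ty)
    log <- log_line(log, sprintf("Otsu-binarized (thresholds %.4f / %.4f)", tx, ty))
  } else {
    log <- log_line(log, "grayscale mode: no segmentation")
  }
  res <- cwssi(ix, iy, config)
  res$preprocessing_log <- c(log, res$preprocessing_log)
  res
}
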