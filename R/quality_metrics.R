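#' Difference-method SNR over an ROI
#'
#' Estimates the signal-to-noise ratio from a repeat-acquisition pair
#' (A, B): the numerator is the ROI mean of the voxelwise average of A and
#' B, the denominator the ROI standard deviation (sample, n-1) of the
#' difference image A - B. With `convention = "paper"` the estimator is
#'
#'   SNR = (1 / sqrt(2)) * mean_ROI((A + B) / 2) / sd_ROI(A - B)
#'
#' for a homogeneous ROI of signal S and per-acquisition noise sigma this
#' converges to S / (2 sigma). `convention = "nema"` uses the conventional
#' difference-method prefactor sqrt(2) instead of 1/sqrt(2), converging to
#' the familiar S / sigma.
#'
#' @param pair an [make_pair()] acquisition pair whose volumes are on a
#'   common grid (register first when `true_misalignment` is not identity).
#' @param roi_voxels non-empty integer vector of linear voxel indices (or a
#'   logical array) selecting the ROI.
#' @param convention `"paper"` (default) or `"nema"`.
#' @param acquisition_id,roi_label identifiers carried into the result.
#' @return object of class `snr_result`: fields `snr`, `mean_signal`,
#'   `sigma_diff`, `convention`, `acquisition_id`, `roi_label`.
#' @export
snr_difference <- function(pair, roi_voxels, convention = c("paper", "nema"),
                           acquisition_id = "acq", roi_label = "roi") {
  convention <- match.arg(convention)
  if (is.logical(roi_voxels)) roi_voxels <- which(roi_voxels)
  abort_if(length(roi_voxels) == 0L, "`roi_voxels` must be non-empty")
  a <- pair$volume_a$data[roi_voxels]
  b <- pair$volume_b$data[roi_voxels]
  mean_signal <- mean((a + b) / 2)
  sigma_diff <- stats::sd(a - b)
  abort_if(!is.finite(sigma_diff) || sigma_diff == 0,
           "degenerate input: sd of (A - B) over the ROI is zero; ",
           "the difference method needs two independently noisy acquisitions")
  snr <- if (convention == "paper") mean_signal / (sqrt(2) * sigma_diff)
         else sqrt(2) * mean_signal / sigma_diff
  structure(list(acquisition_id = acquisition_id, roi_label = roi_label,
                 snr = snr, mean_signal = mean_signal,
                 sigma_diff = sigma_diff, convention = convention),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("<snr_result> %s/%s: SNR = %.4g (mean %.4g, sigma_diff %.4g, %s convention)\n",
              x$acquisition_id, x$roi_label, x$snr, x$mean_signal,
              x$sigma_diff, x$convention))
  invisible(x)
}

#' Paired-ROI contrast-to-noise ratio
#'
#' CNR between a vessel ROI and its same-size adjacent parenchymal ROI on a
#' single acquisition:
#'
#'   CNR = (mean_vessel - mean_parenchyma) /
#'         sqrt(sd_vessel^2 + sd_parenchyma^2)
#'
#' Standard deviations are sample (n-1). The sign is preserved (a vessel
#' darker than parenchyma yields a negative CNR), and swapping the two ROIs
#' negates the value exactly.
#'
#' @param volume a [volume3d()] (by convention the A acquisition).
#' @param vessel_roi,parenchyma_roi non-empty voxel index sets of identical
#'   size (logical arrays or integer index vectors).
#' @param acquisition_id,roi_label identifiers carried into the result.
#' @return object of class `cnr_result`.
#' @export
cnr <- function(volume, vessel_roi, parenchyma_roi,
                acquisition_id = "acq", roi_label = "roi") {
  if (is.logical(vessel_roi)) vessel_roi <- which(vessel_roi)
  if (is.logical(parenchyma_roi)) parenchyma_roi <- which(parenchyma_roi)
  abort_if(length(vessel_roi) == 0L || length(parenchyma_roi) == 0L,
           "both ROIs must be non-empty")
  abort_if(length(vessel_roi) != length(parenchyma_roi),
           "vessel and parenchymal ROIs must have identical voxel counts")
  v <- volume$data[vessel_roi]
  p <- volume$data[parenchyma_roi]
  sv <- stats::sd(v); sp <- stats::sd(p)
  denom <- sqrt(sv^2 + sp^2)
  abort_if(!is.finite(denom) || denom == 0,
           "degenerate input: both ROI standard deviations are zero")
  structure(list(acquisition_id = acquisition_id, roi_label = roi_label,
                 cnr = (mean(v) - mean(p)) / denom,
                 vessel_mean = mean(v), parenchyma_mean = mean(p),
                 vessel_sd = sv, parenchyma_sd = sp),
            class = "cnr_result")
}

#' @export
print.cnr_result <- function(x, ...) {
  cat(sprintf("<cnr_result> %s/%s: CNR = %.4g (vessel %.4g±%.3g, parenchyma %.4g±%.3g)\n",
              x$acquisition_id, x$roi_label, x$cnr, x$vessel_mean,
              x$vessel_sd, x$parenchyma_mean, x$parenchyma_sd))
  invisible(x)
}

#' @export
as.data.frame.snr_result <- function(x, ...) {
  data.frame(acquisition_id = x$acquisition_id, roi_label = x$roi_label,
             metric = "snr", value = x$snr, stringsAsFactors = FALSE)
}

#' @export
as.data.frame.cnr_result <- function(x, ...) {
  data.frame(acquisition_id = x$acquisition_id, roi_label = x$roi_label,
             metric = "cnr", value = x$cnr, stringsAsFactors = FALSE)
}

#' Summarize per-ROI metrics by group, box-plot style
#'
#' Aggregates a collection of [snr_difference()] / [cnr()] results (or a
#' tidy data frame with a `value` column) per group, reporting mean, sd,
#' median, quartiles and 5th/95th percentiles — the quantities a box plot
#' with 25th/75th-percentile boxes and 5th/95th-percentile whiskers
#' displays. Percentiles use linear interpolation between closest ranks.
#' Groups with fewer than two entries get `NA` as the sd marker.
#'
#' @param results list of `snr_result`/`cnr_result` objects, or a data frame
#'   with columns `acquisition_id`, `roi_label`, optionally `caliber_class`,
#'   and `value`.
#' @param group_by `"acquisition"` or `"caliber_class"`.
#' @return data frame with one row per group: `group`, `n`, `mean`, `sd`,
#'   `median`, `q25`, `q75`, `p05`, `p95`.
#' @export
aggregate_metric <- function(results, group_by = c("acquisition",
                                                   "caliber_class")) {
  group_by <- match.arg(group_by)
  df <- if (is.data.frame(results)) results else
    do.call(rbind, lapply(results, as.data.frame))
  abort_if(is.null(df) || nrow(df) == 0L, "`results` must be non-empty")
  key <- switch(group_by, acquisition = df$acquisition_id,
                caliber_class = df$caliber_class)
  abort_if(is.null(key), sprintf("grouping column for '%s' is missing", group_by))
  out <- lapply(split(df$value, key), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               median = pctl(v, 0.5), q25 = pctl(v, 0.25),
               q75 = pctl(v, 0.75), p05 = pctl(v, 0.05), p95 = pctl(v, 0.95))
  })
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res)
  rownames(res) <- NULL
  res
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for paired samples. Zero differences are
#' dropped, ties are mid-ranked. For n <= `exact_max` (default 25, which
#' covers a 17-ROI design comfortably) the null distribution of the rank sum
#' is computed exactly by dynamic programming over all 2^n sign assignments;
#' above that a normal approximation with continuity correction and tie
#' correction is used. The reported `statistic` is the sum of negative
#' ranks, so samples where every `a` exceeds `b` give statistic 0.
#'
#' @param values_a,values_b equal-length numeric vectors (n >= 5 pairs).
#' @param exact_max largest n for which the exact null is enumerated.
#' @return list with `statistic` (sum of negative ranks), `w_pos`, `w_neg`,
#'   `n_used` (non-zero differences), `p_value`, `method`.
#' @export
paired_wilcoxon <- function(values_a, values_b, exact_max = 25L) {
  abort_if(length(values_a) != length(values_b),
           "`values_a` and `values_b` must have equal length")
  abort_if(length(values_a) < 5L, "need at least 5 pairs")
  d <- values_a - values_b
  d <- d[d != 0]
  abort_if(length(d) == 0L,
           "no variability: all paired differences are zero")
  n <- length(d)
  r <- rank(abs(d)) # midranks
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  if (n <= exact_max) {
    # DP over the doubled (integer) ranks: distribution of 2*W under the null
    m <- as.integer(round(2 * r))
    total <- sum(m)
    f <- c(1, numeric(total))
    for (mi in m) {
      shifted <- c(numeric(mi), f[seq_len(total + 1 - mi)])
      f <- f + shifted
    }
    f <- f / 2^n
    cdf <- cumsum(f)
    w2 <- as.integer(round(2 * w_neg))
    p_le <- cdf[w2 + 1]
    p_ge <- 1 - (if (w2 >= 1) cdf[w2] else 0)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact signed-rank (enumerated null)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_neg - mu + sign(mu - w_neg) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with continuity correction"
  }
  list(statistic = w_neg, w_pos = w_pos, w_neg = w_neg, n_used = n,
       p_value = p, method = method)
}

#' Qualitative vessel-visibility score table
#'
#' Holds 5-point reader scores (0 = vessel not visible ... 4 = excellent
#' visibility) for vessel categories across volunteers and field strengths.
#'
#' @param entries data frame with columns `vessel_category`, `volunteer`,
#'   `field_strength` (`"3T"`/`"7T"`) and integer `score` in 0..4.
#' @return object of class `score_table`.
#' @export
score_table <- function(entries) {
  need <- c("vessel_category", "volunteer", "field_strength", "score")
  abort_if(!all(need %in% names(entries)),
           "`entries` needs columns ", paste(need, collapse = ", "))
  abort_if(!all(entries$score %in% 0:4), "scores must be integers in 0..4")
  structure(list(entries = entries), class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d entries, %d vessel categories, volunteers: %s\n",
              nrow(x$entries), length(unique(x$entries$vessel_category)),
              paste(sort(unique(x$entries$volunteer)), collapse = ", ")))
  invisible(x)
}

#' Read a score table from CSV
#' @param path CSV with columns `vessel_category`, `volunteer`,
#'   `field_strength`, `score`.
#' @export
read_score_table <- function(path) {
  score_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Bundled 7-T vs 3-T TOF-MRA reader scores
#'
#' The package's example score table: vessel-visibility scores of seven
#' intracranial vessel categories in four healthy volunteers, each imaged at
#' 3 T and at 7 T, on the 0-4 scale.
#' @return a [score_table()].
#' @export
tof_quality_scores <- function() {
  read_score_table(system.file("extdata", "tof_quality_scores.csv",
                               package = "angioqa", mustWork = TRUE))
}

#' Mean qualitative score for a field strength
#'
#' Arithmetic mean over all (vessel category x volunteer) cells of the
#' chosen field strength, optionally restricted to a subset of vessel
#' categories.
#' @param table a [score_table()].
#' @param field_strength `"3T"` or `"7T"`.
#' @param vessel_subset optional character vector of vessel categories.
#' @export
score_mean <- function(table, field_strength, vessel_subset = NULL) {
  e <- table$entries
  if (!is.null(vessel_subset)) {
    missing <- setdiff(vessel_subset, e$vessel_category)
    abort_if(length(missing) > 0,
             "unknown vessel categories: ", paste(missing, collapse = ", "))
  }
  sel <- e$field_strength == field_strength
  if (!is.null(vessel_subset)) sel <- sel & e$vessel_category %in% vessel_subset
  abort_if(!any(sel), "empty selection")
  mean(e$score[sel])
}

#' Per-volunteer total score
#'
#' Integer sum of the per-category scores of one volunteer at one field
#' strength; errors if any of the expected categories is missing.
#' @inheritParams score_mean
#' @param volunteer volunteer identifier.
#' @export
score_total <- function(table, volunteer, field_strength) {
  e <- table$entries
  sel <- e$volunteer == volunteer & e$field_strength == field_strength
  abort_if(!any(sel), "no entries for this volunteer/field strength")
  cats_all <- unique(e$vessel_category)
  missing <- setdiff(cats_all, e$vessel_category[sel])
  abort_if(length(missing) > 0,
           "missing categories for this volunteer: ",
           paste(missing, collapse = ", "))
  as.integer(sum(e$score[sel]))
}

#' Detection rate as a percentage
#'
#' `100 * n_detected / n_reference`, reported to one decimal place — e.g.
#' 16 of 19 reference findings detected gives 84.2.
#' @param n_detected,n_reference non-negative counts with
#'   `n_detected <= n_reference`, `n_reference > 0`.
#' @export
detection_rate <- function(n_detected, n_reference) {
  abort_if(n_reference <= 0, "`n_reference` must be positive")
  abort_if(n_detected < 0 || n_detected > n_reference,
           "`n_detected` must lie in [0, n_reference]")
  round(100 * n_detected / n_reference, 1)
}
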