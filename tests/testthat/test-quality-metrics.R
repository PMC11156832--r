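test_that("difference-method SNR follows the printed estimator exactly", {
  clean <- volume3d(array(100, c(20, 20, 20)), rep(0.3, 3))
  pair <- make_pair(clean, 10, 1, 2)
  roi <- seq_len(4000)
  res <- snr_difference(pair, roi)
  a <- pair$volume_a$data[roi]; b <- pair$volume_b$data[roi]
  expect_identical(res$snr, mean((a + b) / 2) / (sqrt(2) * sd(a - b)))
  # NEMA convention is exactly 2x the printed form
  res2 <- snr_difference(pair, roi, convention = "nema")
  expect_equal(res2$snr, 2 * res$snr, tolerance = 1e-12)
})

test_that("SNR is scale invariant and rejects degenerate pairs", {
  clean <- volume3d(array(100, c(20, 20, 20)), rep(0.3, 3))
  pair <- make_pair(clean, 10, 1, 2)
  roi <- seq_len(4000)
  scaled <- pair
  scaled$volume_a$data <- pair$volume_a$data * 3.7
  scaled$volume_b$data <- pair$volume_b$data * 3.7
  expect_equal(snr_difference(scaled, roi)$snr,
               snr_difference(pair, roi)$snr, tolerance = 1e-12)

  flat <- make_pair(clean, 0, 1, 2) # A = B exactly
  expect_error(snr_difference(flat, roi), "degenerate")
  expect_error(snr_difference(pair, integer(0)), "non-empty")
})

test_that("CNR matches its closed form, is antisymmetric, and flags degeneracy", {
  set.seed(5)
  v <- volume3d(array(60, c(40, 40, 50)), rep(0.25, 3))
  v$data[, , 1:25] <- 300
  v <- add_noise(v, 10, 7)
  vessel <- which(slice.index(v$data, 3) <= 25)
  paren <- which(slice.index(v$data, 3) > 25)
  res <- cnr(v, vessel, paren)
  expect_identical(res$cnr, (res$vessel_mean - res$parenchyma_mean) /
                     sqrt(res$vessel_sd^2 + res$parenchyma_sd^2))
  swapped <- cnr(v, paren, vessel)
  expect_equal(swapped$cnr, -res$cnr, tolerance = 1e-12)

  # two ROIs in the same homogeneous region: null contrast
  null <- cnr(v, paren[1:10000], paren[10001:20000])
  expect_lt(abs(null$cnr), 0.05)

  flat <- volume3d(array(5, c(10, 10, 10)), rep(0.5, 3))
  expect_error(cnr(flat, 1:10, 11:20), "degenerate")
  expect_error(cnr(v, vessel[1:5], paren[1:6]), "identical voxel counts")
})

test_that("aggregate_metric reports box-plot statistics by group", {
  df <- data.frame(acquisition_id = "a", roi_label = paste0("r", 1:3),
                   value = c(1, 2, 3))
  s <- aggregate_metric(df, "acquisition")
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_equal(s$sd, 1)

  # percentile convention: linear interpolation between closest ranks
  df2 <- data.frame(acquisition_id = "a", roi_label = paste0("r", 1:100),
                    value = 1:100)
  s2 <- aggregate_metric(df2, "acquisition")
  expect_equal(s2$q25, 25.75)
  expect_equal(s2$q75, 75.25)

  # order invariance
  s3 <- aggregate_metric(df2[sample(100), ], "acquisition")
  expect_equal(s3, s2)

  # single-entry group: sd reported as the undefined marker
  s4 <- aggregate_metric(data.frame(acquisition_id = "x", roi_label = "r",
                                    value = 5), "acquisition")
  expect_true(is.na(s4$sd))

  # list-of-results interface and caliber grouping
  clean <- volume3d(array(100, c(20, 20, 20)), rep(0.3, 3))
  pair <- make_pair(clean, 10, 1, 2)
  res <- lapply(1:3, function(i)
    snr_difference(pair, ((i - 1) * 1000 + 1):(i * 1000),
                   roi_label = paste0("roi", i)))
  expect_identical(aggregate_metric(res, "acquisition")$n, 3L)
})

test_that("the exact signed-rank test matches enumeration and wilcox.test", {
  # all-positive differences of distinct magnitude: W- = 0, p = 2/2^6
  w <- paired_wilcoxon(c(2, 3, 4, 5, 6, 7), rep(1, 6))
  expect_identical(w$statistic, 0)
  expect_equal(w$p_value, 0.03125, tolerance = 1e-12)

  # full-null enumeration oracle at n = 6: compare against every
  # sign-assignment of the absolute differences
  d <- c(1.3, -0.4, 2.2, 0.9, -3.1, 0.5)
  r <- rank(abs(d))
  w_obs <- sum(r[d < 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  null_w <- signs %*% r
  p_le <- mean(null_w <= w_obs)
  p_ge <- mean(null_w >= w_obs)
  p_exact <- min(1, 2 * min(p_le, p_ge))
  got <- paired_wilcoxon(d + 10, rep(10, 6))
  expect_equal(got$p_value, p_exact, tolerance = 1e-12)

  # symmetry under swapping the samples
  set.seed(2); a <- rnorm(10); b <- rnorm(10)
  expect_equal(paired_wilcoxon(a, b)$p_value,
               paired_wilcoxon(b, a)$p_value, tolerance = 1e-12)
  expect_equal(paired_wilcoxon(a, b)$w_pos, paired_wilcoxon(b, a)$w_neg)

  # independent reference implementation on tie-free data
  set.seed(3); a <- rnorm(15); b <- rnorm(15)
  expect_equal(paired_wilcoxon(a, b)$p_value,
               wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)

  # above the exact cutoff the normal approximation tracks wilcox.test
  set.seed(4); a <- rnorm(40); b <- rnorm(40, 0.3)
  expect_equal(paired_wilcoxon(a, b)$p_value,
               wilcox.test(a, b, paired = TRUE, exact = FALSE,
                           correct = TRUE)$p.value,
               tolerance = 1e-6)

  expect_error(paired_wilcoxon(1:6, 1:6), "no variability")
  expect_error(paired_wilcoxon(1:4, 2:5), "at least 5")
})

test_that("score tables aggregate to the published means and totals", {
  tab <- tof_quality_scores()
  expect_equal(score_mean(tab, "7T"), 81 / 28, tolerance = 1e-12)
  expect_equal(score_mean(tab, "3T"), 64 / 28, tolerance = 1e-12)
  expect_equal(round(score_mean(tab, "7T"), 2), 2.89)
  # the 3-T grand mean prints as 2.28 at the table's precision
  expect_lt(abs(score_mean(tab, "3T") - 2.28), 0.01)

  small <- c("lenticulostriate_arteries", "thalamic_perforating_arteries")
  expect_equal(score_mean(tab, "7T", small), 3.50, tolerance = 1e-12)
  expect_equal(score_mean(tab, "3T", small), 1.625, tolerance = 1e-12)
  expect_equal(score_mean(tab, "7T", "pontine_perforating_arteries"), 1)
  expect_equal(score_mean(tab, "3T", "pontine_perforating_arteries"), 0)

  totals_7t <- vapply(1:4, function(v) score_total(tab, v, "7T"), integer(1))
  totals_3t <- vapply(1:4, function(v) score_total(tab, v, "3T"), integer(1))
  expect_identical(totals_7t, c(21L, 23L, 18L, 19L))
  expect_identical(totals_3t, c(20L, 15L, 14L, 15L))

  expect_error(score_mean(tab, "7T", "no_such_vessel"), "unknown")
  zero <- score_table(data.frame(vessel_category = rep(letters[1:7], 2),
                                 volunteer = 1,
                                 field_strength = rep(c("3T", "7T"), each = 7),
                                 score = 0L))
  expect_identical(score_total(zero, 1, "7T"), 0L)
})

test_that("detection rates follow the printed convention", {
  expect_identical(detection_rate(16, 19), 84.2)
  expect_identical(round(detection_rate(27, 32)), 84)
  expect_identical(detection_rate(0, 7), 0)
  expect_error(detection_rate(5, 0), "positive")
  expect_error(detection_rate(8, 7), "n_reference")
})
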