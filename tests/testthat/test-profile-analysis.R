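test_that("min-max normalization maps the window to [0, 1] exactly", {
  ch <- make_gaussian_trace(c(40, 45), c(2, 5))
  nm <- normalize_profile(ch)
  expect_equal(min(nm$abundance), 0)
  expect_equal(max(nm$abundance), 1)
  # affine invariance: a x + c normalizes identically
  aff <- chromatogram(ch$rt, 3.7 * ch$abundance + 11)
  expect_equal(normalize_profile(aff)$abundance, nm$abundance)
  flat <- chromatogram(c(37, 38, 39), c(2, 2, 2))
  expect_error(normalize_profile(flat), "flat")
  expect_error(normalize_profile(ch, window = c(100, 110)), "overlap")
})

test_that("two-Gaussian trace normalizes to its closed-form values", {
  apex <- c(40, 45); h <- c(0.5, 1)
  ch <- make_gaussian_trace(apex, h)
  nm <- normalize_profile(ch)
  # trace minimum is (numerically) 0 far from both peaks, max is h2 at 45
  f <- function(rt) {
    h[1] * exp(-(rt - apex[1])^2 / (2 * 0.02^2)) +
      h[2] * exp(-(rt - apex[2])^2 / (2 * 0.02^2))
  }
  i40 <- which.min(abs(nm$rt - 40))
  expect_equal(nm$abundance[i40], f(nm$rt[i40]) / h[2], tolerance = 1e-9)
})

test_that("peak detection honors threshold and plateau convention", {
  tri <- chromatogram(1:5 / 10 + 36, c(0, 0.5, 1, 0.5, 0))
  tri$normalized <- TRUE
  pk <- find_peaks(tri)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$rt, 36.3)
  low <- chromatogram(1:5 / 10 + 36, c(0, 0.02, 0.05, 0.02, 0))
  low$normalized <- TRUE
  expect_identical(nrow(find_peaks(low)), 0L)
  # plateau apex reports its leftmost point
  plat <- chromatogram(1:6 / 10 + 36, c(0, 0.4, 0.4, 0.4, 0.2, 0))
  plat$normalized <- TRUE
  expect_equal(find_peaks(plat)$rt, 36.2)
  expect_error(find_peaks(make_gaussian_trace(40, 1)), "normalize")
})

test_that("a 12-peak synthetic profile keeps the 9 above-threshold peaks", {
  apex <- seq(37, 48, by = 1)
  h <- c(rep(1, 9), rep(0.05, 3))
  nm <- normalize_profile(make_gaussian_trace(apex, h))
  pk <- find_peaks(nm)
  expect_identical(nrow(pk), 9L)
  expect_true(all(abs(sort(pk$rt) - apex[1:9]) <= 0.011))
})

test_that("binning uses floor((rt - origin)/width) on shared edges", {
  pk <- structure(data.frame(rt = c(42.70, 42.71), abundance = c(1, 2)),
                  class = c("peak_table", "data.frame"))
  bp <- bin_peaks(pk)
  expect_identical(sum(as.numeric(bp) > 0), 1L)  # same 0.03-min bin, summed
  expect_equal(max(as.numeric(bp)), 3)
  pk2 <- structure(data.frame(rt = c(42.70, 42.74), abundance = c(1, 2)),
                   class = c("peak_table", "data.frame"))
  expect_identical(sum(as.numeric(bin_peaks(pk2)) > 0), 2L)
  empty <- structure(data.frame(rt = numeric(0), abundance = numeric(0)),
                     class = c("peak_table", "data.frame"))
  expect_true(all(as.numeric(bin_peaks(empty)) == 0))
})

test_that("cross-correlation similarity is a proper normalized similarity", {
  v <- c(0, 1, 0, 2, 0.5, 0)
  p <- structure(v, bin_width = 0.03, origin = 0, first_bin = 1200,
                 class = "binned_profile")
  q <- structure(c(0, 0, 1, 0, 2, 0.5), bin_width = 0.03, origin = 0,
                 first_bin = 1200, class = "binned_profile")
  expect_equal(xcorr_similarity(p, p), 1)
  # scale invariance
  p2 <- p; p2[] <- 10 * v
  expect_equal(xcorr_similarity(p, p2), 1)
  # disjoint support at zero lag
  d1 <- p; d1[] <- c(1, 1, 0, 0, 0, 0)
  d2 <- p; d2[] <- c(0, 0, 0, 1, 1, 0)
  expect_equal(xcorr_similarity(d1, d2), 0)
  # one-bin shift is recovered when the lag search allows it
  expect_lt(xcorr_similarity(p, q, max_lag = 0), 1)
  expect_equal(xcorr_similarity(p, q, max_lag = 1), 1)
  # symmetry
  expect_equal(xcorr_similarity(p, q, max_lag = 1),
               xcorr_similarity(q, p, max_lag = 1))
  z <- p; z[] <- 0
  expect_error(xcorr_similarity(p, z), "zero-norm")
})

test_that("group comparison separates shared from colony-specific profiles", {
  coh <- gen_cohort(seed = 42)
  res <- run_profile_compare(coh, n_boot = 50, seed = 9)
  expect_gt(res$test$groups$TF$mean, res$test$groups$body$mean)
  expect_lt(res$test$p_value, 0.01)
  # permutation agrees on direction at this effect size
  perm <- compare_groups(res$pairs, method = "permutation")
  expect_lt(perm$p_value, 0.01)
})

test_that("exhaustive permutation returns the smallest attainable p", {
  df <- data.frame(id1 = "a", id2 = "b",
                   similarity = c(0.9, 0.9, 0.9, 0.5, 0.5, 0.5),
                   partition = rep(c("within-TF", "within-body"), each = 3))
  res <- compare_groups(df, method = "permutation")
  expect_true(res$exact)
  expect_equal(res$p_value, 2 / choose(6, 3))
  expect_error(compare_groups(df, method = "welch"), "permutation")
})

test_that("bootstrap clustering joins identical profiles with full support", {
  set.seed(5)
  base <- stats::runif(40)
  m <- cbind(a = base, b = base, c = stats::runif(40))
  cl <- hierarchical_cluster(m, n_boot = 50)
  pair_idx <- which(vapply(seq_along(cl$support), function(i) {
    h <- cl$hclust$merge[i, ]
    all(h < 0) && setequal(cl$hclust$labels[-h[h < 0]], c("a", "b"))
  }, logical(1)))
  expect_length(pair_idx, 1L)
  expect_equal(cl$support[pair_idx], 100)
  # a single replicate still yields a tree with support in {0, 100}
  cl1 <- hierarchical_cluster(m, n_boot = 1)
  expect_true(all(cl1$support %in% c(0, 100)))
  expect_error(hierarchical_cluster(m[, 1:2], n_boot = 10), "at least 3")
})

test_that("body profiles cluster by colony under the default regime", {
  coh <- gen_cohort(seed = 301)
  res <- run_profile_compare(coh, n_boot = 20, seed = 3)
  hc <- res$clustering$hclust
  # body samples are colony-specific: they must not all join before any TF
  labs <- hc$labels
  body <- grep("_body$", labs, value = TRUE)
  tf <- grep("_TF$", labs, value = TRUE)
  # TF samples share most peaks: their average pairwise distance is smaller
  d <- stats::cophenetic(hc)
  dm <- as.matrix(d)
  mean_tf <- mean(dm[tf, tf][upper.tri(dm[tf, tf])])
  mean_body <- mean(dm[body, body][upper.tri(dm[body, body])])
  expect_lt(mean_tf, mean_body)
})

test_that("the profile pipeline is deterministic under a fixed seed", {
  coh <- gen_cohort(seed = 77)
  r1 <- run_profile_compare(coh, n_boot = 25, seed = 11)
  r2 <- run_profile_compare(coh, n_boot = 25, seed = 11)
  expect_identical(r1$test$p_value, r2$test$p_value)
  expect_identical(r1$clustering$support, r2$clustering$support)
  expect_identical(unclass(r1$similarity), unclass(r2$similarity))
})
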