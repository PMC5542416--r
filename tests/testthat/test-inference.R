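test_that("cluster test: flat null data yields no clusters, p-values never 0", {
  set.seed(71)
  tc <- manual_tc(matrix(rnorm(8 * 50, 0, 1), 8, 50))
  res <- sign_permutation_cluster_test(tc, n_perm = 300, seed = 2)
  expect_true(all(res$p_timepoint$p > 0))
  expect_true(all(res$clusters$p_value > 0))
  expect_lte(nrow(res$clusters[res$clusters$significant, ]), 1) # FWER-rare
  zero <- manual_tc(matrix(0, 6, 30))
  expect_equal(nrow(sign_permutation_cluster_test(zero, n_perm = 300)$clusters), 0)
})

test_that("a shared constant effect matches an exhaustive sign-enumeration oracle", {
  # 8 subjects, all 256 sign patterns; per-subject values constant over time
  set.seed(70)
  vals <- 5 + rnorm(8, 0, 0.01)
  tc <- manual_tc(matrix(rep(vals, 40), 8, 40))
  res <- sign_permutation_cluster_test(tc, n_perm = 300, seed = 3)
  expect_true(res$params$exhaustive)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$size, 40) # spans the whole window
  expect_equal(res$clusters$sign, "pos")

  # independent oracle: enumerate the 2^8 sign patterns by hand
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  v <- abs(as.numeric(signs %*% vals) / 8)
  obs <- mean(vals)
  p_obs <- (1 + sum(v >= obs - 1e-12)) / 257
  expect_equal(res$p_timepoint$p, rep(p_obs, 40), tolerance = 1e-12)
  # every permutation's time course is flat, so its max cluster is 40 or 0
  null_max <- ifelse(vapply(v, function(u) sum(v >= u - 1e-12) / 256,
                            numeric(1)) < 0.05, 40, 0)
  expect_equal(sort(res$null_max_size), sort(null_max))
  expect_equal(res$clusters$p_value, (1 + sum(null_max >= 40)) / 257,
               tolerance = 1e-12)
  # the max-size statistic is insensitive to flat effects: about an alpha
  # fraction of sign patterns also span the window, so the cluster p cannot
  # undercut the cluster-definition level here
  expect_equal(res$clusters$significant,
               res$clusters$p_value <= 0.05)
})

test_that("cluster detection is equivariant to time reversal", {
  set.seed(72)
  m <- matrix(rnorm(8 * 60, 0, 1), 8, 60)
  m[, 20:30] <- m[, 20:30] + 3
  tc <- manual_tc(m, times = seq(0, by = 10, length.out = 60))
  tc_rev <- manual_tc(m[, 60:1], times = seq(0, by = 10, length.out = 60))
  a <- sign_permutation_cluster_test(tc, n_perm = 300, seed = 5)
  b <- sign_permutation_cluster_test(tc_rev, n_perm = 300, seed = 5)
  expect_equal(nrow(a$clusters), nrow(b$clusters))
  total <- 590 # start + end mirror around the reversed axis
  expect_equal(sort(total - b$clusters$end_ms), sort(a$clusters$start_ms))
  expect_equal(sort(b$clusters$size), sort(a$clusters$size))
  expect_equal(sort(b$clusters$p_value), sort(a$clusters$p_value))
})

test_that("cluster test guards its permutation resolution", {
  tc <- manual_tc(matrix(rnorm(40), 4, 10))
  expect_error(sign_permutation_cluster_test(tc, n_perm = 10,
                                             cluster_alpha = 0.05),
               "n_perm too small")
})

test_that("bootstrap latencies: identical subjects give zero-width CIs", {
  base <- c(rep(0, 10), 0.2, 1, 3, 6, 8, 6, 3, 1, 0.2, rep(0, 21))
  m <- matrix(rep(base, each = 6), 6, 40)
  tc <- manual_tc(m, times = seq(-100, 290, by = 10))
  est <- bootstrap_latency_ci(tc, n_boot = 30, n_perm = 200, seed = 7)
  expect_equal(est$onset_ci[1], est$onset_ci[2])
  expect_equal(est$peak_ci[1], est$peak_ci[2])
  expect_equal(est$peak, 40) # the bump's peak sits at 40 ms
  expect_equal(est$n_no_cluster, 0)
  expect_lte(est$onset_ci[1], est$onset)
  expect_lte(est$onset, est$onset_ci[2])
})

test_that("bootstrap recovers the peak of a single-bump group effect", {
  set.seed(73)
  times <- seq(-100, 390, by = 10)
  env <- megrsa:::envelope_halfcos(times, 100, 200, 320)
  m <- 4 * matrix(rep(env, each = 8), 8, length(times)) +
    matrix(rnorm(8 * length(times), 0, 0.8), 8)
  tc <- manual_tc(m, times = times)
  est <- bootstrap_latency_ci(tc, n_boot = 100, n_perm = 300, seed = 8)
  expect_lt(abs(est$peak - 200), 40)
  expect_gte(est$onset_ci[2], est$onset)
  expect_true(est$onset >= 100 - 20 && est$onset <= 250)
})

test_that("peak-to-peak difference test localizes a known latency gap", {
  set.seed(74)
  times <- seq(-100, 400, by = 10)
  bump <- function(peak) {
    env <- megrsa:::envelope_halfcos(times, peak - 60, peak, peak + 60)
    5 * matrix(rep(env, each = 8), 8, length(times)) +
      matrix(rnorm(8 * length(times), 0, 0.5), 8)
  }
  a <- manual_tc(bump(250), times = times)
  b <- manual_tc(bump(100), times = times)
  res <- peak_to_peak_difference_test(a, b, n_boot = 200, seed = 9)
  expect_true(res$significant)
  expect_true(res$difference_ci[1] <= 150 && 150 <= res$difference_ci[2])
  # antisymmetry under swapping
  res2 <- peak_to_peak_difference_test(b, a, n_boot = 200, seed = 9)
  expect_equal(res2$difference, -res$difference)
  expect_equal(sort(res2$difference_ci), sort(-res$difference_ci))
  # identical inputs: degenerate at 0, not significant
  res0 <- peak_to_peak_difference_test(a, a, n_boot = 50, seed = 10)
  expect_equal(res0$difference, 0)
  expect_false(res0$significant)
})

test_that("label permutation test separates matching from unrelated models", {
  design <- generate_design(3)
  set.seed(75)
  r <- matrix(rnorm(48 * 48), 48, 48); r <- r + t(r); diag(r) <- 0
  m <- model_rdm(r, conditions = design$condition_id)
  # identical model: minimal attainable p
  res <- label_permutation_test(m, m, n_perm = 200, seed = 11)
  expect_equal(res$rho, 1)
  expect_equal(res$p_value, 1 / 201)
  # unrelated model: p well inside the distribution (single calibrated draw)
  r2 <- matrix(rnorm(48 * 48), 48, 48); r2 <- r2 + t(r2); diag(r2) <- 0
  m2 <- model_rdm(r2, conditions = design$condition_id)
  res2 <- label_permutation_test(m, m2, n_perm = 200, seed = 12)
  expect_gt(res2$p_value, 0.005)
  expect_error(label_permutation_test(
    model_rdm(matrix(0, 4, 4)), model_rdm(matrix(0, 4, 4))), "constant RDM")
})

test_that("label permutation p-values are calibrated under independence", {
  design <- generate_design(1)
  set.seed(76)
  mk <- function() {
    r <- matrix(rnorm(256), 16, 16); r <- r + t(r); diag(r) <- 0
    model_rdm(r, conditions = design$condition_id)
  }
  ps <- replicate(40, label_permutation_test(mk(), mk(), n_perm = 99,
                                             seed = sample.int(1e6, 1))$p_value)
  expect_lt(abs(mean(ps) - 0.5), 3 * 0.29 / sqrt(40))
})

test_that("FDR correction applies the step-up rule", {
  # worked example: 0.01, 0.02, 0.03 survive at q = .05; 0.9 does not
  res <- fdr_correct(c(0.01, 0.02, 0.03, 0.9), q = 0.05)
  expect_equal(res$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$p_adjusted, p.adjust(c(0.01, 0.02, 0.03, 0.9), "BH"))
  expect_true(fdr_correct(0.01, 0.05)$significant)
  expect_false(any(fdr_correct(rep(1, 5))$significant))
  expect_error(fdr_correct(numeric(0)), "empty")
  expect_error(fdr_correct(c(0.5, 1.2)), "in \\[0, 1\\]")
})

test_that("tidy and glance methods expose cluster and latency summaries", {
  set.seed(77)
  m <- matrix(rnorm(6 * 30), 6, 30); m[, 10:20] <- m[, 10:20] + 4
  tc <- manual_tc(m)
  ct <- sign_permutation_cluster_test(tc, n_perm = 200, seed = 13)
  expect_s3_class(tidy(ct), "tbl_df")
  g <- glance(ct)
  expect_equal(g$n_significant, sum(ct$clusters$significant))
  est <- bootstrap_latency_ci(tc, n_boot = 20, n_perm = 200, seed = 14)
  expect_named(glance(est), c("onset_ms", "onset_lo", "onset_hi", "peak_ms",
                              "peak_lo", "peak_hi", "n_no_cluster", "n_boot"))
  expect_equal(nrow(tidy(est)), 20)
})
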