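test_that("subaverage groups trials and preserves the used-trial mean", {
  set.seed(1)
  x <- matrix(rnorm(60 * 4), 60, 4)
  p <- subaverage(x, k = 5, seed = 2)
  expect_equal(dim(p), c(12, 4)) # M = 60, k = 5 -> 12 pseudo-trials
  expect_equal(colMeans(p), colMeans(x)) # all trials used when k | M
  # k = 1: pseudo-trials are a permutation of the raw trials
  p1 <- subaverage(x, k = 1, seed = 3)
  expect_equal(p1[order(p1[, 1]), ], x[order(x[, 1]), ])
  # leftovers dropped: 7 trials, k = 2 -> 3 rows averaging 6 distinct trials
  p2 <- subaverage(x[1:7, ], k = 2, seed = 4)
  expect_equal(dim(p2), c(3, 4))
  expect_error(subaverage(x[1:3, ], k = 5), "fewer trials")
})

test_that("pairwise decoding separates separable classes and stays symmetric", {
  design <- generate_design(1)[1:3, ]
  design$condition_id <- 1:3
  set.seed(5)
  n_tr <- 12; nc <- 6; nt <- 4
  data <- array(rnorm(3 * n_tr * nc * nt, sd = 0.5), c(3 * n_tr, nc, nt))
  # conditions 1 and 2 far apart, condition 3 on top of condition 1
  data[1:n_tr, 1, ] <- data[1:n_tr, 1, ] + 10
  data[n_tr + 1:n_tr, 1, ] <- data[n_tr + 1:n_tr, 1, ] - 10
  data[2 * n_tr + 1:n_tr, 1, ] <- data[2 * n_tr + 1:n_tr, 1, ] + 10
  info <- tibble::tibble(condition_id = rep(1:3, each = n_tr), subject_id = 1)
  ep <- epoch_set(data, times = c(0, 10, 20, 30), info = info)
  rdms <- pairwise_decoding_timecourse(ep, decoding_config(k = 3, n_repetitions = 4,
                                                           seed = 6))
  acc <- rdms$acc
  expect_true(all(acc[1, , 1, 2] == 100)) # margin >> noise
  expect_true(all(acc[1, , 2, 3] == 100))
  expect_true(all(abs(acc[1, , 1, 3] - 50) < 35)) # overlapping classes: chance-ish
  expect_true(all(is.na(acc[1, , 1, 1]))) # undefined diagonal
  expect_equal(acc[1, , , ], aperm(acc[1, , , ], c(1, 3, 2))) # symmetry
})

test_that("null decoding sits at the 50% chance level (3 SE)", {
  set.seed(7)
  accs <- replicate(150, {
    A <- array(rnorm(12 * 16), c(12, 16, 1))
    B <- array(rnorm(12 * 16), c(12, 16, 1))
    cpp <- megrsa:::cpp_pair_loo(A, B, 4L, 1,
                                 megrsa:::perm_matrix(16, 3),
                                 megrsa:::perm_matrix(16, 3))
    cpp[1]
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 50), 3 * se + 1e-9)
})

test_that("accuracy is invariant to channel permutation and rotation", {
  design <- generate_design(1)[1:2, ]
  design$condition_id <- 1:2
  set.seed(8)
  data <- array(rnorm(2 * 10 * 8 * 3), c(20, 8, 3))
  data[1:10, 2, ] <- data[1:10, 2, ] + 1.5
  info <- tibble::tibble(condition_id = rep(1:2, each = 10), subject_id = 1)
  ep <- epoch_set(data, c(0, 10, 20), info)
  cfg <- decoding_config(k = 2, n_repetitions = 3, seed = 11)
  base <- pairwise_decoding_timecourse(ep, cfg)$acc[1, , 1, 2]

  perm <- sample(8)
  ep_p <- epoch_set(data[, perm, ], ep$times, info)
  expect_equal(pairwise_decoding_timecourse(ep_p, cfg)$acc[1, , 1, 2], base)

  rot <- qr.Q(qr(matrix(rnorm(64), 8, 8))) # orthonormal channel mixing
  dr <- data
  for (t in 1:3) dr[, , t] <- data[, , t] %*% rot
  ep_r <- epoch_set(dr, ep$times, info)
  expect_equal(pairwise_decoding_timecourse(ep_r, cfg)$acc[1, , 1, 2], base,
               tolerance = 1e-6)
})

test_that("leave-one-out decoding matches an exhaustive fold-loop oracle", {
  # small instance: 4 pseudo-trials per class, 2 channels, replicated in R
  set.seed(13)
  nA <- 8; nB <- 8; k <- 2; d <- 2; nt <- 3
  A <- array(rnorm(d * nA * nt), c(d, nA, nt))
  B <- array(rnorm(d * nB * nt, mean = 0.8), c(d, nB, nt))
  pA <- megrsa:::perm_matrix(nA, 2)
  pB <- megrsa:::perm_matrix(nB, 2)
  got <- as.numeric(megrsa:::cpp_pair_loo(A, B, as.integer(k), 1, pA, pB))

  P <- nA %/% k
  oracle <- numeric(nt)
  for (rep in 1:2) {
    for (t in 1:nt) {
      PA <- sapply(1:P, function(p) rowMeans(A[, pA[((p - 1) * k + 1):(p * k), rep], t]))
      PB <- sapply(1:P, function(p) rowMeans(B[, pB[((p - 1) * k + 1):(p * k), rep], t]))
      correct <- 0
      for (f in 1:P) {
        Xtr <- t(cbind(PA[, -f], PB[, -f]))
        y <- c(rep(1L, P - 1), rep(-1L, P - 1))
        fv <- megrsa:::cpp_svm_decision(Xtr, y, 1, t(cbind(PA[, f], PB[, f])))
        correct <- correct + (fv[1] >= 0) + (fv[2] < 0)
      }
      oracle[t] <- oracle[t] + 100 * correct / (2 * P)
    }
  }
  expect_equal(got, oracle / 2, tolerance = 1e-9)
})

test_that("the SMO solver agrees with libsvm on random problems", {
  set.seed(17)
  agree <- 0; total <- 0
  for (i in 1:20) {
    n <- sample(4:9, 1); d <- sample(2:5, 1)
    X <- rbind(matrix(rnorm(n * d, 1), n), matrix(rnorm(n * d, -1), n))
    y <- c(rep(1L, n), rep(-1L, n))
    Xte <- matrix(rnorm(10 * d), 10)
    f <- megrsa:::cpp_svm_decision(X, y, 1, Xte)
    m <- e1071::svm(X, factor(y, levels = c(1, -1)), kernel = "linear",
                    cost = 1, scale = FALSE)
    dv <- as.numeric(attr(predict(m, Xte, decision.values = TRUE),
                          "decision.values"))
    agree <- agree + sum((f >= 0) == (dv >= 0)); total <- total + 10
  }
  expect_gte(agree / total, 0.98)
})

test_that("matched-exemplar averaging pools exactly the factor-matched cells", {
  design <- generate_design(3)
  # brute-force enumeration of matched pairs: 16 combos x choose(3,2) = 48
  n_matched <- 0
  for (i in 1:47) for (j in (i + 1):48) {
    same <- all(design[i, design_factors()] == design[j, design_factors()])
    n_matched <- n_matched + same
  }
  expect_equal(n_matched, 48)

  acc <- array(50, c(2, 3, 48, 48))
  for (s in 1:2) for (t in 1:3) diag(acc[s, t, , ]) <- NA
  # raise exactly the matched cells to 55: time course must read 55
  for (i in 1:47) for (j in (i + 1):48) {
    if (all(design[i, design_factors()] == design[j, design_factors()])) {
      acc[, , i, j] <- 55; acc[, , j, i] <- 55
    }
  }
  rdms <- manual_rdms(acc, conditions = design$condition_id)
  tc <- factor_average_decoding(rdms, design)
  expect_true(all(tc$value == 55))
  expect_equal(nrow(tc), 2 * 3)
})

test_that("cross-classification pools 720 raw vectors per class at full scale", {
  design <- generate_design(3)
  info <- tibble::tibble(condition_id = rep(design$condition_id, each = 60),
                         subject_id = 1)
  dd <- design[match(info$condition_id, design$condition_id), ]
  sel <- dd$size == "small" & dd$clutter == "high"
  expect_equal(sum(sel), 720) # 12 images x 60 trials
  # and the identity split feeds 16 factor-level combinations
  combos <- dplyr::distinct(design[design_factors()])
  expect_equal(nrow(combos), 16)
})

test_that("cross-decoding generalizes iff the pattern is shared across levels", {
  design <- generate_design(1)
  times <- seq(-100, 300, by = 20)
  shared <- signal_spec(signal_effect("size", 100, 180, 300, 500))
  ep_s <- preprocess(tiny_epochs(design, n_subjects = 3, n_trials = 20,
                                 n_channels = 16, times = times, seed = 31,
                                 signal = shared))
  cfg <- decoding_config(k = 60, n_repetitions = 4, seed = 32)
  tc <- cross_decoding_timecourse(ep_s, design, "size", "clutter", cfg)
  post <- dplyr::filter(tc, time_ms >= 160, time_ms <= 260)
  pre <- dplyr::filter(tc, time_ms < 60)
  expect_gt(mean(post$value), 85)
  expect_lt(abs(mean(pre$value) - 50), 15)

  # no injected effect: accuracy stays at chance
  ep_n <- preprocess(tiny_epochs(design, n_subjects = 3, n_trials = 20,
                                 n_channels = 16, times = times, seed = 33))
  tc_n <- cross_decoding_timecourse(ep_n, design, "size", "clutter", cfg)
  expect_lt(abs(mean(tc_n$value) - 50), 6)
  expect_error(cross_decoding_timecourse(ep_n, design, "size", "size", cfg),
               "must differ")
})

test_that("identity cross-decoding needs shared factor structure, not image codes", {
  design <- generate_design(3)
  times <- seq(-100, 260, by = 20)
  cfg <- decoding_config(k = 60, n_repetitions = 3, seed = 41)

  # condition-unique patterns only: generalization across exemplars must fail
  ident <- signal_spec(signal_effect("identity", 100, 160, 260, 500))
  ep_i <- preprocess(tiny_epochs(design, n_subjects = 2, n_trials = 10,
                                 n_channels = 16, times = times, seed = 42,
                                 signal = ident))
  tc_i <- identity_cross_decoding(ep_i, design, "size", cfg)
  # a single realization of condition-unique patterns carries a fixed
  # geometric bias, so the curve hovers near (not exactly at) chance and
  # never approaches the shared-pattern regime
  post_i <- dplyr::filter(tc_i, time_ms >= 140, time_ms <= 220)
  expect_lt(mean(post_i$value), 75)
  pre_i <- dplyr::filter(tc_i, time_ms < 60)
  expect_lt(abs(mean(pre_i$value) - 50), 12)

  # shared size pattern: generalization succeeds after onset
  shared <- signal_spec(signal_effect("size", 100, 160, 260, 500))
  ep_s <- preprocess(tiny_epochs(design, n_subjects = 2, n_trials = 10,
                                 n_channels = 16, times = times, seed = 43,
                                 signal = shared))
  tc_s <- identity_cross_decoding(ep_s, design, "size", cfg)
  post <- dplyr::filter(tc_s, time_ms >= 140, time_ms <= 220)
  expect_gt(mean(post$value), 80)
  expect_gt(mean(post$value), mean(post_i$value) + 10)

  expect_error(identity_cross_decoding(ep_s, generate_design(2), "size", cfg),
               "3 exemplars")
})
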