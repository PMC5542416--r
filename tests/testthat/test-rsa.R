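test_that("explicit factor model RDM is binary with the right disagreement count", {
  design <- generate_design(3)
  m <- factor_model_rdm(design, "size")
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(diag(m) == 0))
  expect_true(all(m %in% c(0, 1)))
  # brute force: each condition differs from the 24 opposite-level conditions
  n_ones <- 0
  for (i in 1:48) for (j in 1:48) {
    if (i != j && design$size[i] != design$size[j]) n_ones <- n_ones + 1
  }
  expect_equal(sum(m), n_ones)
  expect_equal(sum(m), 48 * 24)
  expect_error(factor_model_rdm(design, "banana"), "unknown factor")

  # degenerate single-level factor -> all zeros
  d1 <- design; d1$clutter <- "low"
  expect_true(all(factor_model_rdm(d1, "clutter") == 0))
})

test_that("feature RDM is 1 - Spearman and matches a rank-then-Pearson oracle", {
  set.seed(51)
  f <- feature_set(matrix(rnorm(6 * 20), 6, 20), layer = "test")
  m <- feature_rdm(f)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(m[i, j], 1 - spearman_oracle(f[i, ], f[j, ]),
                 tolerance = 1e-12)
  }
  # identical vectors -> 0; exactly reversed rank order -> 2
  x <- seq_len(10)
  f2 <- feature_set(rbind(x, x, rev(x)))
  m2 <- feature_rdm(f2)
  expect_equal(m2[1, 2], 0)
  expect_equal(m2[1, 3], 2)
  # rank-based: invariant to strictly monotone transforms
  f3 <- feature_set(rbind(exp(f[1, ]), f[2, ]^3 + 5 * f[2, ]))
  m3 <- feature_rdm(feature_set(rbind(f[1, ], f[2, ])))
  expect_equal(feature_rdm(f3)[1, 2], m3[1, 2], tolerance = 1e-12)
  expect_error(feature_rdm(feature_set(rbind(x, rep(1, 10)))), "constant")
})

test_that("clustering time course averages between minus within cells", {
  # 4-condition toy: between cells 60, within 55 -> statistic 5
  design <- generate_design(1)[c(1, 5, 9, 13), ] # varies only in size/clutter
  design$condition_id <- 1:4
  lev <- design$size
  acc <- array(NA_real_, c(1, 2, 4, 4))
  for (i in 1:4) for (j in 1:4) {
    if (i != j) acc[, , i, j] <- ifelse(lev[i] != lev[j], 60, 55)
  }
  rdms <- manual_rdms(acc, conditions = 1:4)
  tc <- clustering_timecourse(rdms, design, "size")
  expect_true(all(tc$value == 5))
  # constant RDM -> 0
  acc0 <- acc; acc0[!is.na(acc0)] <- 52
  expect_true(all(clustering_timecourse(manual_rdms(acc0, conditions = 1:4),
                                        design, "size")$value == 0))
})

test_that("clustering and the model-correlation variant agree in sign", {
  design <- generate_design(1)
  set.seed(53)
  # RDMs with a genuine (noisy) size effect of varying polarity over time
  acc <- array(NA_real_, c(1, 6, 16, 16))
  size_diff <- outer(design$size, design$size, "!=")
  effects <- c(-3, -1.5, -0.5, 0.5, 1.5, 3)
  for (t in 1:6) {
    base <- matrix(rnorm(16 * 16, 50, 0.2), 16, 16)
    base <- (base + t(base)) / 2 + effects[t] * size_diff
    diag(base) <- NA
    acc[1, t, , ] <- base
  }
  rdms <- manual_rdms(acc, conditions = design$condition_id)
  cl <- clustering_timecourse(rdms, design, "size")
  rs <- rsa_timecourse(rdms, factor_model_rdm(design, "size"))
  expect_equal(sign(cl$value), sign(rs$value))
})

test_that("clustering has zero expectation under exchangeable condition labels", {
  design <- generate_design(1)
  set.seed(54)
  vals <- replicate(200, {
    acc <- array(NA_real_, c(1, 1, 16, 16))
    m <- matrix(rnorm(256, 50, 5), 16, 16)
    m <- (m + t(m)) / 2; diag(m) <- NA
    acc[1, 1, , ] <- m
    perm <- sample(16)
    d2 <- design; d2$size <- design$size[perm]
    clustering_timecourse(manual_rdms(acc, conditions = design$condition_id),
                          d2, "size")$value
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("RSA time course hits +/-1 for (anti)matching models", {
  set.seed(55)
  n <- 12
  m <- matrix(rnorm(n * n, 50), n, n); m <- (m + t(m)) / 2; diag(m) <- NA
  acc <- array(NA_real_, c(1, 2, n, n))
  acc[1, 1, , ] <- m
  acc[1, 2, , ] <- m
  rdms <- manual_rdms(acc, conditions = 1:n)
  model <- m; diag(model) <- 0
  expect_equal(rsa_timecourse(rdms, model_rdm(model, conditions = 1:n))$value,
               c(1, 1))
  anti <- max(m, na.rm = TRUE) - m; diag(anti) <- 0
  expect_equal(rsa_timecourse(rdms, model_rdm(anti, conditions = 1:n))$value,
               c(-1, -1))
  # random model matches the rank-correlation oracle
  r <- matrix(rnorm(n * n), n, n); r <- r + t(r); diag(r) <- 0
  got <- rsa_timecourse(rdms, model_rdm(r, conditions = 1:n))$value[1]
  expect_equal(got, spearman_oracle(m[lower.tri(m)], r[lower.tri(r)]),
               tolerance = 1e-12)
  expect_error(rsa_timecourse(rdms, model_rdm(matrix(0, n, n), conditions = 1:n)),
               "constant model RDM")
})

test_that("multi-layer models average per-layer correlations", {
  set.seed(56)
  n <- 8
  m <- matrix(rnorm(n * n, 50), n, n); m <- (m + t(m)) / 2; diag(m) <- NA
  acc <- array(NA_real_, c(1, 1, n, n)); acc[1, 1, , ] <- m
  rdms <- manual_rdms(acc, conditions = 1:n)
  mk <- function() {
    r <- matrix(rnorm(n * n), n, n); r <- r + t(r); diag(r) <- 0
    model_rdm(r, conditions = 1:n)
  }
  l1 <- mk(); l2 <- mk()
  avg <- rsa_timecourse(rdms, list(l1, l2))$value
  expect_equal(avg, (rsa_timecourse(rdms, l1)$value +
                       rsa_timecourse(rdms, l2)$value) / 2)
})

test_that("partial Spearman reduces to closed forms", {
  set.seed(57)
  x <- rnorm(40); y <- rnorm(40); z <- rnorm(40)
  # empty nuisance: plain Spearman
  expect_equal(partial_spearman(x, y), cor(x, y, method = "spearman"))
  # single nuisance: the textbook partial-correlation identity on ranks
  rxy <- cor(rank(x), rank(y)); rxz <- cor(rank(x), rank(z))
  rzy <- cor(rank(z), rank(y))
  expect_equal(partial_spearman(x, y, list(z)),
               (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2)),
               tolerance = 1e-10)
  # y in the nuisance set: nothing left to correlate
  expect_lt(abs(partial_spearman(x, y, list(y))), 1e-10)
  # collinear nuisance columns are dropped with a message
  expect_message(v <- partial_spearman(x, y, list(z, z)), "collinear")
  expect_equal(v, partial_spearman(x, y, list(z)), tolerance = 1e-12)
  expect_error(partial_spearman(x, y[1:10], list(z)), "same length")
})

test_that("partial RSA removes nuisance structure and spares orthogonal targets", {
  design <- generate_design(3)
  target <- factor_model_rdm(design, "size")
  nuis <- factor_model_rdm(design, "luminance")
  set.seed(58)
  n <- 48
  noise <- matrix(rnorm(n * n, 0, 0.3), n, n)
  base <- 50 + 2 * outer(design$size, design$size, "!=") + (noise + t(noise)) / 2
  diag(base) <- NA
  acc <- array(NA_real_, c(1, 1, n, n)); acc[1, 1, , ] <- base
  rdms <- manual_rdms(acc, conditions = design$condition_id)

  # partialling out the target itself kills the effect
  expect_lt(abs(partial_rsa_timecourse(rdms, target, list(target))$value), 0.05)
  # a (near-)orthogonal nuisance leaves the RSA curve essentially unchanged
  plain <- rsa_timecourse(rdms, target)$value
  part <- partial_rsa_timecourse(rdms, target, list(nuis))$value
  expect_equal(part, plain, tolerance = 0.02)

  # MEG RDM built purely from nuisance structure: target effect vanishes
  base2 <- 50 + 2 * outer(design$luminance, design$luminance, "!=") +
    (noise + t(noise)) / 2
  diag(base2) <- NA
  acc2 <- array(NA_real_, c(1, 1, n, n)); acc2[1, 1, , ] <- base2
  rdms2 <- manual_rdms(acc2, conditions = design$condition_id)
  with_nuis <- partial_rsa_timecourse(rdms2, target, list(nuis))$value
  expect_lt(abs(with_nuis), 0.05)
})

test_that("RDM statistics are invariant to simultaneous condition reordering", {
  design <- generate_design(1)
  set.seed(59)
  m <- matrix(rnorm(256, 50, 2), 16, 16); m <- (m + t(m)) / 2; diag(m) <- NA
  acc <- array(NA_real_, c(1, 1, 16, 16)); acc[1, 1, , ] <- m
  rdms <- manual_rdms(acc, conditions = design$condition_id)
  model <- factor_model_rdm(design, "size")

  perm <- sample(16)
  design_p <- design[perm, ]
  acc_p <- acc[, , perm, perm, drop = FALSE]
  rdms_p <- manual_rdms(acc_p, conditions = design_p$condition_id)
  model_p <- factor_model_rdm(design_p, "size")

  expect_equal(rsa_timecourse(rdms_p, model_p)$value,
               rsa_timecourse(rdms, model)$value, tolerance = 1e-12)
  expect_equal(clustering_timecourse(rdms_p, design_p, "size")$value,
               clustering_timecourse(rdms, design, "size")$value,
               tolerance = 1e-12)
})

test_that("model RDMs round-trip through CSV", {
  design <- generate_design(1)
  m <- factor_model_rdm(design, "contrast")
  path <- withr::local_tempfile(fileext = ".csv")
  write_model_rdm(m, path)
  back <- read_model_rdm(path, source = "contrast", semantics = "binary")
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)
})
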