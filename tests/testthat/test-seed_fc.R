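test_that("seed series is the cluster mean over concatenated runs", {
  r1 <- rbind(c(1, 2, 3), c(4, 5, 6), c(0, 0, 0))
  r2 <- rbind(c(7, 8), c(9, 10), c(1, 1))
  # 1-voxel cluster: that voxel's series, runs concatenated in order
  expect_equal(seed_series(list(r1, r2), 2), c(4, 5, 6, 9, 10))
  # two voxels with series y and -y cancel
  y <- c(1, -2, 3)
  expect_equal(seed_series(list(rbind(y, -y)), 1:2), c(0, 0, 0))
  expect_length(seed_series(list(r1, r2), c(1, 2)), 5)
  expect_error(seed_series(list(r1), integer(0)), "empty")
})

test_that("seed GLM maps are Fisher-z of the voxel-seed correlation", {
  set.seed(6)
  seed <- rnorm(40)
  ts <- rbind(seed,                       # identical: clipped large finite z
              rnorm(40),                  # unrelated
              2 * seed + 5)               # affine copy: r = 1
  z <- seed_glm(ts, seed)
  expect_true(is.finite(z[1]) && z[1] > 7)  # atanh(1 - 1e-7)
  expect_equal(z[1], z[3])
  expect_lt(abs(z[2]), 0.5)

  # orthogonal voxel -> z = 0
  ortho <- rnorm(40)
  ortho <- ortho - seed * sum(ortho * seed) / sum(seed^2)
  ortho <- ortho - mean(ortho) + 0      # also remove mean alignment
  ortho <- ortho - seed * sum(ortho * (seed - mean(seed))) / sum((seed - mean(seed))^2)
  zo <- seed_glm(rbind(ortho), seed)
  expect_lt(abs(zo), 0.05)

  # 5-timepoint toy pair matches hand-computed atanh(r)
  a <- c(1, 3, 2, 5, 4); s <- c(2, 2, 3, 5, 5)
  am <- a - mean(a); sm <- s - mean(s)
  r_hand <- sum(am * sm) / sqrt(sum(am^2) * sum(sm^2))
  expect_equal(seed_glm(rbind(a), s), atanh(r_hand), tolerance = 1e-12)
  expect_error(seed_glm(rbind(a), rep(1, 5)), "constant")
})

test_that("group t-maps match the hand t formula", {
  # values (1,2,3,4): t = 2.5 / (1.2910/2) = 3.873
  zm <- matrix(c(1, 2, 3, 4), ncol = 1)
  st <- group_one_sample_t(zm)
  expect_equal(st$t, 3.873, tolerance = 1e-3)
  expect_equal(st$t, mean(1:4) / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(st$df, 3L)
  # cross-check p against t.test
  expect_equal(st$p, t.test(c(1, 2, 3, 4))$p.value, tolerance = 1e-12)

  sym <- group_one_sample_t(matrix(c(-1, 0, 1), ncol = 1))
  expect_equal(sym$t, 0)

  zv <- group_one_sample_t(matrix(c(1, 1, 1), ncol = 1))
  expect_true(zv$zero_var)
  expect_true(is.na(zv$t))
  expect_error(group_one_sample_t(matrix(1:2, ncol = 1)), "3 subjects")
})

test_that("paired t is the one-sample t of differences, antisymmetric", {
  set.seed(10)
  A <- matrix(rnorm(4 * 6), 4)
  B <- matrix(rnorm(4 * 6), 4)
  pt <- group_paired_t(A, B)
  expect_equal(pt$t, group_one_sample_t(A - B)$t, tolerance = 1e-12)
  expect_equal(group_paired_t(B, A)$t, -pt$t, tolerance = 1e-12)
  expect_true(all(group_paired_t(A, A)$zero_var))
  # 4-subject toy differences (1,2,3,4)
  expect_equal(group_paired_t(matrix(c(2, 4, 6, 8), ncol = 1),
                              matrix(c(1, 2, 3, 4), ncol = 1))$t,
               3.873, tolerance = 1e-3)
  expect_error(group_paired_t(A, B[1:3, ]), "mismatch")
})

test_that("voxel-height FWE behaves at its boundaries and under permutation", {
  set.seed(12)
  Z <- matrix(rnorm(8 * 30), 8, 30)
  Z[, 1] <- Z[, 1] + 3                   # one strong voxel
  st <- group_one_sample_t(Z)

  bon <- fwe_voxel_threshold(st, alpha = 0.05, method = "bonferroni")
  expect_true(bon$mask[1])
  expect_equal(bon$cutoff, 0.05 / 30)

  # alpha = 1 keeps any p <= 1/m
  b1 <- fwe_voxel_threshold(st, alpha = 1, method = "bonferroni")
  expect_equal(b1$cutoff, 1 / 30)
  expect_true(all(b1$mask == (st$p <= 1 / 30)))

  # single-voxel map reduces to the ordinary t test
  st1 <- group_one_sample_t(Z[, 1, drop = FALSE])
  one <- fwe_voxel_threshold(st1, alpha = 0.05, method = "bonferroni")
  expect_equal(one$mask[1], st1$p <= 0.05)

  pm <- fwe_voxel_threshold(st, alpha = 0.05, method = "perm_maxt",
                            z_maps = Z, n_perm = 500, seed = 4)
  expect_true(pm$mask[1])
  pm2 <- fwe_voxel_threshold(st, alpha = 0.05, method = "perm_maxt",
                             z_maps = Z, n_perm = 500, seed = 4)
  expect_identical(pm$cutoff, pm2$cutoff)
})

test_that("contrast masking keeps direction-matched significant voxels only", {
  contrast <- c(2.5, -3, 1.2)
  # empty mask -> empty output
  expect_equal(mask_contrast(contrast, c(0, 0, 0)), c(0, 0, 0))
  # full matching-direction mask -> unchanged contrast
  expect_equal(mask_contrast(contrast, c(4, -4, 4)), contrast)
  # intersection semantics on a 3-voxel toy: voxel 2 dropped (direction
  # mismatch), voxel 3 dropped (not significant)
  expect_equal(mask_contrast(contrast, c(4, 4, 0)), c(2.5, 0, 0))
  expect_error(mask_contrast(contrast, c(1, 2)), "mismatch")
})

test_that("planted seeds produce the expected contrast direction across seeds", {
  # cluster A is built from the high-w end (signal s1); the A>B paired
  # contrast must be higher at high-w voxels than at low-w voxels
  diffs <- numeric(4)
  for (s in 1:4) {
    cfg <- tiny_config(structure = "graded_1d", noise_sd = 0.5,
                       n_subjects = 5L, seed = 100L + s)
    sim <- simulate_timeseries(cfg)
    w <- planted_weights(cfg)$w1
    hi <- order(w, decreasing = TRUE)[1:10]
    lo <- order(w)[1:10]
    Zs <- lapply(sim$subjects, function(runs) {
      Y <- do.call(cbind, lapply(runs, roi_timeseries, roi = sim$roi))
      list(zh = seed_glm(Y, seed_series(list(Y), hi)),
           zl = seed_glm(Y, seed_series(list(Y), lo)))
    })
    pt <- group_paired_t(t(sapply(Zs, `[[`, "zh")), t(sapply(Zs, `[[`, "zl")))
    topw <- w >= quantile(w, 2 / 3); botw <- w <= quantile(w, 1 / 3)
    diffs[s] <- mean(pt$t[topw]) - mean(pt$t[botw])
  }
  expect_true(all(diffs > 0))
  expect_lt(t.test(diffs, alternative = "greater")$p.value, 0.01)
})
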