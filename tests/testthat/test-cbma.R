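toy_db <- function() {
  studies <- data.frame(study_id = c("s1", "s2", "s3"),
                        n_subjects = c(15, 25, 40))
  foci <- data.frame(study_id = c("s1", "s1", "s2", "s3"),
                     x = c(0, 10, 6, 20), y = c(0, 0, 0, 0), z = c(0, 0, 0, 0))
  coordinate_db(studies, foci)
}

test_that("study selection uses a closed 6-mm ball", {
  db <- toy_db()
  expect_true("s1" %in% select_studies(db, c(0, 0, 0)))        # distance 0
  expect_true("s2" %in% select_studies(db, c(0, 0, 0)))        # exactly 6.0
  expect_false("s3" %in% select_studies(db, c(14, 0, 0), 5.99)) # 6.01-like
  expect_true("s3" %in% select_studies(db, c(14, 0, 0), 6))
  expect_warning(sel <- select_studies(db, c(500, 500, 500)), "no studies")
  expect_length(sel, 0)
})

test_that("kernel width shrinks with sample size per the uncertainty model", {
  expect_gt(kernel_sigma(10), kernel_sigma(20))
  expect_gt(kernel_sigma(20), kernel_sigma(50))
  # fixed-FWHM override
  expect_equal(kernel_sigma(10, fixed_fwhm_mm = 10), 10 / 2.35482,
               tolerance = 1e-5)
  # doubling n shrinks the between-subject FWHM component by sqrt(2):
  # recover the subject component from the implemented model and compare
  f2s <- sqrt(8 * log(2))
  total_fwhm <- function(n) kernel_sigma(n) * f2s
  tmpl <- 5.7 / (2 * sqrt(2 / pi)) * f2s
  subj2 <- function(n) total_fwhm(n)^2 - tmpl^2
  expect_equal(subj2(10) / subj2(20), 2, tolerance = 1e-10)
})

test_that("MA maps combine foci by maximum", {
  grid <- ale_grid(c(-20, -8, -8), c(40, 8, 8), 4)
  sg <- kernel_sigma(20)

  single <- ma_map(rbind(c(0, 0, 0)), sg, grid)
  at <- function(m, p) m[which(grid$mm[, 1] == p[1] & grid$mm[, 2] == p[2] &
                                 grid$mm[, 3] == p[3])]
  expect_equal(which.max(single),
               which(grid$mm[, 1] == 0 & grid$mm[, 2] == 0 & grid$mm[, 3] == 0))

  # coincident duplicate foci collapse under max
  dup <- ma_map(rbind(c(0, 0, 0), c(0, 0, 0)), sg, grid)
  expect_equal(dup, single, tolerance = 1e-14)

  # far-apart foci: each peak equals the single-focus value
  two <- ma_map(rbind(c(0, 0, 0), c(32, 0, 0)), sg, grid)
  expect_equal(at(two, c(0, 0, 0)), at(single, c(0, 0, 0)), tolerance = 1e-12)
  expect_equal(at(two, c(32, 0, 0)), at(single, c(0, 0, 0)), tolerance = 1e-12)
  expect_true(all(two >= 0 & two < 1))
})

test_that("ALE is the probabilistic union of MA maps", {
  expect_equal(ale(rbind(c(0.5, 0.1), c(0.5, 0.2))), c(0.75, 1 - 0.9 * 0.8),
               tolerance = 1e-12)
  ma1 <- rbind(c(0.3, 0.2, 0))
  expect_equal(ale(ma1), as.numeric(ma1))          # one study: ALE = MA
  set.seed(4)
  M <- matrix(runif(5 * 20, 0, 0.6), 5, 20)
  a <- ale(M)
  expect_true(all(a >= apply(M, 2, max) - 1e-12))  # union dominates parts
  expect_equal(ale(M[sample(5), ]), a, tolerance = 1e-12)  # order invariant
  expect_true(all(ale(rbind(M, runif(20, 0, 0.5))) >= a - 1e-12)) # monotone
})

test_that("voxelwise MACM keeps per-voxel provenance and neighbour structure", {
  cfg <- tiny_config(n_studies = 30L, seed = 5L)
  out <- simulate_coordinate_db(cfg)
  roi <- make_roi(cfg$dims)
  grid <- grid_for_db(out$db, roi, 6)
  mv <- macm_voxelwise(out$db, roi, grid)
  expect_equal(nrow(mv$maps), roi$n_voxels)
  expect_length(mv$selections, roi$n_voxels)

  # two adjacent voxels differ only by studies whose nearest focus falls in
  # the 6-mm shell between them (geometric brute force)
  for (v in c(1L, 25L)) {
    u <- v + 1L                          # +2 mm along the first axis
    dmin <- function(p) tapply(
      (out$db$foci$x - p[1])^2 + (out$db$foci$y - p[2])^2 +
        (out$db$foci$z - p[3])^2,
      out$db$foci$study_id, min)
    dv <- dmin(roi$mm[v, ]); du <- dmin(roi$mm[u, ])
    expected_v <- sort(names(dv)[dv <= 36])
    expected_u <- sort(names(du)[du <= 36])
    expect_identical(sort(mv$selections[[v]]), expected_v)
    expect_identical(sort(mv$selections[[u]]), expected_u)
  }

  # seed covering all foci selects every study
  allseed <- brain_vol(array(1, c(80, 80, 80)),
                       { a <- diag(c(4, 4, 4, 1)); a[1:3, 4] <- c(-150, -150, -150); a })
  expect_setequal(select_studies_in_mask(out$db, allseed),
                  as.character(out$db$studies$study_id))
})

test_that("FWE thresholding is trivial at alpha 1 and detects planted convergence", {
  grid <- ale_grid(c(0, 0, 0), c(28, 28, 28), 4)
  studies <- data.frame(study_id = sprintf("p%02d", 1:20),
                        n_subjects = rep(20, 20))
  foci <- data.frame(study_id = studies$study_id, x = 12, y = 12, z = 12)
  db <- coordinate_db(studies, foci)
  a <- ale(ma_maps(db, grid))
  thr1 <- ale_fwe_threshold(a, db, grid, n_iter = 100, alpha = 1, seed = 2)
  expect_equal(thr1$threshold, 0)
  expect_equal(thr1$thresholded, a)

  # 20 studies converging on one focus must survive FWE at 0.05
  thr <- ale_fwe_threshold(a, db, grid, n_iter = 200, alpha = 0.05, seed = 2)
  peak <- which(grid$mm[, 1] == 12 & grid$mm[, 2] == 12 & grid$mm[, 3] == 12)
  expect_gt(thr$thresholded[peak], 0)

  # reproducible under a fixed seed
  thr2 <- ale_fwe_threshold(a, db, grid, n_iter = 200, alpha = 0.05, seed = 2)
  expect_identical(thr$null_max, thr2$null_max)
  expect_error(ale_fwe_threshold(a, db, grid, n_iter = 50), ">= 100")
})

test_that("ALE contrasts are antisymmetric and null for identical selections", {
  cfg <- tiny_config(n_studies = 24L, foci_in = 0L, seed = 6L)
  out <- simulate_coordinate_db(cfg)
  nets <- out$truth$network
  ids_a <- names(nets)[nets == "A"]; ids_b <- names(nets)[nets == "B"]
  grid <- grid_for_db(out$db, spacing_mm = 6)

  same <- ale_contrast(out$db, ids_a, ids_a, grid, n_perm = 100)
  expect_true(all(same$diff == 0))
  expect_true(all(same$contrast == 0))

  ab <- ale_contrast(out$db, ids_a, ids_b, grid, n_perm = 200, seed = 3)
  ba <- ale_contrast(out$db, ids_b, ids_a, grid, n_perm = 200, seed = 3)
  expect_equal(ab$diff, -ba$diff, tolerance = 1e-12)

  # planted disjoint clouds: each network's core is significant in its
  # own direction
  coreA <- which.max(ab$diff); coreB <- which.min(ab$diff)
  expect_lt(ab$p_a_gt_b[coreA], 0.05)
  expect_lt(ab$p_b_gt_a[coreB], 0.05)
})
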