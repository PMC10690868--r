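#' Analysis grid for coordinate-based meta-analysis
#'
#' A regular isotropic grid of voxel centres covering a bounding box, used
#' as the "brain" for MA/ALE maps. Synthetic work uses a coarse default
#' spacing so that voxelwise MACM over a few hundred seeds stays cheap.
#'
#' @param lower,upper mm corners of the box (inclusive; snapped to spacing).
#' @param spacing_mm isotropic voxel size in mm.
#' @return an `ale_grid`: list with `mm` (n x 3 voxel centres), `dims`,
#'   `affine`, `spacing`.
#' @export
ale_grid <- function(lower, upper, spacing_mm = 4) {
  stopifnot(spacing_mm > 0, all(upper >= lower))
  lo <- floor(lower / spacing_mm) * spacing_mm
  hi <- ceiling(upper / spacing_mm) * spacing_mm
  ax <- lapply(1:3, function(i) seq(lo[i], hi[i], by = spacing_mm))
  dims <- vapply(ax, length, integer(1))
  mm <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                              KEEP.OUT.ATTRS = FALSE))
  aff <- diag(c(spacing_mm, spacing_mm, spacing_mm, 1))
  aff[1:3, 4] <- lo
  structure(list(mm = mm, dims = dims, affine = aff, spacing = spacing_mm),
            class = "ale_grid")
}

#' Grid covering a coordinate database and an ROI
#'
#' @param db a `coordinate_db`.
#' @param roi an [roi_mask] (optional; included in the bounding box).
#' @param spacing_mm grid spacing in mm.
#' @param pad_mm padding added around the bounding box.
#' @return an `ale_grid`.
#' @export
grid_for_db <- function(db, roi = NULL, spacing_mm = 4, pad_mm = 8) {
  pts <- as.matrix(db$foci[, c("x", "y", "z")])
  if (!is.null(roi)) pts <- rbind(pts, roi$mm)
  ale_grid(apply(pts, 2, min) - pad_mm, apply(pts, 2, max) + pad_mm,
           spacing_mm)
}

#' Select studies reporting a focus near a point
#'
#' A study is included iff the Euclidean distance from its nearest focus to
#' `point_mm` is at most `radius_mm` (closed ball: exactly-on-the-boundary
#' foci count as within).
#'
#' @param db a `coordinate_db`.
#' @param point_mm length-3 mm coordinate.
#' @param radius_mm selection radius (> 0), default 6 mm.
#' @return character vector of selected study ids (possibly empty, with a
#'   warning).
#' @export
select_studies <- function(db, point_mm, radius_mm = 6) {
  stopifnot(radius_mm > 0)
  d2 <- (db$foci$x - point_mm[1])^2 + (db$foci$y - point_mm[2])^2 +
    (db$foci$z - point_mm[3])^2
  ids <- unique(db$foci$study_id[d2 <= radius_mm^2])
  if (!length(ids)) warning("no studies within ", radius_mm, " mm of the point")
  as.character(ids)
}

#' Select studies reporting a focus inside a seed mask
#'
#' A focus lies inside the seed if its nearest voxel (by the seed volume's
#' affine) is part of the mask.
#'
#' @param db a `coordinate_db`.
#' @param seed a binary 3-D [brain_vol].
#' @return character vector of selected study ids.
#' @export
select_studies_in_mask <- function(db, seed) {
  stopifnot(inherits(seed, "brain_vol"))
  if (!any(seed$data != 0)) stop("seed mask is empty")
  ijk <- round(mm_to_voxel(seed$affine, as.matrix(db$foci[, c("x", "y", "z")])))
  d <- dim(seed$data)
  inside <- ijk[, 1] >= 0 & ijk[, 1] < d[1] &
    ijk[, 2] >= 0 & ijk[, 2] < d[2] &
    ijk[, 3] >= 0 & ijk[, 3] < d[3]
  hit <- logical(nrow(ijk))
  if (any(inside)) {
    lin <- ijk[inside, , drop = FALSE] %*% c(1, d[1], d[1] * d[2]) + 1
    hit[inside] <- seed$data[as.integer(lin)] != 0
  }
  ids <- unique(db$foci$study_id[hit])
  if (!length(ids)) warning("no studies report a focus inside the seed")
  as.character(ids)
}

#' Sample-size-dependent ALE kernel width
#'
#' Implements the empirical spatial-uncertainty model behind the revised
#' ALE algorithm: the kernel FWHM combines a fixed between-template
#' component with a between-subject component that shrinks as `1/sqrt(n)`.
#' The Euclidean-distance constants (5.7 mm between-template, 11.6 mm
#' between-subject) are converted to per-axis FWHM via `2 sqrt(2/pi)` and
#' `sqrt(8 ln 2)`. A fixed-FWHM override bypasses the model (useful for
#' controlled tests).
#'
#' @param sample_size number of subjects in the study (>= 1).
#' @param fixed_fwhm_mm if non-`NULL`, the kernel FWHM in mm regardless of
#'   sample size.
#' @param template_ed,subject_ed the two Euclidean-distance uncertainty
#'   constants in mm.
#' @return Gaussian kernel sd in mm.
#' @export
kernel_sigma <- function(sample_size, fixed_fwhm_mm = NULL,
                         template_ed = 5.7, subject_ed = 11.6) {
  f2s <- sqrt(8 * log(2))               # FWHM -> sd
  if (!is.null(fixed_fwhm_mm)) return(fixed_fwhm_mm / f2s)
  stopifnot(sample_size >= 1)
  conv <- 2 * sqrt(2 / pi)              # mean Euclidean distance -> FWHM
  fwhm_t <- template_ed / conv * f2s
  fwhm_s <- subject_ed / conv * f2s / sqrt(sample_size)
  sqrt(fwhm_t^2 + fwhm_s^2) / f2s
}

# discrete kernel normalizer: sum of Gaussian weights over the truncated
# support lattice at the grid spacing (position-independent)
.kernel_norm <- function(sigma_mm, spacing_mm, trunc_sd = 3.5) {
  r <- ceiling(trunc_sd * sigma_mm / spacing_mm)
  offs <- as.matrix(expand.grid(-r:r, -r:r, -r:r)) * spacing_mm
  d2 <- rowSums(offs^2)
  keep <- d2 <= (trunc_sd * sigma_mm)^2
  sum(exp(-d2[keep] / (2 * sigma_mm^2)))
}

#' Modelled-activation map of a single study
#'
#' Each focus contributes a truncated Gaussian (normalized so the discrete
#' kernel has unit mass, hence values in \[0, 1)); foci within a study are
#' combined by the voxelwise maximum, so duplicated foci collapse and focus
#' count does not inflate the map.
#'
#' @param foci_mm k x 3 matrix of the study's foci.
#' @param sigma_mm kernel sd in mm (see [kernel_sigma]).
#' @param grid an [ale_grid].
#' @param trunc_sd kernel support radius in sd units.
#' @return numeric vector over grid voxels.
#' @export
ma_map <- function(foci_mm, sigma_mm, grid, trunc_sd = 3.5) {
  stopifnot(inherits(grid, "ale_grid"), nrow(foci_mm) >= 1)
  norm <- .kernel_norm(sigma_mm, grid$spacing, trunc_sd)
  out <- numeric(nrow(grid$mm))
  r2 <- (trunc_sd * sigma_mm)^2
  for (j in seq_len(nrow(foci_mm))) {
    d2 <- (grid$mm[, 1] - foci_mm[j, 1])^2 +
      (grid$mm[, 2] - foci_mm[j, 2])^2 +
      (grid$mm[, 3] - foci_mm[j, 3])^2
    sel <- d2 <= r2
    if (!any(sel)) next                  # focus outside the grid support
    out[sel] <- pmax(out[sel], exp(-d2[sel] / (2 * sigma_mm^2)) / norm)
  }
  out
}

#' Modelled-activation maps for every study in a database
#'
#' @param db a `coordinate_db`.
#' @param grid an [ale_grid].
#' @param fixed_fwhm_mm optional fixed kernel FWHM (see [kernel_sigma]).
#' @param trunc_sd kernel support radius in sd units.
#' @return n_studies x n_grid matrix with study ids as rownames.
#' @export
ma_maps <- function(db, grid, fixed_fwhm_mm = NULL, trunc_sd = 3.5) {
  ids <- as.character(db$studies$study_id)
  foci_by <- split(db$foci[, c("x", "y", "z")], db$foci$study_id)
  out <- matrix(0, length(ids), nrow(grid$mm), dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    sg <- kernel_sigma(db$studies$n_subjects[i], fixed_fwhm_mm)
    out[i, ] <- ma_map(as.matrix(foci_by[[ids[i]]]), sg, grid, trunc_sd)
  }
  out
}

#' Activation likelihood estimate
#'
#' Voxelwise probabilistic union of the modelled-activation maps:
#' `ALE = 1 - prod_i (1 - MA_i)`. The union dominates every component, so
#' ALE is at least the maximum contributing MA value everywhere, and adding
#' a study can never decrease it.
#'
#' @param ma n_studies x n_grid matrix (or a single MA vector).
#' @return numeric ALE vector over grid voxels.
#' @export
ale <- function(ma) {
  if (is.null(dim(ma))) return(as.numeric(ma))
  if (nrow(ma) == 0) stop("need at least 1 MA map")
  if (nrow(ma) == 1) return(as.numeric(ma[1, ]))
  -expm1(colSums(log1p(-ma)))
}

#' Voxelwise meta-analytic coactivation maps for an ROI
#'
#' For every ROI voxel, selects the studies reporting at least one focus
#' within `radius_mm` of the voxel centre and computes their ALE map over
#' the analysis grid. The unthresholded map matrix feeds
#' [macm_similarity()].
#'
#' @param db a `coordinate_db`.
#' @param roi an [roi_mask].
#' @param grid an [ale_grid].
#' @param radius_mm study-selection radius, default 6 mm.
#' @param ma optional precomputed [ma_maps()] matrix (recomputed otherwise).
#' @param fixed_fwhm_mm passed to [ma_maps()].
#' @return list with `maps` (n_roi x n_grid unthresholded ALE matrix),
#'   `selections` (per-voxel study-id lists, the map provenance), `grid`.
#' @export
macm_voxelwise <- function(db, roi, grid, radius_mm = 6, ma = NULL,
                           fixed_fwhm_mm = NULL) {
  if (is.null(ma)) ma <- ma_maps(db, grid, fixed_fwhm_mm)
  ids <- rownames(ma)
  logc <- log1p(-ma)
  fx <- db$foci$x; fy <- db$foci$y; fz <- db$foci$z
  fid <- match(as.character(db$foci$study_id), ids)
  maps <- matrix(0, roi$n_voxels, ncol(ma))
  selections <- vector("list", roi$n_voxels)
  for (v in seq_len(roi$n_voxels)) {
    p <- roi$mm[v, ]
    d2 <- (fx - p[1])^2 + (fy - p[2])^2 + (fz - p[3])^2
    sel <- sort(unique(fid[d2 <= radius_mm^2]))
    selections[[v]] <- ids[sel]
    if (!length(sel)) next               # all-zero row; macm_similarity errors
    maps[v, ] <- if (length(sel) == 1) -expm1(logc[sel, ])
    else -expm1(colSums(logc[sel, , drop = FALSE]))
  }
  list(maps = maps, selections = selections, grid = grid)
}

#' MACM of a seed region
#'
#' ALE over all studies reporting at least one focus inside the seed mask,
#' optionally FWE-thresholded at the voxel level.
#'
#' @param db a `coordinate_db`.
#' @param seed binary 3-D [brain_vol].
#' @param grid an [ale_grid].
#' @param threshold if `TRUE`, also return the FWE-thresholded map.
#' @param n_iter,alpha,seed passed to [ale_fwe_threshold()].
#' @param fixed_fwhm_mm passed to [ma_maps()].
#' @return list with `ale` (unthresholded vector), `study_ids`, and (when
#'   thresholded) `thresholded`, `threshold_value`.
#' @export
macm_seed <- function(db, seed, grid, threshold = FALSE, n_iter = 1000,
                      alpha = 0.05, seed_rng = 1L, fixed_fwhm_mm = NULL) {
  ids <- select_studies_in_mask(db, seed)
  if (!length(ids)) stop("no studies activate the seed")
  sub <- subset_db(db, ids)
  ma <- ma_maps(sub, grid, fixed_fwhm_mm)
  a <- ale(ma)
  out <- list(ale = a, study_ids = ids)
  if (threshold) {
    thr <- ale_fwe_threshold(a, sub, grid, n_iter = n_iter, alpha = alpha,
                             seed = seed_rng, fixed_fwhm_mm = fixed_fwhm_mm)
    out$thresholded <- thr$thresholded
    out$threshold_value <- thr$threshold
  }
  out
}

#' Restrict a coordinate database to a study subset
#'
#' @param db a `coordinate_db`.
#' @param ids study ids to keep.
#' @return a `coordinate_db` containing only those studies.
#' @export
subset_db <- function(db, ids) {
  keep <- db$studies$study_id %in% ids
  if (!any(keep)) stop("empty study selection")
  st <- db$studies[keep, , drop = FALSE]
  coordinate_db(st,
                db$foci[db$foci$study_id %in% ids, , drop = FALSE],
                if (is.null(db$terms)) NULL
                else db$terms[as.character(st$study_id), , drop = FALSE])
}

#' Voxel-level FWE threshold for an ALE map
#'
#' Monte-Carlo maximum-statistic null: each iteration redraws every study's
#' foci uniformly over the analysis-grid voxels (preserving per-study focus
#' counts and kernels), recomputes the ALE map, and records its maximum.
#' The threshold is the `(1 - alpha)` quantile of the max-ALE null.
#'
#' @param ale_values observed ALE vector over the grid.
#' @param db the `coordinate_db` subset that produced the map.
#' @param grid the [ale_grid].
#' @param n_iter Monte-Carlo iterations (>= 100).
#' @param alpha FWE level.
#' @param seed RNG seed for the null draws.
#' @param fixed_fwhm_mm optional fixed kernel FWHM.
#' @return list with `threshold`, `thresholded` (values below the threshold
#'   zeroed), and `null_max` (the null distribution).
#' @export
ale_fwe_threshold <- function(ale_values, db, grid, n_iter = 1000,
                              alpha = 0.05, seed = 1L, fixed_fwhm_mm = NULL) {
  if (n_iter < 100) stop("n_iter must be >= 100")
  if (n_iter * alpha < 1 && alpha < 1)
    stop("n_iter too small to resolve the ", alpha, " quantile")
  set.seed(seed)
  counts <- table(factor(as.character(db$foci$study_id),
                         levels = as.character(db$studies$study_id)))
  sigmas <- kernel_sigma(db$studies$n_subjects, fixed_fwhm_mm)
  ngrid <- nrow(grid$mm)
  null_max <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    logc <- numeric(ngrid)
    for (i in seq_along(counts)) {
      vox <- sample.int(ngrid, counts[i], replace = TRUE)
      mai <- ma_map(grid$mm[vox, , drop = FALSE], sigmas[i], grid)
      logc <- logc + log1p(-mai)
    }
    null_max[it] <- max(-expm1(logc))
  }
  thr <- if (alpha >= 1) 0 else as.numeric(stats::quantile(null_max, 1 - alpha,
                                                           type = 1))
  out <- ale_values
  out[out < thr] <- 0
  list(threshold = thr, thresholded = out, null_max = null_max)
}

#' ALE contrast between two study selections
#'
#' Observed voxelwise ALE difference (A minus B) against a permutation null
#' built by shuffling study labels between the two groups; returns
#' uncorrected one-sided p-values in each direction and the signed
#' thresholded contrast. Swapping A and B flips the sign of the map.
#'
#' @param db a `coordinate_db`.
#' @param ids_a,ids_b study ids of the two selections (both nonempty).
#' @param grid an [ale_grid].
#' @param n_perm permutations.
#' @param alpha uncorrected threshold, default 0.05.
#' @param seed RNG seed.
#' @param fixed_fwhm_mm optional fixed kernel FWHM.
#' @return list with `diff`, `p_a_gt_b`, `p_b_gt_a`, `contrast`
#'   (diff where significant in its direction, else 0).
#' @export
ale_contrast <- function(db, ids_a, ids_b, grid, n_perm = 1000, alpha = 0.05,
                         seed = 1L, fixed_fwhm_mm = NULL) {
  if (!length(ids_a) || !length(ids_b)) stop("both selections must be nonempty")
  if (setequal(ids_a, ids_b)) {
    z <- numeric(nrow(grid$mm))
    return(list(diff = z, p_a_gt_b = rep(1, length(z)),
                p_b_gt_a = rep(1, length(z)), contrast = z))
  }
  all_ids <- union(ids_a, ids_b)
  sub <- subset_db(db, all_ids)
  ma <- ma_maps(sub, grid, fixed_fwhm_mm)
  logc <- log1p(-ma)
  ale_of <- function(ids) {
    ix <- match(ids, rownames(ma))
    if (length(ix) == 1) -expm1(logc[ix, ]) else -expm1(colSums(logc[ix, , drop = FALSE]))
  }
  obs <- ale_of(ids_a) - ale_of(ids_b)
  set.seed(seed)
  na <- length(ids_a)
  cnt_pos <- numeric(length(obs))
  cnt_neg <- numeric(length(obs))
  for (p in seq_len(n_perm)) {
    perm <- sample(all_ids)
    d <- ale_of(perm[seq_len(na)]) - ale_of(perm[-seq_len(na)])
    cnt_pos <- cnt_pos + (d >= obs)
    cnt_neg <- cnt_neg + (d <= obs)
  }
  p_a <- (cnt_pos + 1) / (n_perm + 1)
  p_b <- (cnt_neg + 1) / (n_perm + 1)
  contrast <- numeric(length(obs))
  sig_a <- p_a < alpha & obs > 0
  sig_b <- p_b < alpha & obs < 0
  contrast[sig_a] <- obs[sig_a]
  contrast[sig_b] <- obs[sig_b]
  list(diff = obs, p_a_gt_b = p_a, p_b_gt_a = p_b, contrast = contrast)
}
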