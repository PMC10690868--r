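#' Cluster-mean seed series
#'
#' Mean over the cluster voxels of the run-concatenated time-series
#' (concatenation in the listed run order).
#'
#' @param runs list of run matrices (n_vox x n_t, shared voxel order) or of
#'   4-D [brain_vol] runs (then `roi` is required).
#' @param cluster integer indices of the cluster voxels (ROI order).
#' @param roi optional [roi_mask] for volume inputs.
#' @return numeric series of length `sum of run lengths`.
#' @export
seed_series <- function(runs, cluster, roi = NULL) {
  if (!length(cluster)) stop("empty cluster")
  mats <- lapply(runs, function(r)
    if (inherits(r, "brain_vol")) roi_timeseries(r, roi) else as.matrix(r))
  yc <- do.call(cbind, mats)             # n_vox x total_t
  colMeans(yc[cluster, , drop = FALSE])
}

#' Subject seed-FC map
#'
#' Simple general linear model of every voxel's series on the seed series
#' (plus intercept); for a single regressor the standardized effect is the
#' voxel-seed Pearson correlation, which is Fisher-z transformed to form
#' the subject map.
#'
#' @param ts n_vox x n_t matrix of the subject's (run-concatenated) series.
#' @param seed numeric seed series of length n_t.
#' @return numeric z-map over voxels.
#' @export
seed_glm <- function(ts, seed) {
  ts <- as.matrix(ts)
  if (length(seed) != ncol(ts)) stop("seed series length mismatch")
  if (stats::sd(seed) == 0) stop("constant seed series")
  sds <- apply(ts, 1, stats::sd)
  r <- numeric(nrow(ts))
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(t(ts[ok, , drop = FALSE]), seed))
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  atanh(r)
}

#' Group one-sample t-map
#'
#' Voxelwise one-sample t-test across subjects: `t = mean / (sd / sqrt(N))`
#' with `df = N - 1` and two-sided p-values.
#'
#' @param z_maps subjects x voxels matrix (or list of vectors).
#' @return a `stat_map` list: `t`, `p`, `df`, `n`, plus `zero_var` flags
#'   for voxels with undefined t (zero variance across subjects).
#' @export
group_one_sample_t <- function(z_maps) {
  if (is.list(z_maps)) z_maps <- do.call(rbind, z_maps)
  n <- nrow(z_maps)
  if (n < 3) stop("need at least 3 subjects")
  m <- colMeans(z_maps)
  s <- apply(z_maps, 2, stats::sd)
  zero_var <- s == 0
  tval <- ifelse(zero_var, NA_real_, m / (s / sqrt(n)))
  p <- 2 * stats::pt(abs(tval), df = n - 1, lower.tail = FALSE)
  structure(list(t = tval, p = p, df = n - 1L, n = n, zero_var = zero_var),
            class = "stat_map")
}

#' Group paired t-map
#'
#' One-sample t-test on the per-subject difference maps A - B; the result
#' is antisymmetric in (A, B). Subjects must be listed in the same order in
#' both inputs.
#'
#' @param z_a,z_b subjects x voxels matrices for the two conditions.
#' @return a `stat_map` (see [group_one_sample_t()]).
#' @export
group_paired_t <- function(z_a, z_b) {
  if (is.list(z_a)) z_a <- do.call(rbind, z_a)
  if (is.list(z_b)) z_b <- do.call(rbind, z_b)
  if (!identical(dim(z_a), dim(z_b)))
    stop("subject order/shape mismatch between the two map sets")
  group_one_sample_t(z_a - z_b)
}

#' Voxel-height FWE threshold for a t-map
#'
#' `bonferroni`: keep voxels with `p <= alpha / m` over the m tested
#' voxels. `perm_maxt`: sign-flipping maximum-statistic permutation null
#' (the subject maps are required); keeps voxels whose |t| exceeds the
#' `(1 - alpha)` quantile of the max-|t| null.
#'
#' @param stat a `stat_map` from [group_one_sample_t()] / [group_paired_t()].
#' @param alpha FWE level in (0, 1\].
#' @param method `"bonferroni"` or `"perm_maxt"`.
#' @param z_maps subjects x voxels matrix (needed for `perm_maxt`).
#' @param n_perm sign-flip permutations.
#' @param seed RNG seed for the permutations.
#' @return list with `mask` (logical, significant voxels), `t_masked`
#'   (t with nonsignificant voxels zeroed), `cutoff` (p or |t| cutoff),
#'   `method`.
#' @export
fwe_voxel_threshold <- function(stat, alpha = 0.05,
                                method = c("bonferroni", "perm_maxt"),
                                z_maps = NULL, n_perm = 1000, seed = 1L) {
  method <- match.arg(method)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  m <- length(stat$t)
  if (m == 0) stop("empty statistic map")
  if (method == "bonferroni") {
    mask <- !is.na(stat$p) & stat$p <= alpha / m
    cutoff <- alpha / m
  } else {
    if (is.null(z_maps)) stop("perm_maxt needs the subject maps")
    if (is.list(z_maps)) z_maps <- do.call(rbind, z_maps)
    set.seed(seed)
    n <- nrow(z_maps)
    null_max <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      zb <- z_maps * signs
      mb <- colMeans(zb)
      sb <- apply(zb, 2, stats::sd)
      tb <- abs(mb / (sb / sqrt(n)))
      null_max[b] <- max(tb[is.finite(tb)])
    }
    cutoff <- as.numeric(stats::quantile(null_max, 1 - alpha, type = 1))
    mask <- !is.na(stat$t) & abs(stat$t) >= cutoff
  }
  t_masked <- ifelse(mask, stat$t, 0)
  t_masked[is.na(t_masked)] <- 0
  list(mask = mask, t_masked = t_masked, cutoff = cutoff, method = method)
}

#' Mask a contrast by independent significance
#'
#' Retains the contrast only where the independently thresholded one-sample
#' map is significant in the matching direction (positive contrast needs
#' positive independent significance, and vice versa).
#'
#' @param contrast_t numeric contrast t-values over voxels.
#' @param independent_t_masked thresholded independent t-map (0 where not
#'   significant), same voxel set.
#' @return masked contrast vector.
#' @export
mask_contrast <- function(contrast_t, independent_t_masked) {
  if (length(contrast_t) != length(independent_t_masked))
    stop("grid mismatch between contrast and mask")
  keep <- independent_t_masked != 0 &
    sign(contrast_t) == sign(independent_t_masked)
  out <- numeric(length(contrast_t))
  out[keep] <- contrast_t[keep]
  out
}
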