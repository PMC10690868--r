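#' Run-level time-series similarity matrix
#'
#' Product-moment (Pearson) correlation between the time-series of every
#' pair of ROI voxels.
#'
#' @param ts a 4-D [brain_vol] or an already-extracted voxel-by-time matrix.
#' @param roi the [roi_mask]; required when `ts` is a volume.
#' @return n x n `similarity_matrix` (attributes: `modality = "task_free"`,
#'   `level = "run"`).
#' @export
timeseries_similarity <- function(ts, roi = NULL) {
  Y <- if (inherits(ts, "brain_vol")) roi_timeseries(ts, roi) else as.matrix(ts)
  if (ncol(Y) < 3) stop("need at least 3 timepoints")
  sds <- apply(Y, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance ROI voxel(s): ",
         paste(which(sds == 0), collapse = ", "))
  R <- stats::cor(t(Y))
  similarity_matrix(R, modality = "task_free", level = "run")
}

#' Tag a matrix as a similarity matrix
#'
#' @param R symmetric numeric matrix of correlations (diagonal 1).
#' @param modality `"task_free"` or `"task_based"`.
#' @param level `"run"`, `"subject"` or `"group"`.
#' @return `R` with class `similarity_matrix` and tags as attributes.
#' @export
similarity_matrix <- function(R, modality, level) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("similarity matrix must be square")
  if (max(abs(R - t(R))) > 1e-8) stop("similarity matrix must be symmetric")
  R <- (R + t(R)) / 2
  structure(R, modality = modality, level = level,
            class = c("similarity_matrix", "matrix", "array"))
}

#' Fisher r-to-z transform and its inverse
#'
#' `fisher_z` is `atanh(r)`; values with `|r| = 1` (in practice the
#' diagonal, which is excluded from aggregation anyway) are clipped to
#' `1 - 1e-7` with a warning. `fisher_z_inv` is `tanh(z)`.
#'
#' @param r correlations in \[-1, 1\].
#' @return transformed values, same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1")
  clip <- abs(r) >= 1 - .Machine$double.eps
  if (any(clip, na.rm = TRUE)) {
    warning("|r| = 1 clipped to 1 - 1e-7 before atanh")
    r[clip] <- sign(r[clip]) * (1 - 1e-7)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher z values.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Aggregate run-level similarity matrices to the group level
#'
#' Run matrices are Fisher-z transformed and averaged within subject, the
#' subject matrices are averaged across subjects, and the group average is
#' transformed back to correlation units. Subjects contribute equal weight
#' regardless of their run count. The diagonal is set back to r = 1 after
#' aggregation (rather than averaging atanh(1)).
#'
#' @param run_matrices list of subjects; each subject is a list of run
#'   `similarity_matrix` objects sharing the ROI voxel order.
#' @return list with `group` (a `similarity_matrix`, level `"group"`) and
#'   `subjects` (list of subject-level matrices, retained for
#'   individual-level gradation analysis).
#' @export
aggregate_similarity <- function(run_matrices) {
  stopifnot(length(run_matrices) >= 1)
  n <- nrow(run_matrices[[1]][[1]])
  subj <- lapply(run_matrices, function(runs) {
    stopifnot(length(runs) >= 1)
    zsum <- 0
    for (R in runs) {
      if (!identical(dim(R), c(n, n)))
        stop("voxel-order/dimension mismatch across run matrices")
      R <- unclass(R)
      diag(R) <- 0                      # diagonal excluded from aggregation
      zsum <- zsum + fisher_z(R)
    }
    zsum / length(runs)
  })
  zgrp <- Reduce(`+`, subj) / length(subj)
  finish <- function(z, level) {
    R <- fisher_z_inv(z)
    diag(R) <- 1
    similarity_matrix(R, modality = "task_free", level = level)
  }
  list(group = finish(zgrp, "group"),
       subjects = lapply(subj, finish, level = "subject"))
}

#' Coactivation similarity matrix from voxelwise MACM maps
#'
#' Pearson correlation between the unthresholded MACM map values of every
#' pair of ROI voxels.
#'
#' @param macm_maps n_roi x n_brain matrix; row v is ROI voxel v's MACM map
#'   over the analysis grid.
#' @return n_roi x n_roi `similarity_matrix` (modality `"task_based"`).
#' @export
macm_similarity <- function(macm_maps) {
  macm_maps <- as.matrix(macm_maps)
  allzero <- rowSums(abs(macm_maps)) == 0
  if (any(allzero))
    stop("all-zero MACM map for ROI voxel(s) ",
         paste(which(allzero), collapse = ", "),
         ": no matching studies; increase the selection radius or the ",
         "study sample")
  sds <- apply(macm_maps, 1, stats::sd)
  if (any(sds == 0))
    stop("constant MACM map for ROI voxel(s) ",
         paste(which(sds == 0), collapse = ", "))
  R <- stats::cor(t(macm_maps))
  similarity_matrix(R, modality = "task_based", level = "group")
}
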