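#' Construct a brain volume
#'
#' A `brain_vol` couples a 3-D (scalar map) or 4-D (time-series) array with a
#' 4x4 affine matrix mapping 0-based voxel indices to world (RAS+) millimetre
#' coordinates, following the NIfTI convention.
#'
#' @param data numeric array, 3-D or 4-D (x, y, z\[, t\]).
#' @param affine 4x4 numeric matrix; must be invertible and have last row
#'   (0, 0, 0, 1).
#' @return An object of class `brain_vol` with elements `data`, `affine`.
#' @export
brain_vol <- function(data, affine) {
  data <- as.array(data)
  if (!(length(dim(data)) %in% c(3L, 4L)))
    stop("brain_vol data must be a 3-D or 4-D array")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 64)
    stop("affine is not invertible")
  if (any(abs(affine[4, ] - c(0, 0, 0, 1)) > 1e-8))
    stop("last affine row must be (0, 0, 0, 1)")
  structure(list(data = data, affine = affine), class = "brain_vol")
}

#' @export
print.brain_vol <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brain_vol> %s voxels, %s\n",
              paste(d[1:3], collapse = "x"),
              if (length(d) == 4L) sprintf("%d timepoints", d[4]) else "scalar map"))
  invisible(x)
}

#' Number of timepoints of a volume (1 for 3-D maps)
#' @param vol a `brain_vol`.
#' @return integer count of frames along the fourth axis.
#' @export
n_timepoints <- function(vol) {
  d <- dim(vol$data)
  if (length(d) == 4L) d[4] else 1L
}

#' Read a NIfTI volume
#'
#' Loads a 3-D or 4-D NIfTI-1 file into a [brain_vol]. The affine is taken
#' from the image xform (sform/qform as resolved by RNifti).
#'
#' @param path file path to a `.nii` or `.nii.gz` file.
#' @return a [brain_vol].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI volume: ", path,
                                           " (", conditionMessage(e), ")"))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  a <- array(as.numeric(img), dim = dim(img))   # strip RNifti attributes
  if (!(length(dim(a)) %in% c(3L, 4L)))
    stop("volume must be 3-D or 4-D, got ", length(dim(a)), " dimensions")
  brain_vol(a, aff)
}

#' Write a brain volume to NIfTI
#'
#' @param vol a [brain_vol].
#' @param path destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "brain_vol"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert voxel indices to millimetre coordinates
#'
#' Voxel indices are 0-based; world coordinates follow the RAS+ NIfTI
#' convention of the affine.
#'
#' @param affine 4x4 voxel-to-mm matrix.
#' @param ijk integer vector of length 3, or an n x 3 matrix of indices.
#' @return numeric mm coordinates, same shape as `ijk`.
#' @export
voxel_to_mm <- function(affine, ijk) {
  one_dim <- is.null(dim(ijk))
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  xyz <- cbind(ijk, 1) %*% t(affine)
  out <- xyz[, 1:3, drop = FALSE]
  if (one_dim && nrow(out) == 1L) as.numeric(out) else out
}

#' @rdname voxel_to_mm
#' @param xyz numeric mm coordinates, length-3 vector or n x 3 matrix.
#' @export
mm_to_voxel <- function(affine, xyz) {
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 64)
    stop("affine is not invertible")
  one_dim <- is.null(dim(xyz))
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  ijk <- cbind(xyz, 1) %*% t(solve(affine))
  out <- ijk[, 1:3, drop = FALSE]
  if (one_dim && nrow(out) == 1L) as.numeric(out) else out
}

#' Build an ROI mask with a fixed voxel order
#'
#' Collects the nonzero voxels of a binary volume in ascending (k, j, i)
#' raster order, i.e. the first index varies fastest. This order fixes the
#' row/column identity of every downstream ROI matrix, so it is stored with
#' the mask and persisted next to matrix artifacts.
#'
#' @param vol a binary [brain_vol] (3-D).
#' @return An object of class `roi_mask`: the volume plus `idx0` (n x 3
#'   0-based voxel indices), `mm` (n x 3 world coordinates) and `n_voxels`.
#' @export
roi_mask <- function(vol) {
  stopifnot(inherits(vol, "brain_vol"))
  d <- dim(vol$data)
  if (length(d) != 3L) stop("ROI mask must be a 3-D volume")
  vals <- unique(as.numeric(vol$data))
  if (!all(vals %in% c(0, 1))) stop("ROI mask must be binary (0/1)")
  lin <- which(vol$data != 0)          # column-major: i fastest
  if (length(lin) < 2L) stop("ROI must contain at least 2 voxels")
  idx0 <- arrayInd(lin, d) - 1L
  structure(list(vol = vol, idx0 = idx0,
                 mm = voxel_to_mm(vol$affine, idx0),
                 n_voxels = length(lin)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d voxels on a %s grid\n", x$n_voxels,
              paste(dim(x$vol$data), collapse = "x")))
  invisible(x)
}

#' Extract the ROI voxel-by-time matrix from a 4-D volume
#'
#' @param ts a 4-D [brain_vol].
#' @param roi an [roi_mask] on the same grid.
#' @return numeric matrix, `n_voxels` x `n_timepoints`, rows in ROI order.
#' @export
roi_timeseries <- function(ts, roi) {
  stopifnot(inherits(ts, "brain_vol"), inherits(roi, "roi_mask"))
  d <- dim(ts$data)
  if (length(d) != 4L) stop("expected a 4-D time-series volume")
  if (!identical(d[1:3], dim(roi$vol$data)))
    stop("time-series grid does not match the ROI grid")
  mat <- matrix(ts$data, prod(d[1:3]), d[4])
  lin <- roi$idx0 %*% c(1L, d[1], d[1] * d[2]) + 1L
  mat[as.integer(lin), , drop = FALSE]
}

#' Write ROI values back into a volume
#'
#' @param values numeric vector, one value per ROI voxel (in ROI order).
#' @param roi an [roi_mask].
#' @param background fill value outside the ROI.
#' @return a 3-D [brain_vol].
#' @export
roi_to_volume <- function(values, roi, background = 0) {
  stopifnot(inherits(roi, "roi_mask"), length(values) == roi$n_voxels)
  d <- dim(roi$vol$data)
  arr <- array(background, d)
  lin <- roi$idx0 %*% c(1L, d[1], d[1] * d[2]) + 1L
  arr[as.integer(lin)] <- values
  brain_vol(arr, roi$vol$affine)
}

#' Read a coordinate database
#'
#' Loads per-study activation foci and the study-by-term frequency table.
#' The foci table must contain columns `study_id`, `x`, `y`, `z` (MNI mm)
#' and `n_subjects`; the term table must have one `study_id` column and one
#' numeric column per term. Duplicate focus rows are retained: real
#' coordinate databases contain them and the non-additive within-study
#' kernel combination makes them harmless.
#'
#' @param foci_path TSV/CSV file of foci.
#' @param terms_path TSV/CSV file of term frequencies (may be `NULL`).
#' @return A `coordinate_db`: list with `studies` (data.frame: `study_id`,
#'   `n_subjects`), `foci` (data.frame), and `terms` (numeric matrix,
#'   studies x terms, rownames = study ids; `NULL` if not supplied).
#' @export
read_coordinate_db <- function(foci_path, terms_path = NULL) {
  foci <- utils::read.table(foci_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("study_id", "x", "y", "z", "n_subjects")
  if (!all(need %in% names(foci)))
    stop("foci table is missing required columns: ",
         paste(setdiff(need, names(foci)), collapse = ", "))
  studies <- unique(foci[, c("study_id", "n_subjects")])
  if (anyDuplicated(studies$study_id))
    stop("inconsistent n_subjects within a study_id")
  foci <- foci[, c("study_id", "x", "y", "z")]
  terms <- NULL
  if (!is.null(terms_path)) {
    tt <- utils::read.table(terms_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (!"study_id" %in% names(tt)) stop("term table must have a study_id column")
    if (!setequal(tt$study_id, studies$study_id))
      stop("study_id mismatch between foci and term tables")
    tt <- tt[match(studies$study_id, tt$study_id), , drop = FALSE]
    terms <- as.matrix(tt[, setdiff(names(tt), "study_id"), drop = FALSE])
    rownames(terms) <- studies$study_id
  }
  coordinate_db(studies, foci, terms)
}

#' Assemble a coordinate database from its parts
#'
#' @param studies data.frame with `study_id`, `n_subjects` (n >= 1).
#' @param foci data.frame with `study_id`, `x`, `y`, `z`; every study must
#'   report at least one focus.
#' @param terms optional studies x terms numeric matrix (rownames = ids).
#' @return a `coordinate_db` object.
#' @export
coordinate_db <- function(studies, foci, terms = NULL) {
  if (any(studies$n_subjects < 1)) stop("sample sizes must be >= 1")
  missing_foci <- setdiff(studies$study_id, foci$study_id)
  if (length(missing_foci))
    stop("studies with zero foci: ", paste(missing_foci, collapse = ", "))
  if (!is.null(terms)) {
    if (nrow(terms) != nrow(studies) ||
        !identical(rownames(terms), as.character(studies$study_id)))
      stop("term matrix rows must align with the study list")
  }
  structure(list(studies = studies, foci = foci, terms = terms),
            class = "coordinate_db")
}

#' @export
print.coordinate_db <- function(x, ...) {
  cat(sprintf("<coordinate_db> %d studies, %d foci, %s terms\n",
              nrow(x$studies), nrow(x$foci),
              if (is.null(x$terms)) "no" else ncol(x$terms)))
  invisible(x)
}

#' Write a coordinate database to TSV files
#'
#' @param db a `coordinate_db`.
#' @param foci_path,terms_path destination files; `terms_path` may be `NULL`.
#' @return `foci_path`, invisibly.
#' @export
write_coordinate_db <- function(db, foci_path, terms_path = NULL) {
  out <- merge(db$foci[, c("study_id", "x", "y", "z")], db$studies,
               by = "study_id", sort = FALSE)
  out <- out[, c("study_id", "x", "y", "z", "n_subjects")]
  utils::write.table(out, foci_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(terms_path) && !is.null(db$terms)) {
    tt <- data.frame(study_id = rownames(db$terms), db$terms,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tt, terms_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(foci_path)
}

#' Persist an ROI matrix with its voxel-order sidecar
#'
#' Matrices are written as plain TSV plus a JSON sidecar recording the ROI
#' voxel order (0-based indices in ascending (k, j, i) raster order) and
#' free-form provenance, so that row/column identity is reproducible.
#'
#' @param mat numeric matrix (n x n, ROI order on both axes).
#' @param roi the [roi_mask] defining row order.
#' @param path destination `.tsv` path; sidecar goes to `<path>.json`.
#' @param provenance named list stored verbatim in the sidecar.
#' @return `path`, invisibly.
#' @export
write_roi_matrix <- function(mat, roi, path, provenance = list()) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sidecar <- list(n_voxels = roi$n_voxels,
                  voxel_order_ijk0 = unname(apply(roi$idx0, 1, as.integer,
                                                  simplify = FALSE)),
                  provenance = provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_roi_matrix
#' @export
read_roi_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  m
}
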