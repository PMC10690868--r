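#' Global-signal regression
#'
#' Regresses the mean in-mask time-series (plus an intercept) out of every
#' voxel's series by ordinary least squares. Residuals are orthogonal to
#' both regressors; applying the projection twice equals applying it once.
#'
#' @param ts a 4-D [brain_vol].
#' @param mask an [roi_mask] defining the voxels whose mean is the global
#'   signal (and the voxels that are residualized).
#' @return a 4-D [brain_vol] of residuals (voxels outside the mask are
#'   passed through unchanged).
#' @export
regress_global_signal <- function(ts, mask) {
  stopifnot(inherits(ts, "brain_vol"), inherits(mask, "roi_mask"))
  Y <- roi_timeseries(ts, mask)               # n_vox x n_t
  if (ncol(Y) < 3) stop("need at least 3 timepoints")
  g <- colMeans(Y)
  if (stats::sd(g) < .Machine$double.eps * 1e4)
    stop("global signal has zero variance")
  X <- cbind(1, g)
  beta <- solve(crossprod(X), crossprod(X, t(Y)))
  R <- t(Y) - X %*% beta                      # n_t x n_vox residuals
  out <- ts
  d <- dim(ts$data)
  lin <- mask$idx0 %*% c(1L, d[1], d[1] * d[2]) + 1L
  nvol <- prod(d[1:3])
  for (t in seq_len(d[4]))
    out$data[(t - 1L) * nvol + as.integer(lin)] <- R[t, ]
  out
}

#' Spatial Gaussian smoothing
#'
#' Separable 3-D Gaussian convolution applied frame by frame. The kernel sd
#' is `FWHM / (2 sqrt(2 ln 2))` in mm, converted to voxels per axis via the
#' affine zooms (anisotropic voxels are handled per axis); near the volume
#' edge the kernel is renormalized over the in-volume support, so a
#' spatially uniform frame is unchanged everywhere. Sheared affines are
#' rejected since axis-separable convolution is then ill-defined.
#'
#' @param ts a 3-D or 4-D [brain_vol].
#' @param fwhm_mm kernel full width at half maximum in mm (0 = identity).
#' @return a [brain_vol] of the same shape.
#' @export
smooth_gaussian <- function(ts, fwhm_mm = 4) {
  stopifnot(inherits(ts, "brain_vol"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(ts)
  A3 <- ts$affine[1:3, 1:3]
  zooms <- sqrt(colSums(A3^2))
  if (any(abs(crossprod(A3) - diag(zooms^2)) > 1e-6 * max(zooms)^2))
    stop("sheared affine: separable Gaussian smoothing not supported")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / zooms
  d <- dim(ts$data)
  is4d <- length(d) == 4L
  nt <- if (is4d) d[4] else 1L
  out <- ts
  for (t in seq_len(nt)) {
    fr <- if (is4d) array(ts$data[, , , t], d[1:3]) else ts$data
    fr <- .gauss3(fr, sigma_vox)
    if (is4d) out$data[, , , t] <- fr else out$data <- fr
  }
  out
}

# separable truncated-Gaussian convolution with edge renormalization
.gauss3 <- function(x, sigma_vox) {
  for (dm in 1:3) {
    s <- sigma_vox[dm]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    kern <- stats::dnorm(-r:r, 0, s)
    n <- dim(x)[dm]
    out <- array(0, dim(x)); wt <- numeric(n)
    for (off in -r:r) {
      kk <- kern[off + r + 1]
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      if (!any(ok)) next
      wt[ok] <- wt[ok] + kk
      if (dm == 1) out[ok, , ] <- out[ok, , ] + kk * x[src[ok], , ]
      else if (dm == 2) out[, ok, ] <- out[, ok, ] + kk * x[, src[ok], ]
      else out[, , ok] <- out[, , ok] + kk * x[, , src[ok]]
    }
    x <- sweep(out, dm, wt, "/")
  }
  x
}

#' Temporal band-pass filter
#'
#' Zero-phase (forward-backward) Butterworth band-pass of every voxel
#' series; the series mean is removed first, so the DC component is zero on
#' output.
#'
#' @param ts a 4-D [brain_vol].
#' @param low_hz,high_hz band edges in Hz; `0 < low < high < Nyquist`.
#' @param tr repetition time in seconds.
#' @param order Butterworth order (applied twice by filtfilt).
#' @return a filtered 4-D [brain_vol].
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08, tr, order = 4) {
  stopifnot(inherits(ts, "brain_vol"))
  d <- dim(ts$data)
  if (length(d) != 4L) stop("expected a 4-D time-series volume")
  nyq <- 1 / (2 * tr)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band must satisfy 0 < low < high < Nyquist (", signif(nyq, 4), " Hz)")
  if (d[4] < 3 * (order + 1))
    stop("series too short for a Butterworth filter of order ", order)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  mat <- matrix(ts$data, prod(d[1:3]), d[4])
  mat <- mat - rowMeans(mat)
  flt <- t(apply(mat, 1, function(y) signal::filtfilt(bf, y)))
  out <- ts
  out$data <- array(flt, d)
  out
}

#' Preprocessing parameters
#'
#' @param gsr,smooth,band_pass logical toggles for the three steps, applied
#'   in that fixed order.
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @param band band-pass edges in Hz.
#' @param tr repetition time in seconds.
#' @param butter_order Butterworth order.
#' @return a `preprocess_params` list.
#' @export
preprocess_params <- function(gsr = TRUE, smooth = TRUE, band_pass = TRUE,
                              fwhm_mm = 4, band = c(0.01, 0.08), tr = 0.72,
                              butter_order = 4) {
  stopifnot(fwhm_mm >= 0, band[1] > 0, band[1] < band[2], tr > 0)
  if (band[2] >= 1 / (2 * tr)) stop("band upper edge must be below Nyquist")
  structure(list(gsr = gsr, smooth = smooth, band_pass = band_pass,
                 fwhm_mm = fwhm_mm, band = band, tr = tr,
                 butter_order = butter_order),
            class = "preprocess_params")
}

#' Run the preprocessing chain on one run
#'
#' Applies, in order, global-signal regression, spatial smoothing and the
#' temporal band-pass, each gated by its toggle.
#'
#' @param ts a 4-D [brain_vol].
#' @param mask the [roi_mask] used for the global signal.
#' @param params a [preprocess_params].
#' @return the preprocessed 4-D [brain_vol].
#' @export
preprocess_run <- function(ts, mask, params = preprocess_params()) {
  stopifnot(inherits(params, "preprocess_params"))
  if (params$gsr) ts <- regress_global_signal(ts, mask)
  if (params$smooth) ts <- smooth_gaussian(ts, params$fwhm_mm)
  if (params$band_pass)
    ts <- bandpass(ts, params$band[1], params$band[2], params$tr,
                   params$butter_order)
  ts
}
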