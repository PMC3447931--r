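# Minimal preprocessing contract preceding ALFF: initial-volume discard,
# motion QC, Gaussian spatial smoothing, ideal band-pass filtering.

#' Discard initial volumes of a run
#'
#' Drops the first `k` volumes (signal equilibration / subject adaptation);
#' volumes `k..t-1` (0-based) are retained. TR and affine are unchanged.
#'
#' @param run An [fmri_4d()].
#' @param k Number of leading volumes to drop (default 10).
#' @return The shortened [fmri_4d()].
#' @export
discard_initial <- function(run, k = 10L) {
  stopifnot(inherits(run, "fmri_4d"))
  k <- as.integer(k)
  nt <- dim(run$data)[4]
  if (k < 0L) stop("`k` must be >= 0", call. = FALSE)
  if (k >= nt)
    stop(sprintf("cannot discard %d of %d volumes", k, nt), call. = FALSE)
  if (k == 0L) return(run)
  run$data <- run$data[, , , (k + 1L):nt, drop = FALSE]
  run
}

#' Motion quality control
#'
#' A run passes QC iff, on every axis, the translation range (max minus min)
#' is strictly less than `max_trans_mm` and the rotation range is strictly
#' less than `max_rot_deg`; a range exactly at the limit fails ("less than"
#' is read strictly).
#'
#' @param trace A [motion_trace()].
#' @param max_trans_mm Translation limit in mm (default 2).
#' @param max_rot_deg Rotation limit in degrees (default 1).
#' @return A list with `pass` (logical), `failed_axes` (character vector of
#'   offending parameter names, empty when passing) and `ranges` (named
#'   numeric vector of per-axis ranges).
#' @export
motion_qc <- function(trace, max_trans_mm = 2, max_rot_deg = 1) {
  stopifnot(inherits(trace, "motion_trace"))
  p <- trace$params
  if (nrow(p) < 1L) stop("motion trace is empty", call. = FALSE)
  ranges <- apply(p, 2L, function(col) diff(range(col)))
  limits <- c(rep(max_trans_mm, 3L), rep(max_rot_deg, 3L))
  bad <- ranges >= limits
  list(pass = !any(bad), failed_axes = names(ranges)[bad], ranges = ranges)
}

# frequency associated with each FFT bin of an N-point series sampled at tr
fft_bin_freqs <- function(n, tr_s) {
  k <- 0:(n - 1L)
  pmin(k, n - k) / (n * tr_s)
}

check_band <- function(band, tr_s) {
  stopifnot(inherits(band, "band_spec"))
  nyq <- 1 / (2 * tr_s)
  if (!(band$f_lo_hz > 0 && band$f_lo_hz < band$f_hi_hz && band$f_hi_hz < nyq))
    stop(sprintf("band [%g, %g] Hz invalid for TR %g s (Nyquist %g Hz)",
                 band$f_lo_hz, band$f_hi_hz, tr_s, nyq), call. = FALSE)
  invisible(band)
}

# ideal band-pass of the columns of a (time x voxels) matrix
bandpass_matrix <- function(X, tr_s, band) {
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 time points", call. = FALSE)
  check_band(band, tr_s)
  f <- fft_bin_freqs(n, tr_s)
  keep <- f >= band$f_lo_hz & f <= band$f_hi_hz
  Xf <- stats::mvfft(X)
  Xf[!keep, ] <- 0 + 0i
  Re(stats::mvfft(Xf, inverse = TRUE)) / n
}

#' Ideal (frequency-domain) band-pass filter
#'
#' Zeroes every FFT bin whose frequency lies outside `[f_lo, f_hi]`
#' (edges inclusive; a bin is in-band iff `f_lo <= k/(N*tr) <= f_hi`) and
#' inverse-transforms. Rectangular filter, no tapering. The operation is
#' linear and idempotent.
#'
#' @param x Numeric vector (a voxel time series) or an [fmri_4d()] run,
#'   filtered voxel-wise.
#' @param tr_s Sampling interval in seconds (taken from the run when `x` is
#'   an [fmri_4d()]).
#' @param band A [band_spec()]; default 0.01-0.08 Hz.
#' @return Filtered object of the same shape/class.
#' @export
bandpass_ideal <- function(x, tr_s = NULL, band = band_spec()) {
  if (inherits(x, "fmri_4d")) {
    d <- dim(x$data)
    X <- matrix(x$data, nrow = prod(d[1:3]), ncol = d[4])
    Y <- t(bandpass_matrix(t(X), x$tr_s, band))
    x$data <- array(Y, dim = d)
    return(x)
  }
  if (is.null(tr_s)) stop("`tr_s` required for a bare series", call. = FALSE)
  drop(bandpass_matrix(matrix(as.double(x), ncol = 1L), tr_s, band))
}

#' Remove a least-squares linear trend from each voxel time series
#'
#' Optional pre-filter step, off by default in [preprocess_run()]: the ideal
#' band-pass already removes the low-frequency power of a linear drift, but
#' some ALFF conventions detrend first.
#'
#' @param run An [fmri_4d()].
#' @return The detrended run.
#' @export
detrend_linear <- function(run) {
  stopifnot(inherits(run, "fmri_4d"))
  d <- dim(run$data)
  nt <- d[4]
  tt <- seq_len(nt)
  X <- cbind(1, tt - mean(tt))
  M <- matrix(run$data, nrow = prod(d[1:3]), ncol = nt)
  beta <- M %*% X %*% solve(crossprod(X))   # (voxels x 2)
  run$data <- array(M - tcrossprod(beta, X), dim = d)
  run
}

# dense 1D convolution matrix, Gaussian kernel, half-sample reflective
# boundary; rows sum to 1 so constant signals are preserved exactly
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  h <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  w <- stats::dnorm(-h:h, sd = sigma_vox)
  w <- w / sum(w)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (m in -h:h) {
      j <- i + m
      while (j < 1L || j > n) {
        if (j < 1L) j <- 1L - j
        if (j > n) j <- 2L * n + 1L - j
      }
      C[i, j] <- C[i, j] + w[m + h + 1L]
    }
  }
  C
}

# apply per-axis convolution matrices to a 3D array
smooth3d <- function(arr, C1, C2, C3) {
  d <- dim(arr)
  m <- C1 %*% matrix(arr, d[1], d[2] * d[3])
  arr <- array(m, d)
  arr <- aperm(arr, c(2L, 1L, 3L))
  m <- C2 %*% matrix(arr, d[2], d[1] * d[3])
  arr <- aperm(array(m, d[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
  arr <- aperm(arr, c(3L, 2L, 1L))
  m <- C3 %*% matrix(arr, d[3], d[2] * d[1])
  aperm(array(m, d[c(3L, 2L, 1L)]), c(3L, 2L, 1L))
}

#' Gaussian spatial smoothing
#'
#' Separable per-axis Gaussian smoothing with
#' `sigma_voxels = fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm`,
#' half-sample reflective boundary handling. 4D inputs are smoothed
#' volume-by-volume. `fwhm_mm = 0` is the identity.
#'
#' @param x 3D/4D numeric array, [fmri_4d()] or [scalar_map()].
#' @param fwhm_mm Kernel full width at half maximum in mm (>= 0).
#' @param voxel_size_mm Length-3 voxel edge lengths in mm (derived from the
#'   affine for package objects).
#' @return Smoothed object of the same shape/class.
#' @export
smooth_gaussian <- function(x, fwhm_mm, voxel_size_mm = NULL) {
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0", call. = FALSE)
  if (inherits(x, "fmri_4d") || inherits(x, "scalar_map")) {
    vs <- voxel_sizes(x$affine)
    x$data <- smooth_gaussian(x$data, fwhm_mm, vs)
    return(x)
  }
  if (is.null(voxel_size_mm)) stop("`voxel_size_mm` required", call. = FALSE)
  voxel_size_mm <- rep_len(voxel_size_mm, 3L)
  if (fwhm_mm == 0) return(x)
  d <- dim(x)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  C1 <- gauss_conv_matrix(d[1], sig[1])
  C2 <- gauss_conv_matrix(d[2], sig[2])
  C3 <- gauss_conv_matrix(d[3], sig[3])
  if (length(d) == 3L) return(smooth3d(x, C1, C2, C3))
  if (length(d) != 4L) stop("expect a 3D or 4D array", call. = FALSE)
  smooth4d(x, C1, C2, C3)
}

# volume-by-volume separable smoothing of a 4D array, all volumes at once
smooth4d <- function(arr, C1, C2, C3) {
  d <- dim(arr)
  m <- C1 %*% matrix(arr, d[1], prod(d[-1]))
  arr <- array(m, d)
  arr <- aperm(arr, c(2L, 1L, 3L, 4L))
  m <- C2 %*% matrix(arr, d[2], d[1] * d[3] * d[4])
  arr <- aperm(array(m, d[c(2L, 1L, 3L, 4L)]), c(2L, 1L, 3L, 4L))
  arr <- aperm(arr, c(3L, 2L, 1L, 4L))
  m <- C3 %*% matrix(arr, d[3], d[2] * d[1] * d[4])
  aperm(array(m, d[c(3L, 2L, 1L, 4L)]), c(3L, 2L, 1L, 4L))
}

#' Standard preprocessing chain for one run
#'
#' Applies, in order: initial-volume discard, optional linear detrending,
#' Gaussian spatial smoothing, and ideal band-pass filtering — the minimal
#' chain preceding ALFF on spatially aligned data.
#'
#' @param run An [fmri_4d()].
#' @param discard Leading volumes to drop (default 10).
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 8; 0 disables).
#' @param band A [band_spec()] (default 0.01-0.08 Hz).
#' @param detrend Remove a linear trend before filtering? Default `FALSE`.
#' @return The preprocessed [fmri_4d()].
#' @export
preprocess_run <- function(run, discard = 10L, fwhm_mm = 8,
                           band = band_spec(), detrend = FALSE) {
  run <- discard_initial(run, discard)
  if (detrend) run <- detrend_linear(run)
  if (fwhm_mm > 0) run <- smooth_gaussian(run, fwhm_mm)
  bandpass_ideal(run, band = band)
}
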