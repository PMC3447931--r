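# ALFF: the mean of the one-sided amplitude (square-rooted power) spectrum
# over the low-frequency band, computed voxel-wise, then standardized by
# the global (within-mask) mean.

#' One-sided amplitude spectrum of a time series
#'
#' FFT of the full series (no zero padding, no taper), folded to one side
#' and normalized so that a pure sinusoid of amplitude `A` at an exact bin
#' frequency yields amplitude `A` at that bin:
#' `amp(k) = (2/N)|X(k)|` for `0 < k < N/2`, and `(1/N)|X(k)|` at `k = 0`
#' and (for even `N`) at the Nyquist bin.
#'
#' @param x Numeric vector, length `N >= 2`.
#' @param tr_s Sampling interval in seconds.
#' @return A list with `freq_hz` (bin frequencies `k/(N*tr)`) and
#'   `amplitude`.
#' @export
amplitude_spectrum <- function(x, tr_s) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (tr_s <= 0) stop("`tr_s` must be > 0", call. = FALSE)
  kmax <- n %/% 2L
  X <- stats::fft(x)[seq_len(kmax + 1L)]
  scale <- rep(2 / n, kmax + 1L)
  scale[1L] <- 1 / n
  if (n %% 2L == 0L) scale[kmax + 1L] <- 1 / n
  list(freq_hz = (0:kmax) / (n * tr_s), amplitude = scale * Mod(X))
}

# indices (into 0..floor(N/2)) of one-sided bins inside the band
inband_bins <- function(n, tr_s, band) {
  k <- 0:(n %/% 2L)
  f <- k / (n * tr_s)
  k[f >= band$f_lo_hz & f <= band$f_hi_hz]
}

# ALFF of the columns of a (time x voxels) matrix
alff_matrix <- function(X, tr_s, band) {
  n <- nrow(X)
  ks <- inband_bins(n, tr_s, band)
  if (length(ks) == 0L)
    stop(sprintf(
      "no FFT bins fall inside [%g, %g] Hz for N = %d, TR = %g s (%d one-sided bins)",
      band$f_lo_hz, band$f_hi_hz, n, tr_s, n %/% 2L + 1L), call. = FALSE)
  Xf <- stats::mvfft(X)[ks + 1L, , drop = FALSE]
  scale <- ifelse(ks == 0L | (n %% 2L == 0L & ks == n %/% 2L), 1 / n, 2 / n)
  colMeans(Mod(Xf) * scale)
}

#' Voxel-wise ALFF map
#'
#' For each in-mask voxel, ALFF is the mean of the one-sided amplitude
#' spectrum (see [amplitude_spectrum()]) over the bins inside `band`.
#' Out-of-mask voxels are set to 0. The run should already be preprocessed
#' ([preprocess_run()]); since only in-band bins are averaged, applying the
#' ideal band-pass first does not change the result.
#'
#' @param run An [fmri_4d()].
#' @param mask A [brain_mask()] on the same grid.
#' @param band A [band_spec()]; default 0.01-0.08 Hz.
#' @return A [scalar_map()] of kind `"alff"` (nonnegative everywhere).
#' @export
compute_alff <- function(run, mask, band = band_spec()) {
  stopifnot(inherits(run, "fmri_4d"), inherits(mask, "brain_mask"))
  d <- dim(run$data)
  if (!all(d[1:3] == dim(mask$data)))
    stop("mask grid does not match run grid", call. = FALSE)
  check_band(band, run$tr_s)
  M <- matrix(run$data, nrow = prod(d[1:3]), ncol = d[4])
  idx <- which(mask$data)
  vals <- alff_matrix(t(M[idx, , drop = FALSE]), run$tr_s, band)
  out <- array(0, dim = d[1:3])
  out[idx] <- vals
  scalar_map(out, affine = run$affine, kind = "alff")
}

#' Standardize an ALFF map by its global mean
#'
#' Divides every in-mask voxel by the mean ALFF over the mask, making maps
#' comparable across subjects; the resulting in-mask mean is 1.
#'
#' @param alff A [scalar_map()] (kind `"alff"`).
#' @param mask A [brain_mask()] on the same grid.
#' @return A [scalar_map()] of kind `"malff"`.
#' @export
standardize_alff <- function(alff, mask) {
  stopifnot(inherits(alff, "scalar_map"), inherits(mask, "brain_mask"))
  if (!all(dim(alff$data) == dim(mask$data)))
    stop("mask grid does not match map grid", call. = FALSE)
  idx <- which(mask$data)
  g <- mean(alff$data[idx])
  if (!is.finite(g) || g <= 0)
    stop("degenerate input: global mean ALFF inside mask is not positive",
         call. = FALSE)
  out <- array(0, dim = dim(alff$data))
  out[idx] <- alff$data[idx] / g
  scalar_map(out, affine = alff$affine, kind = "malff")
}

#' mALFF maps for a collection of runs
#'
#' Convenience wrapper: preprocess each run, compute ALFF, standardize.
#'
#' @param runs List of [fmri_4d()].
#' @param mask Shared [brain_mask()].
#' @param band A [band_spec()].
#' @param discard,fwhm_mm,detrend Forwarded to [preprocess_run()].
#' @return Named list of `"malff"` [scalar_map()]s (names = subject ids).
#' @export
malff_maps <- function(runs, mask, band = band_spec(), discard = 10L,
                       fwhm_mm = 8, detrend = FALSE) {
  out <- lapply(runs, function(r) {
    r <- preprocess_run(r, discard = discard, fwhm_mm = fwhm_mm,
                        band = band, detrend = detrend)
    standardize_alff(compute_alff(r, mask, band), mask)
  })
  names(out) <- vapply(runs, function(r) r$subject_id, "")
  out
}
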