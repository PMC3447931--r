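# Synthetic resting-state cohort generator with planted, recoverable
# ground truth. The in-band signal at each voxel is a sum of K sinusoids
# placed on exact FFT bins of the retained (post-discard) run length, with
# independent uniform phases; exact-bin placement keeps closed-form
# amplitude spectra available for the test suite. Nuisance ("respiratory",
# "cardiac") sinusoids are snapped to exact out-of-band bins of their
# aliased frequency so they contribute no leakage into the analysis band.

#' Synthetic cohort configuration
#'
#' Defaults state the emulated acquisition: TR = 2 s, 200 volumes of which
#' the first 10 are discarded, two groups of 20 subjects, and clinical
#' summaries matching the emulated ALS cohort (age 45.3 +/- 10.0 y vs
#' 47.1 +/- 9.9 y, 13:7 vs 14:6 male:female, duration 15.2 +/- 10.4 months,
#' ALSFRS 31.9 +/- 5.4).
#'
#' @param grid_dims Length-3 positive integers, voxels per axis.
#' @param voxel_size_mm Length-3 voxel edge lengths in mm.
#' @param tr_s Repetition time, seconds.
#' @param n_volumes Volumes per run (> 20).
#' @param n_discard Leading volumes the analysis will discard; in-band
#'   signal frequencies are exact FFT bins of `n_volumes - n_discard`.
#' @param n_per_group Subjects per group (>= 2).
#' @param baseline_amp Per-sinusoid in-band amplitude, arbitrary units.
#' @param effect_rois List of ROIs, each
#'   `list(center = c(i, j, k), radius_mm, multiplier, sign)`: within the
#'   sphere (1-based center voxel, mm radius) the patient-group amplitude
#'   is multiplied by `multiplier^sign` (`sign = +1` increase,
#'   `-1` decrease). The first ROI is the designated ROI for clinical
#'   coupling and amplitude jitter.
#' @param n_sinusoids Number K of in-band sinusoids (default 8).
#' @param signal_band [band_spec()] the sinusoid bins are drawn from.
#' @param nuisance List of `list(freq_hz, amp)` out-of-band nuisance
#'   sinusoids; frequencies beyond Nyquist alias naturally.
#' @param white_noise_sd SD of voxel-wise white noise (>= 0).
#' @param smoothness_fwhm_mm Spatial FWHM of the noise-field smoothing.
#' @param subject_amp_sd SD of the per-subject lognormal amplitude jitter
#'   on the designated ROI; automatically set to 0.2 when
#'   `clinical_coupling_r` is set and no value was given (the coupling
#'   construction needs across-subject amplitude variance).
#' @param clinical_coupling_r Target Pearson correlation (0 < |r| < 1)
#'   between patients' true designated-ROI amplitude and the coupled
#'   clinical variable; `NULL` (default) leaves them independent.
#' @param coupled_variable `"duration_months"` or `"alsfrs"`.
#' @param gm_roi_coupling In `[0, 1)`: patient grey-matter probability
#'   inside effect ROIs is multiplied by `1 - gm_roi_coupling`; default 0
#'   (GM maps independent of the planted effects).
#' @param motion_violators Number of subjects given a motion trace that
#'   violates the 2 mm / 1 degree QC limits (default 0).
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(grid_dims = c(16L, 16L, 16L),
                         voxel_size_mm = c(3, 3, 3),
                         tr_s = 2, n_volumes = 200L, n_discard = 10L,
                         n_per_group = 20L, baseline_amp = 1,
                         effect_rois = list(list(center = c(8L, 8L, 8L),
                                                 radius_mm = 7.5,
                                                 multiplier = 1,
                                                 sign = 1L)),
                         n_sinusoids = 8L,
                         signal_band = band_spec(0.01, 0.08),
                         nuisance = list(list(freq_hz = 0.3, amp = 0.5),
                                         list(freq_hz = 1.1, amp = 0.5)),
                         white_noise_sd = 1,
                         smoothness_fwhm_mm = 6,
                         subject_amp_sd = NULL,
                         clinical_coupling_r = NULL,
                         coupled_variable = c("duration_months", "alsfrs"),
                         gm_roi_coupling = 0,
                         motion_violators = 0L,
                         seed = 1L) {
  coupled_variable <- match.arg(coupled_variable)
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 2L))
    stop("`grid_dims` must be 3 integers >= 2", call. = FALSE)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive reals", call. = FALSE)
  if (tr_s <= 0) stop("`tr_s` must be > 0", call. = FALSE)
  if (n_volumes <= 20L) stop("`n_volumes` must exceed 20", call. = FALSE)
  if (n_discard < 0L || n_discard >= n_volumes)
    stop("`n_discard` out of range", call. = FALSE)
  if (n_per_group < 2L) stop("`n_per_group` must be >= 2", call. = FALSE)
  if (baseline_amp < 0 || white_noise_sd < 0)
    stop("amplitudes and noise SD must be >= 0", call. = FALSE)
  stopifnot(inherits(signal_band, "band_spec"))
  for (roi in effect_rois) {
    if (!all(c("center", "radius_mm", "multiplier") %in% names(roi)))
      stop("each ROI needs center, radius_mm, multiplier", call. = FALSE)
    if (roi$multiplier < 0) stop("ROI multipliers must be >= 0", call. = FALSE)
    rad_vox <- roi$radius_mm / voxel_size_mm
    if (any(roi$center - rad_vox < 1) || any(roi$center + rad_vox > grid_dims))
      stop("effect ROI sphere extends outside the grid", call. = FALSE)
  }
  if (!is.null(clinical_coupling_r)) {
    if (abs(clinical_coupling_r) <= 0 || abs(clinical_coupling_r) >= 1)
      stop("`clinical_coupling_r` must satisfy 0 < |r| < 1", call. = FALSE)
    if (is.null(subject_amp_sd)) subject_amp_sd <- 0.2
    if (subject_amp_sd <= 0)
      stop("clinical coupling needs `subject_amp_sd` > 0 (amplitude must vary across subjects)",
           call. = FALSE)
  }
  if (is.null(subject_amp_sd)) subject_amp_sd <- 0
  if (gm_roi_coupling < 0 || gm_roi_coupling >= 1)
    stop("`gm_roi_coupling` must lie in [0, 1)", call. = FALSE)
  structure(list(
    grid_dims = grid_dims, voxel_size_mm = voxel_size_mm, tr_s = tr_s,
    n_volumes = as.integer(n_volumes), n_discard = as.integer(n_discard),
    n_per_group = as.integer(n_per_group), baseline_amp = baseline_amp,
    effect_rois = effect_rois, n_sinusoids = as.integer(n_sinusoids),
    signal_band = signal_band, nuisance = nuisance,
    white_noise_sd = white_noise_sd,
    smoothness_fwhm_mm = smoothness_fwhm_mm,
    subject_amp_sd = subject_amp_sd,
    clinical_coupling_r = clinical_coupling_r,
    coupled_variable = coupled_variable,
    gm_roi_coupling = gm_roi_coupling,
    motion_violators = as.integer(motion_violators),
    seed = as.integer(seed)), class = "synth_config")
}

# world affine: axis-aligned scaling with the world origin at grid centre
synth_affine <- function(config) {
  aff <- diag(4)
  diag(aff)[1:3] <- config$voxel_size_mm
  aff[1:3, 4] <- -(config$grid_dims - 1) / 2 * config$voxel_size_mm
  aff
}

# logical sphere mask around a 1-based center voxel, radius in mm
roi_sphere <- function(config, center, radius_mm) {
  d <- config$grid_dims
  vs <- config$voxel_size_mm
  dx <- (seq_len(d[1]) - center[1]) * vs[1]
  dy <- (seq_len(d[2]) - center[2]) * vs[2]
  dz <- (seq_len(d[3]) - center[3]) * vs[3]
  r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  r2 <= radius_mm^2
}

# per-voxel per-sinusoid amplitude ground truth for one subject
true_amplitude_map <- function(config, group, jitter = 1) {
  amp <- array(config$baseline_amp, dim = config$grid_dims)
  for (roi in config$effect_rois) {
    sph <- roi_sphere(config, roi$center, roi$radius_mm)
    if (group == "patient") {
      sgn <- roi$sign %||% 1L
      amp[sph] <- amp[sph] * roi$multiplier^sgn
    }
  }
  sph1 <- roi_sphere(config, config$effect_rois[[1]]$center,
                     config$effect_rois[[1]]$radius_mm)
  amp[sph1] <- amp[sph1] * jitter
  amp
}

# fold a frequency into [0, Nyquist] (sampling alias)
alias_freq <- function(f, fs) {
  f <- f %% fs
  if (f > fs / 2) f <- fs - f
  f
}

# snap a nuisance frequency to the nearest exact out-of-band bin of the
# retained run length; returns NA if no out-of-band bin exists
snap_out_of_band <- function(f_hz, n_ret, tr_s, band) {
  fs <- 1 / tr_s
  fa <- alias_freq(f_hz, fs)
  kmax <- n_ret %/% 2L
  k_all <- 1:kmax
  f_all <- k_all / (n_ret * tr_s)
  out <- k_all[f_all < band$f_lo_hz | f_all > band$f_hi_hz]
  if (length(out) == 0L) return(NA_real_)
  out[which.min(abs(out / (n_ret * tr_s) - fa))] / (n_ret * tr_s)
}

#' Generate one synthetic subject
#'
#' Builds a 4D run (in-band sinusoids + nuisance sinusoids + spatially
#' smoothed white noise), a grey-matter probability map, a motion trace,
#' and the subject's ground-truth amplitude map. Deterministic given
#' `(config, group, subject_seed)`.
#'
#' @param config A [synth_config()].
#' @param group `"patient"` or `"control"`.
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Id stored on the run.
#' @param violate_motion Inject a QC-violating motion excursion?
#' @return A list: `run` ([fmri_4d()]), `gm` ([scalar_map()] kind
#'   `"gm_prob"`), `motion` ([motion_trace()]), `truth` (list with `amp`
#'   3D array of per-sinusoid in-band amplitude and `jitter`).
#' @export
generate_subject <- function(config, group = c("patient", "control"),
                             subject_seed = 1L, subject_id = "sub-01",
                             violate_motion = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  group <- match.arg(group)
  set.seed(subject_seed)
  d <- config$grid_dims
  p <- prod(d)
  nt <- config$n_volumes
  n_ret <- nt - config$n_discard
  tr <- config$tr_s
  band <- config$signal_band

  # candidate exact bins of the retained length inside the band
  ks <- inband_bins(n_ret, tr, band)
  ks <- ks[ks > 0L]
  if (length(ks) < 1L)
    stop("no in-band FFT bins for this (n_volumes, n_discard, tr)", call. = FALSE)
  K <- min(config$n_sinusoids, length(ks))
  bins <- sort(sample(ks, K))
  freqs <- bins / (n_ret * tr)

  jitter <- if (config$subject_amp_sd > 0)
    exp(stats::rnorm(1L, 0, config$subject_amp_sd)) else 1
  amp <- true_amplitude_map(config, group, jitter)

  tt <- (0:(nt - 1L)) * tr
  phases <- matrix(stats::runif(p * K, 0, 2 * pi), p, K)
  cosb <- cos(outer(2 * pi * freqs, tt))         # K x nt
  sinb <- sin(outer(2 * pi * freqs, tt))
  a <- as.vector(amp)
  signal <- (a * cos(phases)) %*% cosb - (a * sin(phases)) %*% sinb

  for (nu in config$nuisance) {
    fb <- snap_out_of_band(nu$freq_hz, n_ret, tr, band)
    if (is.na(fb)) next
    psi <- stats::runif(1L, 0, 2 * pi)
    signal <- signal + rep(nu$amp * cos(2 * pi * fb * tt + psi),
                           each = p)
  }

  if (config$white_noise_sd > 0) {
    noise <- array(stats::rnorm(p * nt, 0, config$white_noise_sd),
                   dim = c(d, nt))
    if (config$smoothness_fwhm_mm > 0)
      noise <- smooth_gaussian(noise, config$smoothness_fwhm_mm,
                               config$voxel_size_mm)
    signal <- signal + matrix(noise, p, nt)
  }

  aff <- synth_affine(config)
  run <- fmri_4d(array(signal, dim = c(d, nt)), tr_s = tr, affine = aff,
                 subject_id = subject_id)

  # grey matter: smoothed uniform field rescaled to [0, 1]
  gmf <- array(stats::runif(p), dim = d)
  gmf <- smooth_gaussian(gmf, 4 * max(config$voxel_size_mm),
                         config$voxel_size_mm)
  gmf <- (gmf - min(gmf)) / (max(gmf) - min(gmf))
  if (config$gm_roi_coupling > 0 && group == "patient") {
    for (roi in config$effect_rois) {
      sph <- roi_sphere(config, roi$center, roi$radius_mm)
      gmf[sph] <- gmf[sph] * (1 - config$gm_roi_coupling)
    }
  }
  gm <- scalar_map(gmf, affine = aff, kind = "gm_prob")

  # motion: slow drift + tremor, compliant by default
  drift <- apply(matrix(stats::rnorm(nt * 6L, 0, 0.02), nt, 6L), 2L, cumsum)
  drift <- sweep(drift, 2L, apply(drift, 2L, function(x) max(1, diff(range(x)) / 0.8)), `/`)
  drift[, 4:6] <- drift[, 4:6] * 0.4
  if (violate_motion) {
    half <- nt %/% 2L
    drift[(half + 1L):nt, 1L] <- drift[(half + 1L):nt, 1L] + 3
    drift[(half + 1L):nt, 5L] <- drift[(half + 1L):nt, 5L] + 1.5
  }
  motion <- motion_trace(drift)

  list(run = run, gm = gm, motion = motion,
       truth = list(amp = amp, jitter = jitter, bins = bins))
}

#' Generate a synthetic two-group cohort
#'
#' `2 * n_per_group` subjects (patients first), a shared ellipsoidal brain
#' mask, a clinical table (age, sex, onset site, ALSFRS, disease duration,
#' derived progression rate), and the planted ground truth. When
#' `clinical_coupling_r` is set, the coupled clinical variable is drawn as
#' `r * z(ROI amplitude) + sqrt(1 - r^2) * noise` on standardized scales
#' across patients, then mapped linearly to its clinical units.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_cohort`: `subjects` (list as returned by
#'   [generate_subject()]), `ids`, `groups`, `mask`, `clinical`
#'   (data.frame), `truth` (amplitude array `[x, y, z, subject]`, ROI
#'   masks, per-subject designated-ROI amplitude, planted correlation),
#'   and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_per_group
  total <- 2L * n
  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, total)
  violators <- if (config$motion_violators > 0L)
    sample.int(total, min(config$motion_violators, total)) else integer(0)
  groups <- rep(c("patient", "control"), each = n)
  ids <- c(sprintf("sub-P%02d", seq_len(n)), sprintf("sub-C%02d", seq_len(n)))
  clinical_seed <- sample.int(.Machine$integer.max - 1L, 1L)

  subjects <- vector("list", total)
  for (i in seq_len(total)) {
    subjects[[i]] <- generate_subject(config, groups[i], subject_seeds[i],
                                      subject_id = ids[i],
                                      violate_motion = i %in% violators)
  }

  d <- config$grid_dims
  aff <- synth_affine(config)
  ctr <- (d + 1) / 2
  semi <- d / 2 - 0.5
  xs <- (seq_len(d[1]) - ctr[1]) / semi[1]
  ys <- (seq_len(d[2]) - ctr[2]) / semi[2]
  zs <- (seq_len(d[3]) - ctr[3]) / semi[3]
  ell <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`) <= 1
  mask <- brain_mask(ell, affine = aff)

  roi_masks <- lapply(config$effect_rois, function(roi)
    brain_mask(roi_sphere(config, roi$center, roi$radius_mm), affine = aff))
  roi1 <- roi_masks[[1]]$data
  roi_amp <- vapply(subjects, function(s) mean(s$truth$amp[roi1]), 0)

  set.seed(clinical_seed)
  pat <- seq_len(n); ctl <- n + seq_len(n)
  age <- c(stats::rnorm(n, 45.30, 9.95), stats::rnorm(n, 47.05, 9.89))
  sex <- c(rep(c("M", "F"), c(round(13 / 20 * n), n - round(13 / 20 * n))),
           rep(c("M", "F"), c(round(14 / 20 * n), n - round(14 / 20 * n))))
  onset <- sample(c("bulbar", "cervical", "lumbar"), n, replace = TRUE,
                  prob = c(4, 10, 6) / 20)
  alsfrs <- pmin(pmax(stats::rnorm(n, 31.85, 5.39), 0), 40)
  duration <- pmax(stats::rnorm(n, 15.20, 10.37), 0.5)

  planted_r <- config$clinical_coupling_r
  if (!is.null(planted_r)) {
    z_amp <- roi_amp[pat]
    if (stats::sd(z_amp) == 0)
      stop("clinical coupling needs across-subject amplitude variance", call. = FALSE)
    z_amp <- (z_amp - mean(z_amp)) / stats::sd(z_amp)
    noise <- stats::rnorm(n)
    cov_std <- planted_r * z_amp + sqrt(1 - planted_r^2) * noise
    if (config$coupled_variable == "duration_months") {
      duration <- pmax(15.20 + 10.37 * cov_std, 0.5)
    } else {
      alsfrs <- pmin(pmax(31.85 + 5.39 * cov_std, 0), 40)
    }
  }

  clinical <- data.frame(
    subject_id = ids,
    group = groups,
    age = round(age, 1),
    sex = sex,
    handedness = "R",
    onset_site = c(onset, rep(NA_character_, n)),
    alsfrs = c(alsfrs, rep(NA_real_, n)),
    duration_months = c(duration, rep(NA_real_, n)),
    stringsAsFactors = FALSE)
  clinical$progression_rate <- NA_real_
  clinical$progression_rate[pat] <- progression_rate(alsfrs, duration)

  amp4 <- array(0, dim = c(d, total))
  for (i in seq_len(total)) amp4[, , , i] <- subjects[[i]]$truth$amp

  structure(list(
    subjects = subjects, ids = ids, groups = groups, mask = mask,
    clinical = clinical,
    truth = list(amp = amp4, roi_masks = roi_masks, roi_amp = roi_amp,
                 planted_r = planted_r,
                 coupled_variable = config$coupled_variable,
                 violators = violators),
    config = config), class = "synth_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject 4D runs and grey-matter maps as `.nii.gz`, motion
#' traces as whitespace-delimited 6-column text, the shared brain mask,
#' the clinical table and a design table as CSV, ground-truth ROI masks as
#' NIfTI, and a plain-text manifest.
#'
#' @param cohort A `synth_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cohort$ids)
  design <- data.frame(subject_id = cohort$ids, group = cohort$groups,
                       run_path = NA_character_, gm_path = NA_character_,
                       motion_path = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    id <- cohort$ids[i]
    s <- cohort$subjects[[i]]
    design$run_path[i] <- file.path(dir, paste0(id, "_run.nii.gz"))
    design$gm_path[i] <- file.path(dir, paste0(id, "_gm.nii.gz"))
    design$motion_path[i] <- file.path(dir, paste0(id, "_motion.txt"))
    write_nifti(s$run, design$run_path[i])
    write_nifti(s$gm, design$gm_path[i])
    utils::write.table(s$motion$params, design$motion_path[i],
                       row.names = FALSE, col.names = FALSE)
  }
  write_nifti(cohort$mask, file.path(dir, "mask.nii.gz"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(design, file.path(dir, "design.csv"), row.names = FALSE)
  for (j in seq_along(cohort$truth$roi_masks))
    write_nifti(cohort$truth$roi_masks[[j]],
                file.path(dir, sprintf("truth_roi%02d.nii.gz", j)))
  manifest <- c(
    "alffkit synthetic cohort (all data simulated; no real subjects)",
    sprintf("seed: %d", cohort$config$seed),
    sprintf("subjects: %d (%d per group)", n, cohort$config$n_per_group),
    sprintf("grid: %s voxels of %s mm", paste(cohort$config$grid_dims, collapse = "x"),
            paste(cohort$config$voxel_size_mm, collapse = "x")),
    sprintf("tr_s: %g, n_volumes: %d, n_discard: %d", cohort$config$tr_s,
            cohort$config$n_volumes, cohort$config$n_discard),
    sprintf("planted clinical coupling: %s",
            if (is.null(cohort$truth$planted_r)) "none"
            else sprintf("r = %g with %s", cohort$truth$planted_r,
                         cohort$truth$coupled_variable)))
  writeLines(manifest, file.path(dir, "MANIFEST.txt"))
  invisible(dir)
}
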