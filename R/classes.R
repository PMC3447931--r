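#' Construct a 4D fMRI run
#'
#' A subject's 4D voxel grid (x, y, z, t) together with the repetition time
#' and the voxel-to-world affine. This is the raw input to preprocessing and
#' ALFF computation.
#'
#' @param data Numeric 4D array (x, y, z, t).
#' @param tr_s Repetition time in seconds (> 0).
#' @param affine 4x4 voxel-to-world (mm) transform; must be invertible.
#'   Voxel indices are 0-based in world-coordinate computations.
#' @param subject_id Character scalar identifying the subject.
#' @return An object of class `fmri_4d`.
#' @export
fmri_4d <- function(data, tr_s, affine = diag(4), subject_id = "unknown") {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)", call. = FALSE)
  if (dim(data)[4] < 2L)
    stop("a 4D run needs at least 2 volumes", call. = FALSE)
  if (anyNA(data))
    stop("4D run contains NaN/NA values; refusing to construct", call. = FALSE)
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("`tr_s` must be a single positive number (seconds)", call. = FALSE)
  check_affine(affine)
  structure(
    list(data = data, tr_s = as.numeric(tr_s), affine = affine,
         subject_id = as.character(subject_id)),
    class = "fmri_4d")
}

#' Construct a 3D scalar map
#'
#' A per-voxel 3D map sharing a grid and affine with its companions:
#' an ALFF map, a standardized (mALFF) map, a grey-matter probability map,
#' or a t-statistic map (which additionally carries degrees of freedom).
#'
#' @param data Numeric 3D array.
#' @param affine 4x4 voxel-to-world transform.
#' @param kind One of `"alff"`, `"malff"`, `"gm_prob"`, `"tstat"`, `"generic"`.
#' @param df Degrees of freedom; required when `kind == "tstat"`.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(data, affine = diag(4),
                       kind = c("generic", "alff", "malff", "gm_prob", "tstat"),
                       df = NULL) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (anyNA(data))
    stop("scalar map contains NaN/NA values", call. = FALSE)
  check_affine(affine)
  if (kind == "tstat" && (is.null(df) || df < 1))
    stop("a t-statistic map must carry positive degrees of freedom", call. = FALSE)
  structure(list(data = data, affine = affine, kind = kind,
                 df = if (is.null(df)) NULL else as.integer(df)),
            class = "scalar_map")
}

#' Construct a brain mask
#'
#' @param data Logical (or 0/1 numeric) 3D array; must contain at least one
#'   `TRUE` voxel.
#' @param affine 4x4 voxel-to-world transform.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(data, affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask contains NA", call. = FALSE)
  if (!any(data)) stop("mask is empty", call. = FALSE)
  check_affine(affine)
  structure(list(data = data, affine = affine), class = "brain_mask")
}

#' Construct a motion trace
#'
#' Per-volume rigid-body motion parameters: three translations (mm) and
#' three rotations (degrees), one row per volume.
#'
#' @param params Numeric matrix with 6 columns
#'   (`trans_x`, `trans_y`, `trans_z`, `rot_x`, `rot_y`, `rot_z`).
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  if (ncol(params) != 6L)
    stop("a motion trace has 6 columns: 3 translations (mm), 3 rotations (deg)",
         call. = FALSE)
  if (nrow(params) < 1L) stop("motion trace is empty", call. = FALSE)
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  structure(list(params = params), class = "motion_trace")
}

#' Construct a frequency band specification
#'
#' @param f_lo_hz,f_hi_hz Band edges in Hz; `0 < f_lo < f_hi`. Validity
#'   against the Nyquist frequency is checked where the repetition time is
#'   known (see [bandpass_ideal()]).
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(f_lo_hz = 0.01, f_hi_hz = 0.08) {
  if (!(f_lo_hz > 0 && f_hi_hz > f_lo_hz))
    stop("need 0 < f_lo_hz < f_hi_hz", call. = FALSE)
  structure(list(f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz), class = "band_spec")
}

#' Construct a two-group inference design
#'
#' Subject-to-group assignment plus optional scalar covariates (e.g. total
#' intracranial volume) and optional per-subject image covariates (grey
#' matter probability maps).
#'
#' @param ids Character vector of subject ids.
#' @param group Factor or character vector, one of two levels per subject;
#'   the first level (or `"patient"` if present) is the positive direction
#'   of the group contrast.
#' @param covariates Optional data.frame of scalar covariates, one row per
#'   subject in `ids` order.
#' @param gm_maps Optional list of [scalar_map()] grey-matter covariates,
#'   one per subject, all on the analysis grid.
#' @return An object of class `group_design`.
#' @export
group_design <- function(ids, group, covariates = NULL, gm_maps = NULL) {
  ids <- as.character(ids)
  group <- as.character(group)
  if (length(ids) != length(group))
    stop("`ids` and `group` lengths differ", call. = FALSE)
  lev <- unique(group)
  if (length(lev) != 2L)
    stop("design must have exactly two groups", call. = FALSE)
  if ("patient" %in% lev) lev <- c("patient", setdiff(lev, "patient"))
  if (any(table(group) < 2L))
    stop("need at least 2 subjects per group", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(ids))
      stop("covariate rows must match subjects", call. = FALSE)
  }
  if (!is.null(gm_maps)) {
    if (length(gm_maps) != length(ids))
      stop("need one image covariate per subject", call. = FALSE)
    dims <- lapply(gm_maps, function(m) dim(m$data))
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
      stop("image covariates must share one grid", call. = FALSE)
  }
  structure(list(ids = ids, group = factor(group, levels = lev),
                 covariates = covariates, gm_maps = gm_maps),
            class = "group_design")
}

#' Construct a world coordinate
#'
#' A point in millimetre world space carrying its stereotactic space tag.
#'
#' @param x,y,z Coordinates in mm.
#' @param space `"MNI"` or `"Talairach"`.
#' @return An object of class `world_coordinate`.
#' @export
world_coordinate <- function(x, y, z, space = c("MNI", "Talairach")) {
  space <- match.arg(space)
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                 space = space), class = "world_coordinate")
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  d <- det(affine)
  if (!is.finite(d) || abs(d) < .Machine$double.eps)
    stop("`affine` must be invertible", call. = FALSE)
  invisible(affine)
}

# mm edge lengths of one voxel, from the affine
voxel_sizes <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' @export
print.fmri_4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fmri_4d> %s: %dx%dx%d voxels, %d volumes, TR %.3g s\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' @export
print.scalar_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scalar_map:%s> %dx%dx%d%s\n", x$kind, d[1], d[2], d[3],
              if (!is.null(x$df)) sprintf(", df = %d", x$df) else ""))
  invisible(x)
}

#' @export
print.brain_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brain_mask> %dx%dx%d, %d voxels in mask\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' @export
print.world_coordinate <- function(x, ...) {
  cat(sprintf("(%.1f, %.1f, %.1f) mm [%s]\n", x$x, x$y, x$z, x$space))
  invisible(x)
}
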