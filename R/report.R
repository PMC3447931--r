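# Coordinate reporting and the end-to-end pipeline driver.

# Brett's published mni2tal piecewise-affine coefficients
# (http://imaging.mrc-cbu.cam.ac.uk/imaging/MniTalairach):
# one matrix above the AC-PC plane (z >= 0), one below.
MNI2TAL_UP <- matrix(c(
  0.9900, 0.0000,  0.0000, 0,
  0.0000, 0.9688,  0.0460, 0,
  0.0000, -0.0485, 0.9189, 0,
  0.0000, 0.0000,  0.0000, 1), nrow = 4L, byrow = TRUE)
MNI2TAL_DOWN <- matrix(c(
  0.9900, 0.0000,  0.0000, 0,
  0.0000, 0.9688,  0.0420, 0,
  0.0000, -0.0485, 0.8390, 0,
  0.0000, 0.0000,  0.0000, 1), nrow = 4L, byrow = TRUE)

#' Convert an MNI coordinate to Talairach space
#'
#' Brett piecewise-affine `mni2tal` mapping: one affine for `z >= 0`,
#' another for `z < 0`; the origin is a fixed point of both.
#'
#' @param coord A [world_coordinate()] tagged `"MNI"`.
#' @return A [world_coordinate()] tagged `"Talairach"`.
#' @export
mni_to_talairach <- function(coord) {
  stopifnot(inherits(coord, "world_coordinate"))
  if (coord$space != "MNI")
    stop("input coordinate is tagged ", coord$space, ", not MNI", call. = FALSE)
  M <- if (coord$z >= 0) MNI2TAL_UP else MNI2TAL_DOWN
  v <- M %*% c(coord$x, coord$y, coord$z, 1)
  world_coordinate(v[1], v[2], v[3], space = "Talairach")
}

# add Talairach peak columns to a cluster table (peaks assumed MNI)
add_talairach_columns <- function(tab) {
  if (nrow(tab) == 0L) {
    tab$tal_x_mm <- numeric(0); tab$tal_y_mm <- numeric(0)
    tab$tal_z_mm <- numeric(0)
    return(tab)
  }
  tal <- t(vapply(seq_len(nrow(tab)), function(i) {
    w <- mni_to_talairach(world_coordinate(tab$peak_x_mm[i], tab$peak_y_mm[i],
                                           tab$peak_z_mm[i], "MNI"))
    c(w$x, w$y, w$z)
  }, numeric(3)))
  tab$tal_x_mm <- tal[, 1]; tab$tal_y_mm <- tal[, 2]; tab$tal_z_mm <- tal[, 3]
  tab
}

#' Run the full analysis pipeline on a cohort directory
#'
#' Reads a cohort as written by [write_cohort()] (design table, clinical
#' table, brain mask, per-subject runs / grey-matter maps / motion
#' traces), then: applies motion QC, preprocesses each run
#' (initial-volume discard, smoothing, band-pass), computes standardized
#' ALFF maps, runs the two-group permutation cluster-FWE comparison
#' (optionally repeated with grey-matter maps as voxel-wise covariates),
#' extracts significant clusters as VOIs, and correlates patient VOI mean
#' mALFF with clinical variables. All outputs, the resolved configuration
#' and a structured log are written to `out_dir`.
#'
#' @param data_dir Cohort directory (must contain `design.csv`,
#'   `clinical.csv`, `mask.nii.gz`).
#' @param out_dir Output directory (created).
#' @param discard,fwhm_mm,band Preprocessing parameters (defaults 10, 8 mm,
#'   0.01-0.08 Hz).
#' @param config An [inference_config()].
#' @param gm_covariate Also run the grey-matter-corrected comparison?
#' @param exclude_failed_qc Drop subjects failing motion QC (default TRUE;
#'   at least 2 per group must remain).
#' @return Invisibly, a list: `malff`, `clusters` (plain), `clusters_gm`
#'   (or NULL), `correlations` (or NULL), `qc`, `paths`.
#' @export
run_pipeline <- function(data_dir, out_dir, discard = 10L, fwhm_mm = 8,
                         band = band_spec(), config = inference_config(),
                         gm_covariate = FALSE, exclude_failed_qc = TRUE) {
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logi <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  fail <- function(stage, id, msg)
    stop(sprintf("pipeline stage `%s` failed for %s: %s", stage, id, msg),
         call. = FALSE)

  design <- utils::read.csv(file.path(data_dir, "design.csv"),
                            stringsAsFactors = FALSE)
  clinical <- utils::read.csv(file.path(data_dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  mask <- read_nifti(file.path(data_dir, "mask.nii.gz"), as = "mask")
  logi("loaded design (%d subjects) from %s", nrow(design), data_dir)

  # motion QC
  qc <- data.frame(subject_id = design$subject_id, pass = NA,
                   failed_axes = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(design))) {
    tr_tab <- tryCatch(
      as.matrix(utils::read.table(design$motion_path[i])),
      error = function(e) fail("motion_qc", design$subject_id[i], conditionMessage(e)))
    res <- motion_qc(motion_trace(tr_tab))
    qc$pass[i] <- res$pass
    qc$failed_axes[i] <- paste(res$failed_axes, collapse = ";")
  }
  keep <- if (exclude_failed_qc) qc$pass else rep(TRUE, nrow(design))
  logi("motion QC: %d/%d subjects pass", sum(qc$pass), nrow(qc))
  design_kept <- design[keep, , drop = FALSE]
  if (any(table(design_kept$group) < 2L))
    stop("fewer than 2 subjects per group remain after motion QC", call. = FALSE)

  # per-subject mALFF
  malff <- list()
  gm_maps <- list()
  for (i in seq_len(nrow(design_kept))) {
    id <- design_kept$subject_id[i]
    run <- tryCatch(read_nifti(design_kept$run_path[i], as = "fmri",
                               subject_id = id),
                    error = function(e) fail("read", id, conditionMessage(e)))
    m <- tryCatch({
      run <- preprocess_run(run, discard = discard, fwhm_mm = fwhm_mm,
                            band = band)
      standardize_alff(compute_alff(run, mask, band), mask)
    }, error = function(e) fail("alff", id, conditionMessage(e)))
    malff[[id]] <- m
    write_nifti(m, file.path(out_dir, paste0(id, "_malff.nii.gz")))
    if (gm_covariate)
      gm_maps[[id]] <- tryCatch(
        read_nifti(design_kept$gm_path[i], as = "map", kind = "gm_prob"),
        error = function(e) fail("read_gm", id, conditionMessage(e)))
  }
  logi("computed %d mALFF maps (discard %d, fwhm %g mm, band %g-%g Hz)",
       length(malff), discard, fwhm_mm, band$f_lo_hz, band$f_hi_hz)

  dsg <- group_design(design_kept$subject_id, design_kept$group,
                      gm_maps = if (gm_covariate) unname(gm_maps) else NULL)
  tab <- permutation_cluster_fwe(malff, dsg, mask, config)
  tab <- add_talairach_columns(tab)
  write_nifti(attr(tab, "tmap"), file.path(out_dir, "tmap.nii.gz"))
  utils::write.csv(as.data.frame(tab), file.path(out_dir, "clusters.csv"),
                   row.names = FALSE)
  sig <- which(tab$corrected_p <= config$cluster_alpha)
  logi("group inference: %d cluster(s), %d significant at alpha %g",
       nrow(tab), length(sig), config$cluster_alpha)

  tab_gm <- NULL
  if (gm_covariate) {
    tmap_gm <- ancova_image_covariate(malff, dsg, mask)
    tab_gm <- extract_clusters(tmap_gm, config$cluster_forming_t,
                               config$connectivity, config$tail)
    tab_gm <- add_talairach_columns(tab_gm)
    write_nifti(tmap_gm, file.path(out_dir, "tmap_gm_corrected.nii.gz"))
    utils::write.csv(as.data.frame(tab_gm),
                     file.path(out_dir, "clusters_gm_corrected.csv"),
                     row.names = FALSE)
    logi("GM-corrected inference: %d cluster(s)", nrow(tab_gm))
  }

  # VOI correlations on significant clusters, patients only
  correlations <- NULL
  if (length(sig) > 0L) {
    members <- attr(tab, "voxel_members")
    vois <- list()
    for (s in sig) {
      vm <- array(FALSE, dim = dim(mask$data))
      vm[members[[s]]] <- TRUE
      vois[[sprintf("cluster%02d_%s", tab$cluster_id[s], tab$tail[s])]] <-
        brain_mask(vm, affine = mask$affine)
      write_nifti(vois[[length(vois)]],
                  file.path(out_dir, sprintf("voi_cluster%02d.nii.gz",
                                             tab$cluster_id[s])))
    }
    pat_ids <- design_kept$subject_id[design_kept$group == "patient"]
    clin_pat <- clinical[match(pat_ids, clinical$subject_id), , drop = FALSE]
    if (length(pat_ids) >= 3L) {
      correlations <- tryCatch(
        correlate_vois(malff[pat_ids], vois, clin_pat),
        error = function(e) {
          logi("correlation skipped: %s", conditionMessage(e)); NULL
        })
      if (!is.null(correlations))
        utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                         row.names = FALSE)
    }
  }

  resolved <- c(
    sprintf("data_dir=%s", data_dir),
    sprintf("discard=%d", discard),
    sprintf("fwhm_mm=%g", fwhm_mm),
    sprintf("band=%g %g", band$f_lo_hz, band$f_hi_hz),
    sprintf("cluster_forming_t=%g", config$cluster_forming_t),
    sprintf("cluster_alpha=%g", config$cluster_alpha),
    sprintf("n_permutations=%d", config$n_permutations),
    sprintf("connectivity=%d", config$connectivity),
    sprintf("tail=%s", config$tail),
    sprintf("seed=%d", config$seed),
    sprintf("gm_covariate=%s", gm_covariate),
    sprintf("exclude_failed_qc=%s", exclude_failed_qc))
  writeLines(resolved, file.path(out_dir, "resolved_config.txt"))
  logi("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  utils::write.csv(qc, file.path(out_dir, "motion_qc.csv"), row.names = FALSE)

  invisible(list(malff = malff, clusters = tab, clusters_gm = tab_gm,
                 correlations = correlations, qc = qc,
                 paths = list(out_dir = out_dir)))
}
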