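# Synthetic cohort generator: determinism, planted effects, clinical
# coupling, motion injection, cohort assembly and on-disk layout.

test_that("identical (config, seed) gives bit-identical subjects", {
  cfg <- tiny_config(white_noise_sd = 0.8,
                     nuisance = list(list(freq_hz = 0.3, amp = 0.5)))
  s1 <- generate_subject(cfg, "patient", 123, "a")
  s2 <- generate_subject(cfg, "patient", 123, "a")
  expect_identical(s1$run$data, s2$run$data)
  expect_identical(s1$gm$data, s2$gm$data)
  expect_identical(s1$motion$params, s2$motion$params)
  # and a different seed gives different data
  s3 <- generate_subject(cfg, "patient", 124, "a")
  expect_false(identical(s1$run$data, s3$run$data))
})

test_that("multiplier 1 plants no group difference in true amplitude", {
  cfg <- tiny_config(multiplier = 1, n_per_group = 2L)
  co <- generate_cohort(cfg)
  pat <- which(co$groups == "patient"); ctl <- which(co$groups == "control")
  mp <- apply(co$truth$amp[, , , pat], 1:3, mean)
  mc <- apply(co$truth$amp[, , , ctl], 1:3, mean)
  expect_equal(mp, mc)
})

test_that("noise-free multiplier 2 yields ALFF ratio 2 inside the ROI", {
  cfg <- tiny_config(multiplier = 2)
  sp <- generate_subject(cfg, "patient", 11, "p")
  sc <- generate_subject(cfg, "control", 12, "c")
  msk <- full_mask(cfg$grid_dims, sp$run$affine)
  ap <- compute_alff(sp$run, msk)
  ac <- compute_alff(sc$run, msk)
  roi <- alffkit:::roi_sphere(cfg, cfg$effect_rois[[1]]$center,
                              cfg$effect_rois[[1]]$radius_mm)
  expect_lt(abs(mean(ap$data[roi]) / mean(ac$data[roi]) - 2), 1e-6)
  # sign = -1 plants a decrease of the same magnitude
  cfgd <- tiny_config(multiplier = 2, sign = -1L)
  spd <- generate_subject(cfgd, "patient", 11, "p")
  apd <- compute_alff(spd$run, msk)
  expect_lt(abs(mean(apd$data[roi]) / mean(ac$data[roi]) - 0.5), 1e-6)
})

test_that("zero-noise recovery is exact up to one global constant", {
  cfg <- tiny_config(multiplier = 1.5)
  s <- generate_subject(cfg, "patient", 5, "p")
  msk <- full_mask(cfg$grid_dims, s$run$affine)
  alff <- compute_alff(s$run, msk)
  ratio <- alff$data / s$truth$amp
  expect_lt(diff(range(ratio)), 1e-9)   # one constant, all voxels
})

test_that("cohorts have the right size, labels and clinical fields", {
  cfg <- tiny_config(grid = c(6L, 6L, 6L), n_volumes = 32L,
                     n_per_group = 20L, center = c(3L, 3L, 3L), radius_mm = 4)
  co <- generate_cohort(cfg)
  expect_length(co$subjects, 40L)
  expect_equal(as.vector(table(co$groups)), c(20L, 20L))
  cl <- co$clinical
  expect_setequal(
    c("subject_id", "group", "age", "sex", "alsfrs", "duration_months",
      "progression_rate"),
    intersect(names(cl), c("subject_id", "group", "age", "sex", "alsfrs",
                           "duration_months", "progression_rate")))
  pat <- cl[cl$group == "patient", ]
  expect_true(all(pat$duration_months > 0))
  expect_true(all(pat$alsfrs >= 0 & pat$alsfrs <= 40))
  expect_equal(pat$progression_rate,
               (40 - pat$alsfrs) / pat$duration_months)
  expect_equal(sum(pat$sex == "M"), 13L)  # 13:7 at n = 20
  expect_true(all(is.na(cl$alsfrs[cl$group == "control"])))
})

test_that("clinical coupling hits the planted correlation", {
  rs <- vapply(1:20, function(s) {
    cfg <- tiny_config(grid = c(6L, 6L, 6L), n_volumes = 32L,
                       n_per_group = 50L, center = c(3L, 3L, 3L),
                       radius_mm = 4, clinical_coupling_r = 0.9, seed = s)
    co <- generate_cohort(cfg)
    pat <- which(co$groups == "patient")
    cor(co$truth$roi_amp[pat], co$clinical$duration_months[pat])
  }, 0)
  expect_lt(max(abs(rs - 0.9)), 0.1)
})

test_that("without coupling the covariate is independent of amplitude", {
  # null distribution of Pearson r at n = 40: |r| < 0.35 has probability
  # ~0.973, so the >= 0.95 bound needs enough seeds to be stable
  rs <- vapply(1:200, function(s) {
    cfg <- tiny_config(grid = c(5L, 5L, 5L), n_volumes = 24L,
                       n_per_group = 40L, center = c(3L, 3L, 3L),
                       radius_mm = 4, subject_amp_sd = 0.2, seed = s)
    co <- generate_cohort(cfg)
    pat <- which(co$groups == "patient")
    cor(co$truth$roi_amp[pat], co$clinical$duration_months[pat])
  }, 0)
  expect_gte(mean(abs(rs) < 0.35), 0.95)
})

test_that("motion traces are compliant unless violators are requested", {
  cfg <- tiny_config(n_per_group = 2L, motion_violators = 1L)
  co <- generate_cohort(cfg)
  qc <- vapply(co$subjects, function(s) motion_qc(s$motion)$pass, TRUE)
  expect_equal(sum(!qc), 1L)
  expect_equal(which(!qc), co$truth$violators)
  cfg0 <- tiny_config(n_per_group = 2L)
  co0 <- generate_cohort(cfg0)
  expect_true(all(vapply(co0$subjects, function(s) motion_qc(s$motion)$pass, TRUE)))
})

test_that("grey-matter maps live in [0, 1] and can couple to the ROI", {
  cfg <- tiny_config(n_per_group = 2L, gm_roi_coupling = 0.5)
  co <- generate_cohort(cfg)
  for (s in co$subjects)
    expect_true(all(s$gm$data >= 0 & s$gm$data <= 1))
  roi <- co$truth$roi_masks[[1]]$data
  gm_pat <- sapply(co$subjects[co$groups == "patient"],
                   function(s) mean(s$gm$data[roi]))
  gm_ctl <- sapply(co$subjects[co$groups == "control"],
                   function(s) mean(s$gm$data[roi]))
  expect_lt(mean(gm_pat), mean(gm_ctl))
})

test_that("invalid configurations are refused", {
  expect_error(synth_config(grid_dims = c(0, 4, 4)), "grid_dims")
  expect_error(synth_config(n_volumes = 10L), "exceed 20")
  expect_error(tiny_config(radius_mm = 100), "outside the grid")
  expect_error(synth_config(clinical_coupling_r = 1.2), "0 < |r| < 1",
               fixed = TRUE)
  expect_error(synth_config(clinical_coupling_r = 0.5, subject_amp_sd = 0),
               "subject_amp_sd")
  expect_error(synth_config(n_per_group = 1L), ">= 2")
})

test_that("write_cohort produces a loadable on-disk layout", {
  cfg <- tiny_config(n_per_group = 2L, white_noise_sd = 0.5)
  co <- generate_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  design <- read.csv(file.path(dir, "design.csv"))
  expect_equal(nrow(design), 4L)
  run <- read_nifti(design$run_path[1], as = "fmri")
  expect_equal(run$tr_s, cfg$tr_s)
  expect_equal(dim(run$data), c(cfg$grid_dims, cfg$n_volumes))
  expect_equal(run$data, co$subjects[[1]]$run$data, tolerance = 2e-6)
  mt <- as.matrix(read.table(design$motion_path[1]))
  expect_equal(unname(mt), unname(co$subjects[[1]]$motion$params),
               tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "MANIFEST.txt")))
  expect_true(file.exists(file.path(dir, "truth_roi01.nii.gz")))
  unlink(dir, recursive = TRUE)
})
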