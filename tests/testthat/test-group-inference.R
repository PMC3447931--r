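# Group inference: t-maps, summary tests, cluster machinery, permutation
# FWE mechanics, covariate models — each against independent oracles.

mk_maps <- function(n, dims = c(4L, 4L, 4L), seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    scalar_map(array(rnorm(prod(dims)), dims)))
}

test_that("two_sample_tmap: zero under identity, oracle on random maps", {
  msk <- full_mask(c(4, 4, 4))
  maps <- mk_maps(3L)
  t0 <- two_sample_tmap(maps, maps, msk)
  expect_true(all(t0$data == 0))
  expect_equal(t0$df, 4L)

  a <- mk_maps(5L, seed = 2); b <- mk_maps(5L, seed = 3)
  tm <- two_sample_tmap(a, b, msk)
  expect_equal(tm$df, 8L)
  # oracle: per-voxel var.equal t.test
  for (v in c(1L, 17L, 64L)) {
    xa <- sapply(a, function(m) m$data[v])
    xb <- sapply(b, function(m) m$data[v])
    want <- t.test(xa, xb, var.equal = TRUE)$statistic
    expect_equal(tm$data[v], unname(want), tolerance = 1e-10)
  }
  # sign anti-symmetry
  rev <- two_sample_tmap(b, a, msk)
  expect_equal(rev$data, -tm$data, tolerance = 1e-12)
  expect_error(two_sample_tmap(a, mk_maps(5L, dims = c(3L, 3L, 3L)), msk),
               "grid")
})

test_that("zero-variance voxels give t = 0 and are counted", {
  msk <- full_mask(c(2, 2, 2))
  a <- lapply(1:3, function(i) scalar_map(array(1, c(2, 2, 2))))
  b <- lapply(1:3, function(i) scalar_map(array(2, c(2, 2, 2))))
  expect_message(tm <- two_sample_tmap(a, b, msk), "zero-variance")
  expect_true(all(tm$data == 0))
  expect_equal(attr(tm, "n_zero_variance"), 8L)
})

test_that("t_test_from_summary reproduces printed and closed-form values", {
  # demographic age comparison: 45.30+/-9.95 vs 47.05+/-9.89, n = 20 each
  res <- t_test_from_summary(45.30, 9.95, 20, 47.05, 9.89, 20)
  expect_equal(round(res$p, 2), 0.58)
  expect_equal(res$df, 38)
  # closed form: t = -1 / sqrt(2/10)
  res2 <- t_test_from_summary(0, 1, 10, 1, 1, 10)
  expect_equal(res2$t, -1 / sqrt(2 / 10), tolerance = 1e-3)
  expect_equal(t_test_from_summary(5, 1, 10, 5, 1, 10)$p, 1)
  expect_equal(t_test_from_summary(5, 0, 10, 5, 0, 10),
               list(t = 0, df = 18, p = 1))
  # oracle: t.test on raw data with matching summaries
  set.seed(9)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  want <- t.test(x, y, var.equal = TRUE)
  got <- t_test_from_summary(mean(x), sd(x), 12, mean(y), sd(y), 15)
  expect_equal(got$t, unname(want$statistic), tolerance = 1e-10)
  expect_equal(got$p, want$p.value, tolerance = 1e-10)
})

test_that("chi_square_2x2 reproduces the printed sex comparison", {
  res <- chi_square_2x2(13, 7, 14, 6)
  expect_equal(round(res$p, 2), 0.74)
  expect_equal(res$statistic, 0.1140, tolerance = 1e-3)
  # direct formula evaluation as the oracle
  expect_equal(res$statistic, 40 * (13 * 6 - 7 * 14)^2 / (20 * 20 * 27 * 13))
  # base-R oracle without continuity correction
  want <- chisq.test(matrix(c(13, 14, 7, 6), 2), correct = FALSE)
  expect_equal(res$statistic, unname(want$statistic), tolerance = 1e-12)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$statistic, 0)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$p, 1)
  expect_error(chi_square_2x2(0, 0, 5, 5), "margin")
})

test_that("critical_t: printed threshold, median, and normal limit", {
  expect_equal(round(critical_t(0.001, 38, "one"), 2), 3.32)
  expect_equal(critical_t(0.5, 7, "one"), 0)
  expect_equal(critical_t(0.025, 1e6, "one"), 1.96, tolerance = 0.01)
  expect_equal(critical_t(0.05, 30, "two"), qt(0.975, 30))
})

test_that("extract_clusters: blocks, connectivity rules, partition", {
  dims <- c(8L, 8L, 8L)
  tm <- array(0, dims)
  tm[3:5, 3:5, 3:5] <- 5
  map <- scalar_map(tm, kind = "tstat", df = 38L)
  tab <- extract_clusters(map, 3.32)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_voxels, 27L)
  expect_equal(tab$peak_t, 5)
  # all-zero map -> empty table
  expect_equal(nrow(extract_clusters(
    scalar_map(array(0, dims), kind = "tstat", df = 10L), 3.32)), 0L)

  # edge-adjacent pair: one cluster at 18/26, two at 6
  tm2 <- array(0, dims); tm2[1, 1, 1] <- 4; tm2[2, 2, 1] <- 4
  m2 <- scalar_map(tm2, kind = "tstat", df = 10L)
  expect_equal(nrow(extract_clusters(m2, 3.32, connectivity = 6L)), 2L)
  expect_equal(nrow(extract_clusters(m2, 3.32, connectivity = 18L)), 1L)
  expect_equal(nrow(extract_clusters(m2, 3.32, connectivity = 26L)), 1L)
  # corner-adjacent pair: one cluster only at 26
  tm3 <- array(0, dims); tm3[1, 1, 1] <- 4; tm3[2, 2, 2] <- 4
  m3 <- scalar_map(tm3, kind = "tstat", df = 10L)
  expect_equal(nrow(extract_clusters(m3, 3.32, connectivity = 18L)), 2L)
  expect_equal(nrow(extract_clusters(m3, 3.32, connectivity = 26L)), 1L)

  # negative tail handled separately; partition property
  set.seed(12)
  tr <- array(rnorm(prod(dims), sd = 3), dims)
  mr <- scalar_map(tr, kind = "tstat", df = 10L)
  for (conn in c(6L, 18L, 26L)) {
    tab <- extract_clusters(mr, 3, connectivity = conn)
    expect_equal(sum(tab$n_voxels), sum(abs(tr) > 3))
  }
})

test_that("component labelling agrees with a brute-force flood fill", {
  dims <- c(6L, 6L, 6L)
  set.seed(13)
  for (conn in c(6L, 18L, 26L)) {
    pat <- which(array(runif(prod(dims)) < 0.25, dims))
    got <- alffkit:::label_components(pat, dims, conn)
    want <- naive_components(pat, dims, conn)
    # same partition: equal label matrices up to renaming
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
  }
})

test_that("peak world coordinates follow the affine (0-based indices)", {
  dims <- c(5L, 5L, 5L)
  aff <- diag(4); diag(aff)[1:3] <- c(3, 3, 3); aff[1:3, 4] <- c(-6, -6, -6)
  tm <- array(0, dims); tm[4, 2, 5] <- 6
  tab <- extract_clusters(scalar_map(tm, affine = aff, kind = "tstat", df = 8L), 3)
  expect_equal(c(tab$peak_i, tab$peak_j, tab$peak_k), c(3, 1, 4))
  expect_equal(c(tab$peak_x_mm, tab$peak_y_mm, tab$peak_z_mm),
               c(3 * 3 - 6, 1 * 3 - 6, 4 * 3 - 6))
})

test_that("permutation corrected p-values respect the add-one floor", {
  cfg <- tiny_config(grid = c(8L, 8L, 8L), n_volumes = 32L, n_per_group = 6L,
                     center = c(4L, 4L, 4L), radius_mm = 5, multiplier = 3,
                     white_noise_sd = 0.5)
  co <- generate_cohort(cfg)
  mf <- cohort_malff(co, fwhm_mm = 0)
  icfg <- inference_config(n_permutations = 200L, seed = 3)
  tab <- permutation_cluster_fwe(mf, group_design(co$ids, co$groups),
                                 co$mask, icfg)
  expect_gt(nrow(tab), 0L)
  expect_true(all(tab$corrected_p >= 1 / (1 + 200)))
  expect_true(all(tab$corrected_p <= 1))
  # the planted ROI is recovered as a significant positive cluster (the
  # global-mean standardization also produces a genuine negative
  # "dilution" cluster outside the ROI, so we select by tail)
  pos <- which(tab$tail == "positive")
  expect_gt(length(pos), 0L)
  expect_lte(min(tab$corrected_p[pos]), 0.05)
  best <- pos[which.min(tab$corrected_p[pos])]
  truth <- which(alffkit:::roi_sphere(cfg, c(4L, 4L, 4L), 5))
  ovl <- length(intersect(attr(tab, "voxel_members")[[best]], truth))
  expect_gt(ovl / length(truth), 0.3)
  # determinism under the same seed
  tab2 <- permutation_cluster_fwe(mf, group_design(co$ids, co$groups),
                                  co$mask, icfg)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
})

test_that("small designs switch to exhaustive enumeration", {
  cfg <- tiny_config(grid = c(6L, 6L, 6L), n_volumes = 32L, n_per_group = 3L,
                     center = c(3L, 3L, 3L), radius_mm = 4, multiplier = 4,
                     white_noise_sd = 0.3)
  co <- generate_cohort(cfg)
  mf <- cohort_malff(co, fwhm_mm = 0)
  tab <- permutation_cluster_fwe(mf, group_design(co$ids, co$groups), co$mask,
                                 inference_config(n_permutations = 100L))
  expect_true(attr(tab, "exhaustive"))
  expect_length(attr(tab, "null_max_size"), choose(6, 3))
  expect_true(all(tab$corrected_p >= 1 / choose(6, 3)))
})

test_that("image-covariate ANCOVA matches a per-voxel lm oracle", {
  dims <- c(4L, 4L, 4L)
  msk <- full_mask(dims)
  maps <- mk_maps(10L, dims, seed = 21)
  gms <- mk_maps(10L, dims, seed = 22)
  dsg <- group_design(sprintf("s%02d", 1:10),
                      rep(c("patient", "control"), each = 5), gm_maps = gms)
  tm <- ancova_image_covariate(maps, dsg, msk)
  expect_equal(tm$df, 7L)
  g <- as.numeric(dsg$group == "patient")
  for (v in c(1L, 23L, 64L)) {
    y <- sapply(maps, function(m) m$data[v])
    cv <- sapply(gms, function(m) m$data[v])
    want <- summary(lm(y ~ g + cv))$coefficients["g", "t value"]
    expect_equal(tm$data[v], want, tolerance = 1e-8)
  }
})

test_that("degenerate image covariates fall back to the two-group fit", {
  dims <- c(3L, 3L, 3L)
  msk <- full_mask(dims)
  maps <- mk_maps(8L, dims, seed = 31)
  zero_gms <- lapply(1:8, function(i) scalar_map(array(0, dims)))
  dsg <- group_design(sprintf("s%d", 1:8),
                      rep(c("patient", "control"), each = 4),
                      gm_maps = zero_gms)
  tm <- ancova_image_covariate(maps, dsg, msk)
  plain <- two_sample_tmap(maps[1:4], maps[5:8], msk)
  expect_equal(tm$data, plain$data, tolerance = 1e-10)
  expect_equal(tm$df, 6L)   # covariate dropped everywhere: df = n - 2

  # covariate equal to the response: group effect fully absorbed, t = 0
  dsg2 <- group_design(sprintf("s%d", 1:8),
                       rep(c("patient", "control"), each = 4), gm_maps = maps)
  tm2 <- ancova_image_covariate(maps, dsg2, msk)
  expect_true(all(abs(tm2$data) < 1e-6))
})

test_that("scalar-covariate ANCOVA matches lm and handles collinearity", {
  dims <- c(3L, 3L, 3L)
  msk <- full_mask(dims)
  maps <- mk_maps(10L, dims, seed = 41)
  set.seed(42)
  tiv <- rnorm(10, 1500, 100)
  dsg <- group_design(sprintf("s%02d", 1:10),
                      rep(c("patient", "control"), each = 5),
                      covariates = data.frame(tiv = tiv))
  tm <- ancova_scalar_covariate(maps, dsg, "tiv", msk)
  expect_equal(tm$df, 7L)
  g <- as.numeric(dsg$group == "patient")
  for (v in c(2L, 14L, 27L)) {
    y <- sapply(maps, function(m) m$data[v])
    want <- summary(lm(y ~ g + tiv))$coefficients["g", "t value"]
    expect_equal(tm$data[v], want, tolerance = 1e-8)
  }
  # constant covariate: dropped with a warning, plain t with df n - 2
  dsgc <- group_design(sprintf("s%02d", 1:10),
                       rep(c("patient", "control"), each = 5),
                       covariates = data.frame(tiv = rep(1500, 10)))
  expect_warning(tmc <- ancova_scalar_covariate(maps, dsgc, "tiv", msk),
                 "constant")
  plain <- two_sample_tmap(maps[1:5], maps[6:10], msk)
  expect_equal(tmc$data, plain$data, tolerance = 1e-10)
  expect_equal(tmc$df, 8L)
  # identical groups with a group-balanced covariate -> t = 0 exactly
  # (an unbalanced covariate legitimately shifts the adjusted contrast)
  same <- c(maps[1:5], maps[1:5])
  dsgb <- group_design(sprintf("s%02d", 1:10),
                       rep(c("patient", "control"), each = 5),
                       covariates = data.frame(tiv = rep(tiv[1:5], 2)))
  tms <- ancova_scalar_covariate(same, dsgb, "tiv", msk)
  expect_lt(max(abs(tms$data)), 1e-8)
})
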