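# Shared fixtures: small configurations and independent mini-oracles.

# a compact cohort configuration that fits comfortably in test runtime
tiny_config <- function(grid = c(10L, 10L, 10L), n_volumes = 64L,
                        n_per_group = 3L, multiplier = 1, sign = 1L,
                        white_noise_sd = 0, nuisance = list(),
                        center = NULL, radius_mm = 6, ...) {
  if (is.null(center)) center <- pmax(grid %/% 2L, 3L)
  synth_config(grid_dims = grid, n_volumes = n_volumes, n_discard = 0L,
               n_per_group = n_per_group,
               effect_rois = list(list(center = center, radius_mm = radius_mm,
                                       multiplier = multiplier, sign = sign)),
               white_noise_sd = white_noise_sd, nuisance = nuisance, ...)
}

full_mask <- function(dims, affine = diag(4)) {
  brain_mask(array(TRUE, dim = dims), affine = affine)
}

# independent naive ALFF: per-voxel DFT written out directly
naive_alff <- function(run, mask, f_lo = 0.01, f_hi = 0.08) {
  d <- dim(run$data)
  n <- d[4]
  out <- array(0, dim = d[1:3])
  ks <- 0:(n %/% 2)
  fs <- ks / (n * run$tr_s)
  inband <- ks[fs >= f_lo & fs <= f_hi]
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask$data[i, j, k]) next
    x <- run$data[i, j, k, ]
    amps <- vapply(inband, function(kk) {
      re <- sum(x * cos(2 * pi * kk * (0:(n - 1)) / n))
      im <- -sum(x * sin(2 * pi * kk * (0:(n - 1)) / n))
      sc <- if (kk == 0 || (n %% 2 == 0 && kk == n %/% 2)) 1 / n else 2 / n
      sc * sqrt(re^2 + im^2)
    }, 0)
    out[i, j, k] <- mean(amps)
  }
  out
}

# O(m^2) flood-fill component labelling, independent of the package path
naive_components <- function(idx, dims, connectivity) {
  m <- length(idx)
  if (m == 0L) return(integer(0))
  co <- arrayInd(idx, dims)
  adj <- matrix(FALSE, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    d <- abs(co[a, ] - co[b, ])
    if (a == b || max(d) > 1) next
    s <- sum(d)
    adj[a, b] <- switch(as.character(connectivity),
                        `6` = s == 1, `18` = s <= 2, `26` = s >= 1)
  }
  lab <- rep(0L, m)
  cur <- 0L
  for (a in seq_len(m)) {
    if (lab[a] > 0L) next
    cur <- cur + 1L
    queue <- a
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (lab[v] > 0L) next
      lab[v] <- cur
      queue <- c(queue, which(adj[v, ] & lab == 0L))
    }
  }
  lab
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# mALFF maps for every subject of a cohort (thin wrapper used all over)
cohort_malff <- function(cohort, fwhm_mm = 8, subset = NULL) {
  subs <- if (is.null(subset)) cohort$subjects else cohort$subjects[subset]
  malff_maps(lapply(subs, `[[`, "run"), cohort$mask,
             discard = 0L, fwhm_mm = fwhm_mm)
}
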