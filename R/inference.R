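# Voxel-wise between-group inference on standardized ALFF maps: pooled
# two-sample t-maps, cluster extraction, permutation cluster-level FWE,
# and covariate-adjusted (ANCOVA-style) models with either a scalar
# covariate (e.g. total intracranial volume) or a voxel-wise image
# covariate (grey-matter probability).

#' Inference configuration
#'
#' @param cluster_forming_t Voxel-level t threshold defining suprathreshold
#'   clusters (default 3.32, the one-tailed p < 0.001 cutoff at 38 df).
#' @param cluster_alpha Cluster-level corrected significance level.
#' @param n_permutations Number of label permutations for the FWE null
#'   (>= 100); when the total number of distinct group-label arrangements
#'   is smaller, all arrangements are enumerated instead.
#' @param connectivity Voxel neighbourhood: 6 (faces), 18 (faces + edges,
#'   the default, SPM's convention) or 26 (faces + edges + corners).
#' @param tail `"both"`, `"positive"` or `"negative"` — which t-map signs
#'   form clusters.
#' @param seed Integer seed controlling the permutation draw.
#' @return A list of class `inference_config`.
#' @export
inference_config <- function(cluster_forming_t = 3.32, cluster_alpha = 0.05,
                             n_permutations = 5000L,
                             connectivity = c(18L, 6L, 26L),
                             tail = c("both", "positive", "negative"),
                             seed = 1L) {
  connectivity <- as.integer(connectivity)[1]
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  tail <- match.arg(tail)
  if (cluster_forming_t <= 0) stop("cluster_forming_t must be > 0", call. = FALSE)
  if (cluster_alpha <= 0 || cluster_alpha >= 1)
    stop("cluster_alpha must lie in (0, 1)", call. = FALSE)
  if (n_permutations < 100L) stop("need n_permutations >= 100", call. = FALSE)
  structure(list(cluster_forming_t = cluster_forming_t,
                 cluster_alpha = cluster_alpha,
                 n_permutations = as.integer(n_permutations),
                 connectivity = connectivity, tail = tail,
                 seed = as.integer(seed)),
            class = "inference_config")
}

# pooled-variance two-sample t for each row of Xa (p x nA) vs Xb (p x nB);
# zero-variance rows give t = 0
row_t_pooled <- function(Xa, Xb) {
  nA <- ncol(Xa); nB <- ncol(Xb)
  mA <- rowMeans(Xa); mB <- rowMeans(Xb)
  vA <- rowSums((Xa - mA)^2) / (nA - 1)
  vB <- rowSums((Xb - mB)^2) / (nB - 1)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- ifelse(se > 0, (mA - mB) / se, 0)
  t
}

maps_to_matrix <- function(maps, idx) {
  vapply(maps, function(m) {
    d <- if (inherits(m, "scalar_map")) m$data else m
    d[idx]
  }, numeric(length(idx)))
}

#' Voxel-wise two-sample t-map
#'
#' Pooled-variance two-sample t statistic (group A minus group B) at every
#' in-mask voxel; `df = nA + nB - 2` is stored on the returned map.
#' Zero-variance voxels yield t = 0; their count is attached as attribute
#' `n_zero_variance` and reported via [message()] when positive.
#'
#' @param maps_a,maps_b Lists of [scalar_map()]s (or 3D arrays), one per
#'   subject, sharing one grid.
#' @param mask A [brain_mask()] on that grid.
#' @return A [scalar_map()] of kind `"tstat"`.
#' @export
two_sample_tmap <- function(maps_a, maps_b, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  if (length(maps_a) < 2L || length(maps_b) < 2L)
    stop("need at least 2 maps per group", call. = FALSE)
  dims <- dim(mask$data)
  for (m in c(maps_a, maps_b)) {
    d <- if (inherits(m, "scalar_map")) dim(m$data) else dim(m)
    if (!all(d == dims)) stop("map grid does not match mask grid", call. = FALSE)
  }
  idx <- which(mask$data)
  Xa <- maps_to_matrix(maps_a, idx)
  Xb <- maps_to_matrix(maps_b, idx)
  t <- row_t_pooled(Xa, Xb)
  # zero pooled variance: each group internally constant
  nzv <- sum(rowSums((Xa - rowMeans(Xa))^2) == 0 &
             rowSums((Xb - rowMeans(Xb))^2) == 0)
  out <- array(0, dim = dims)
  out[idx] <- t
  aff <- if (inherits(maps_a[[1]], "scalar_map")) maps_a[[1]]$affine else mask$affine
  res <- scalar_map(out, affine = aff, kind = "tstat",
                    df = length(maps_a) + length(maps_b) - 2L)
  attr(res, "n_zero_variance") <- nzv
  if (nzv > 0L) message(nzv, " zero-variance voxel(s) set to t = 0")
  res
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance two-sample t-test given group means, standard deviations
#' and sizes, with `df = n1 + n2 - 2` and a two-tailed Student-t p-value.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @return A list with `t`, `df` and `p` (two-tailed).
#' @export
t_test_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else t <- (m1 - m2) / se
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction, 1 degree of freedom:
#' `X^2 = N (ad - bc)^2 / (r1 r2 c1 c2)`.
#'
#' @param a,b,c,d Cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return A list with `statistic`, `df = 1` and two-tailed `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0))
    stop("a margin of the 2x2 table is zero", call. = FALSE)
  n <- sum(counts)
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, df = 1L, p = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Critical Student-t value
#'
#' Upper quantile of the Student-t distribution: the cluster-forming
#' threshold `t > 3.32` corresponds to `critical_t(0.001, 38, "one")`.
#'
#' @param alpha Tail probability in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @param tails `"one"` or `"two"`.
#' @return The critical t value.
#' @export
critical_t <- function(alpha, df, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  stats::qt(1 - if (tails == "one") alpha else alpha / 2, df)
}

conn_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  s <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 `6` = s == 1, `18` = s <= 2, `26` = rep(TRUE, nrow(g)))
  as.matrix(g[keep, , drop = FALSE])
}

# label connected components among `idx` (linear indices into an array of
# dims `dims`); returns an integer label per index (1..n_components)
label_components <- function(idx, dims, connectivity = 18L) {
  m <- length(idx)
  if (m == 0L) return(integer(0))
  coords <- arrayInd(idx, dims)
  offs <- conn_offsets(connectivity)
  # half set: avoid recording each undirected edge twice
  half <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
               (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), , drop = FALSE]
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(idx)
  sorted_idx <- idx[ord]
  for (r in seq_len(nrow(half))) {
    nb <- sweep(coords, 2L, half[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] + (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    pos <- match(lin, sorted_idx)
    hit <- !is.na(pos)
    if (!any(hit)) next
    from <- which(ok)[hit]
    to <- ord[pos[hit]]
    for (e in seq_along(from)) {
      ra <- find(from[e]); rb <- find(to[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(m), find, 0L)
  match(roots, unique(roots))
}

empty_cluster_table <- function() {
  structure(
    data.frame(cluster_id = integer(0), tail = character(0),
               n_voxels = integer(0), peak_t = numeric(0),
               peak_i = integer(0), peak_j = integer(0), peak_k = integer(0),
               peak_x_mm = numeric(0), peak_y_mm = numeric(0),
               peak_z_mm = numeric(0), corrected_p = numeric(0)),
    class = c("cluster_table", "data.frame"))
}

#' Extract suprathreshold clusters from a t-map
#'
#' Connected components of `{t > threshold}` (positive tail) and/or
#' `{t < -threshold}` (negative tail) under the chosen voxel connectivity.
#' The cluster peak is the voxel maximizing `|t|`; its world coordinate
#' comes from the map affine (0-based voxel indices).
#'
#' @param tmap A `"tstat"` [scalar_map()].
#' @param threshold Positive cluster-forming t value.
#' @param connectivity 6, 18 (default) or 26.
#' @param tail `"both"` (default), `"positive"` or `"negative"`.
#' @return A `cluster_table` data.frame (possibly empty): id, tail, voxel
#'   count, peak t, 0-based peak voxel index, peak world coordinate (mm),
#'   `corrected_p` (`NA` here; filled by [permutation_cluster_fwe()]).
#' @export
extract_clusters <- function(tmap, threshold, connectivity = 18L,
                             tail = c("both", "positive", "negative")) {
  stopifnot(inherits(tmap, "scalar_map"))
  if (is.null(tmap$df)) stop("t-map must carry df", call. = FALSE)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  tail <- match.arg(tail)
  dims <- dim(tmap$data)
  rows <- list()
  sides <- switch(tail, both = c("positive", "negative"),
                  positive = "positive", negative = "negative")
  next_id <- 1L
  for (side in sides) {
    idx <- if (side == "positive") which(tmap$data > threshold)
           else which(tmap$data < -threshold)
    if (length(idx) == 0L) next
    lab <- label_components(idx, dims, connectivity)
    for (cl in seq_len(max(lab))) {
      vox <- idx[lab == cl]
      tv <- tmap$data[vox]
      pk <- vox[which.max(abs(tv))]
      ijk <- arrayInd(pk, dims)
      world <- tmap$affine %*% c(ijk - 1L, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = next_id, tail = side, n_voxels = length(vox),
        peak_t = tv[which.max(abs(tv))],
        peak_i = ijk[1] - 1L, peak_j = ijk[2] - 1L, peak_k = ijk[3] - 1L,
        peak_x_mm = world[1], peak_y_mm = world[2], peak_z_mm = world[3],
        corrected_p = NA_real_)
      next_id <- next_id + 1L
    }
  }
  if (length(rows) == 0L) return(empty_cluster_table())
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_voxels), , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("cluster_table", "data.frame")
  attr(out, "voxel_members") <- NULL
  out
}

# voxel membership of each cluster (list of linear-index vectors), in the
# same order as the rows of extract_clusters() output
cluster_members <- function(tmap, threshold, connectivity, tail) {
  dims <- dim(tmap$data)
  sides <- switch(tail, both = c("positive", "negative"),
                  positive = "positive", negative = "negative")
  mem <- list()
  for (side in sides) {
    idx <- if (side == "positive") which(tmap$data > threshold)
           else which(tmap$data < -threshold)
    if (length(idx) == 0L) next
    lab <- label_components(idx, dims, connectivity)
    for (cl in seq_len(max(lab))) mem[[length(mem) + 1L]] <- idx[lab == cl]
  }
  mem[order(-lengths(mem))]
}

# largest suprathreshold component size for each column of a t matrix
# restricted to in-mask voxels `idx` of a grid `dims`
max_cluster_sizes <- function(Tmat, idx, dims, threshold, connectivity, tail) {
  apply(Tmat, 2L, function(tv) {
    best <- 0L
    if (tail %in% c("both", "positive")) {
      sup <- idx[tv > threshold]
      if (length(sup))
        best <- max(best, max(tabulate(label_components(sup, dims, connectivity))))
    }
    if (tail %in% c("both", "negative")) {
      sup <- idx[tv < -threshold]
      if (length(sup))
        best <- max(best, max(tabulate(label_components(sup, dims, connectivity))))
    }
    best
  })
}

# t statistics for every label arrangement in indicator matrix G (n x B)
perm_t_matrix <- function(X, X2, G, nA, nB) {
  SA <- X %*% G
  QA <- X2 %*% G
  Stot <- rowSums(X)
  Qtot <- rowSums(X2)
  SB <- Stot - SA
  QB <- Qtot - QA
  mA <- SA / nA; mB <- SB / nB
  vA <- (QA - nA * mA^2) / (nA - 1)
  vB <- (QB - nB * mB^2) / (nB - 1)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  sp2[sp2 < 0] <- 0
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  Tm <- (mA - mB) / se
  Tm[se == 0] <- 0
  Tm
}

#' Cluster-level FWE inference by group-label permutation
#'
#' Computes the observed two-sample t-map and its suprathreshold clusters,
#' then scores each observed cluster size against the permutation null
#' distribution of the maximum cluster size (group labels permuted, same
#' cluster-forming threshold and connectivity). The corrected p-value uses
#' the add-one estimator `(1 + #\{perm max size >= observed size\}) /
#' (1 + n_permutations)`, so p > 0 always. When the total number of
#' distinct label arrangements is at most `n_permutations`, all
#' arrangements are enumerated and the exact proportion (which includes the
#' observed arrangement) is reported instead.
#'
#' @param maps List of mALFF [scalar_map()]s, one per subject, in design
#'   order.
#' @param design A [group_design()].
#' @param mask A [brain_mask()] on the analysis grid.
#' @param config An [inference_config()].
#' @return A `cluster_table` with `corrected_p` filled, plus attributes:
#'   `tmap` (the observed t-map), `null_max_size` (the permutation null),
#'   `significant` (logical per cluster at `cluster_alpha`), and
#'   `voxel_members` (list of linear-index vectors per cluster).
#' @export
permutation_cluster_fwe <- function(maps, design, mask,
                                    config = inference_config()) {
  stopifnot(inherits(design, "group_design"), inherits(mask, "brain_mask"),
            inherits(config, "inference_config"))
  n <- length(design$ids)
  if (length(maps) != n)
    stop("need one map per design subject", call. = FALSE)
  gA <- design$group == levels(design$group)[1]
  nA <- sum(gA); nB <- n - nA
  if (nA < 2L || nB < 2L) stop("need at least 2 subjects per group", call. = FALSE)

  dims <- dim(mask$data)
  idx <- which(mask$data)
  X <- t(maps_to_matrix(maps, idx))            # n x p
  tmap <- two_sample_tmap(maps[gA], maps[!gA], mask)

  tab <- extract_clusters(tmap, config$cluster_forming_t,
                          config$connectivity, config$tail)
  members <- cluster_members(tmap, config$cluster_forming_t,
                             config$connectivity, config$tail)

  total_arrangements <- choose(n, nA)
  exhaustive <- is.finite(total_arrangements) &&
    total_arrangements <= config$n_permutations
  if (exhaustive) {
    combos <- utils::combn(n, nA)
    B <- ncol(combos)
    G <- matrix(0, n, B)
    for (b in seq_len(B)) G[combos[, b], b] <- 1
  } else {
    set.seed(config$seed)
    B <- config$n_permutations
    G <- matrix(0, n, B)
    for (b in seq_len(B)) G[sample.int(n, nA), b] <- 1
  }

  Xp <- t(X)      # p x n
  X2p <- Xp^2
  null_max <- integer(B)
  chunk <- 256L
  for (start in seq(1L, B, by = chunk)) {
    cols <- start:min(start + chunk - 1L, B)
    Tm <- perm_t_matrix(Xp, X2p, G[, cols, drop = FALSE], nA, nB)
    null_max[cols] <- max_cluster_sizes(Tm, idx, dims,
                                        config$cluster_forming_t,
                                        config$connectivity, config$tail)
  }

  if (nrow(tab) > 0L) {
    tab$corrected_p <- vapply(tab$n_voxels, function(sz) {
      if (exhaustive) mean(null_max >= sz)
      else (1 + sum(null_max >= sz)) / (1 + B)
    }, 0)
  }
  attr(tab, "tmap") <- tmap
  attr(tab, "null_max_size") <- null_max
  attr(tab, "significant") <- tab$corrected_p <= config$cluster_alpha
  attr(tab, "voxel_members") <- members
  attr(tab, "exhaustive") <- exhaustive
  tab
}

# vectorized per-voxel 3-column regression y ~ 1 + g + c with c varying by
# voxel; returns the t statistic for the g coefficient and per-voxel
# degeneracy flags
ancova_rows <- function(Y, Cmat, g) {
  n <- ncol(Y)
  Sg <- sum(g); Sgg <- sum(g^2)
  Sc <- rowSums(Cmat)
  Scc <- rowSums(Cmat^2)
  Sgc <- drop(Cmat %*% g)
  Sy <- rowSums(Y)
  Sgy <- drop(Y %*% g)
  Scy <- rowSums(Cmat * Y)
  yty <- rowSums(Y^2)

  a11 <- n;   a12 <- Sg;  a13 <- Sc
  a22 <- Sgg; a23 <- Sgc; a33 <- Scc
  det3 <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  scale3 <- pmax(abs(a11 * a22 * a33), 1)
  degenerate <- abs(det3) <= 1e-10 * scale3

  det3s <- ifelse(degenerate, 1, det3)   # placeholder, masked later
  i11 <- (a22 * a33 - a23^2) / det3s
  i12 <- (a13 * a23 - a12 * a33) / det3s
  i13 <- (a12 * a23 - a13 * a22) / det3s
  i22 <- (a11 * a33 - a13^2) / det3s
  i23 <- (a12 * a13 - a11 * a23) / det3s
  i33 <- (a11 * a22 - a12^2) / det3s
  b0 <- i11 * Sy + i12 * Sgy + i13 * Scy
  b1 <- i12 * Sy + i22 * Sgy + i23 * Scy
  b2 <- i13 * Sy + i23 * Sgy + i33 * Scy
  rss <- pmax(yty - (b0 * Sy + b1 * Sgy + b2 * Scy), 0)
  sigma2 <- rss / (n - 3)
  se <- sqrt(sigma2 * i22)
  t <- ifelse(se > 0, b1 / se, 0)
  t[degenerate] <- NA_real_
  list(t = t, degenerate = degenerate)
}

#' Group t-map adjusted for a voxel-wise image covariate
#'
#' At each in-mask voxel, fits the least-squares model
#' `malff ~ intercept + group + covariate(voxel)` where the covariate is
#' that voxel's value in the subject's image covariate (grey-matter
#' probability), and returns the t statistic of the group coefficient with
#' `df = n - 3`. Voxels where the covariate is constant across subjects
#' fall back to the plain two-group fit (covariate dropped, residual
#' df `n - 2`); remaining rank-deficient voxels get t = 0 and are counted
#' in attribute `n_degenerate`.
#'
#' @param maps List of mALFF [scalar_map()]s in design order.
#' @param design A [group_design()] carrying `gm_maps`.
#' @param mask A [brain_mask()].
#' @return A `"tstat"` [scalar_map()], df = n - 3.
#' @export
ancova_image_covariate <- function(maps, design, mask) {
  stopifnot(inherits(design, "group_design"), inherits(mask, "brain_mask"))
  if (is.null(design$gm_maps))
    stop("design has no image covariates (gm_maps)", call. = FALSE)
  n <- length(design$ids)
  if (length(maps) != n) stop("need one map per subject", call. = FALSE)
  dims <- dim(mask$data)
  idx <- which(mask$data)
  Y <- maps_to_matrix(maps, idx)                # p x n
  Cmat <- maps_to_matrix(design$gm_maps, idx)   # p x n
  g <- as.numeric(design$group == levels(design$group)[1])

  res <- ancova_rows(Y, Cmat, g)
  t <- res$t

  # constant-covariate voxels: drop the covariate, fit y ~ 1 + g
  const_cov <- apply(Cmat, 1L, function(r) max(r) - min(r) == 0)
  if (any(const_cov)) {
    sub <- which(const_cov)
    ta <- row_t_pooled(Y[sub, g == 1, drop = FALSE], Y[sub, g == 0, drop = FALSE])
    t[sub] <- ta
  }
  ndeg <- sum(is.na(t))
  t[is.na(t)] <- 0
  out <- array(0, dim = dims)
  out[idx] <- t
  df <- if (all(const_cov)) n - 2L else n - 3L
  resmap <- scalar_map(out, affine = mask$affine, kind = "tstat", df = df)
  attr(resmap, "n_degenerate") <- ndeg
  attr(resmap, "n_constant_covariate") <- sum(const_cov)
  if (ndeg > 0L) message(ndeg, " rank-deficient voxel(s) set to t = 0")
  resmap
}

#' Group t-map adjusted for a scalar covariate
#'
#' At each in-mask voxel, fits `value ~ intercept + group + covariate`
#' where the covariate is one scalar per subject (e.g. total intracranial
#' volume, for grey-matter volume comparisons) and returns the group
#' coefficient t, `df = n - 3`. A covariate constant across subjects is
#' collinear with the intercept: it is dropped with a warning and the
#' plain two-sample t (df `n - 2`) returned.
#'
#' @param maps List of [scalar_map()]s in design order.
#' @param design A [group_design()] whose `covariates` contains
#'   `covariate_name`.
#' @param covariate_name Column name in `design$covariates`.
#' @param mask A [brain_mask()].
#' @return A `"tstat"` [scalar_map()].
#' @export
ancova_scalar_covariate <- function(maps, design, covariate_name, mask) {
  stopifnot(inherits(design, "group_design"), inherits(mask, "brain_mask"))
  if (is.null(design$covariates) || !covariate_name %in% names(design$covariates))
    stop("scalar covariate `", covariate_name, "` not present in design",
         call. = FALSE)
  z <- design$covariates[[covariate_name]]
  if (anyNA(z)) stop("covariate has missing values", call. = FALSE)
  n <- length(design$ids)
  g <- as.numeric(design$group == levels(design$group)[1])
  idx <- which(mask$data)
  Y <- maps_to_matrix(maps, idx)
  if (max(z) - min(z) == 0) {
    warning("covariate `", covariate_name,
            "` is constant; dropped (plain two-sample t, df = n - 2)")
    t <- row_t_pooled(Y[, g == 1, drop = FALSE], Y[, g == 0, drop = FALSE])
    df <- n - 2L
  } else {
    Cmat <- matrix(z, nrow = length(idx), ncol = n, byrow = TRUE)
    res <- ancova_rows(Y, Cmat, g)
    t <- res$t
    t[is.na(t)] <- 0
    df <- n - 3L
  }
  out <- array(0, dim = dim(mask$data))
  out[idx] <- t
  scalar_map(out, affine = mask$affine, kind = "tstat", df = df)
}
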