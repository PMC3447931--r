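# VOI extraction and clinical correlation: progression rate, mean mALFF
# within volumes of interest, and Pearson correlations with clinical
# variables (disease duration, progression rate, ALSFRS).

#' ALS progression rate
#'
#' `rate = (40 - ALSFRS) / disease duration (months)`, per month. ALSFRS
#' ranges 0-40 (40 = no impairment), so the rate is nonnegative.
#'
#' @param alsfrs ALSFRS score(s), in `[0, 40]`.
#' @param duration_months Disease duration(s) in months (> 0).
#' @return Progression rate per month (vectorized).
#' @export
progression_rate <- function(alsfrs, duration_months) {
  if (any(duration_months <= 0))
    stop("disease duration must be > 0 months", call. = FALSE)
  if (any(alsfrs < 0 | alsfrs > 40))
    stop("ALSFRS scores lie in [0, 40]", call. = FALSE)
  (40 - alsfrs) / duration_months
}

#' Mean map value within a volume of interest
#'
#' @param map A [scalar_map()].
#' @param voi A non-empty [brain_mask()] on the same grid.
#' @return Arithmetic mean of the in-VOI voxels.
#' @export
voi_mean <- function(map, voi) {
  stopifnot(inherits(map, "scalar_map"), inherits(voi, "brain_mask"))
  if (!all(dim(map$data) == dim(voi$data)))
    stop("VOI grid does not match map grid", call. = FALSE)
  idx <- which(voi$data)
  if (length(idx) == 0L) stop("VOI is empty", call. = FALSE)
  mean(map$data[idx])
}

#' Pearson correlation with two-tailed Student-t p-value
#'
#' Sample Pearson r with `p` from `t = r * sqrt(n - 2) / sqrt(1 - r^2)`,
#' two-tailed with `df = n - 2`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each with nonzero
#'   variance.
#' @return A list with `r`, `n` and `p`.
#' @export
pearson_corr <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` lengths differ", call. = FALSE)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in `x` or `y`", call. = FALSE)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(r = r, n = n, p = p)
}

#' Correlate VOI mean mALFF with clinical variables
#'
#' For each (VOI, clinical variable) pair, extracts the per-patient mean
#' mALFF within the VOI and computes the Pearson correlation with the
#' variable. Significance is flagged at two-tailed p < 0.05 uncorrected
#' (the study convention); an optional Bonferroni correction across all
#' pairs is available but off by default.
#'
#' @param malff_maps Named list of patient mALFF [scalar_map()]s.
#' @param vois Named list of [brain_mask()] volumes of interest.
#' @param clinical Data.frame with one row per patient (same order as
#'   `malff_maps`) containing the requested variables.
#' @param variables Character vector of clinical column names (default
#'   `c("duration_months", "progression_rate", "alsfrs")`).
#' @param alpha Significance level (default 0.05, two-tailed).
#' @param bonferroni Apply Bonferroni correction across pairs? Default
#'   `FALSE`.
#' @return Data.frame: `voi`, `variable`, `voi_mean_sd`, `r`, `n`, `p`,
#'   `significant`.
#' @export
correlate_vois <- function(malff_maps, vois, clinical,
                           variables = c("duration_months",
                                         "progression_rate", "alsfrs"),
                           alpha = 0.05, bonferroni = FALSE) {
  n <- length(malff_maps)
  if (n < 3L) stop("need at least 3 patients", call. = FALSE)
  if (nrow(clinical) != n)
    stop("clinical rows must match the number of maps", call. = FALSE)
  missing_vars <- setdiff(variables, names(clinical))
  if (length(missing_vars))
    stop("clinical table lacks: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  if (is.null(names(vois))) names(vois) <- paste0("voi", seq_along(vois))
  rows <- list()
  n_tests <- length(vois) * length(variables)
  thr <- if (bonferroni) alpha / n_tests else alpha
  for (v in names(vois)) {
    means <- vapply(malff_maps, voi_mean, 0, voi = vois[[v]])
    for (var in variables) {
      res <- pearson_corr(means, clinical[[var]])
      rows[[length(rows) + 1L]] <- data.frame(
        voi = v, variable = var,
        voi_mean_sd = stats::sd(means),
        r = res$r, n = res$n, p = res$p,
        significant = res$p < thr)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
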