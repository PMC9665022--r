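# Reliability statistics. Conventions pinned deliberately: the CCC uses
# population (1/n) moments, the ANOVA mean squares use standard degrees of
# freedom. Undefined statistics (zero variance) are reported as missing and
# excluded from averages, with counts carried on the tables.

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed model, consistency, single rating: targets (rows) are the ROI
#' instances, raters (columns) are the reconstruction channels, which form a
#' fixed set. `icc = (MS_rows - MS_error) / (MS_rows + (k - 1) MS_error)`,
#' where `MS_rows` is the between-target mean square and `MS_error` the
#' residual after removing target and rater effects. Invariant under a common
#' affine transform and under per-rater additive offsets.
#'
#' @param m Numeric matrix, `n targets x k raters`, complete.
#' @return Object of class `icc_result`: `icc`, `ms_rows`, `ms_error`,
#'   `n_targets`, `k_raters`.
#' @export
icc_3_1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("ICC needs at least 2 targets and 2 raters")
  if (anyNA(m)) stop("ICC ratings matrix must be complete")
  grand <- mean(m)
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  ss_rows <- k * sum((rm_ - grand)^2)
  ss_cols <- n * sum((cm_ - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- max(0, ss_err) / ((n - 1) * (k - 1))
  denom <- ms_rows + (k - 1) * ms_err
  if (denom <= 0) {
    stop(structure(
      class = c("pcctstab_undefined_icc", "error", "condition"),
      list(message = "undefined ICC: no target or residual variance", call = NULL)
    ))
  }
  structure(
    list(icc = (ms_rows - ms_err) / denom, ms_rows = ms_rows, ms_error = ms_err,
         n_targets = n, k_raters = k),
    class = "icc_result"
  )
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two measurement vectors, penalizing both decorrelation and
#' location/scale shift: `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean x - mean y)^2)`
#' with population (1/n) moments, Lin's original convention.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Object of class `ccc_result`: `ccc`, `pearson_r`, `mean_x`,
#'   `mean_y`, `var_x`, `var_y` (population variances).
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("CCC needs at least 3 paired observations")
  mx <- mean(x)
  my <- mean(y)
  vx <- mean((x - mx)^2)
  vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) {
    stop(structure(
      class = c("pcctstab_undefined_ccc", "error", "condition"),
      list(message = "undefined CCC: both vectors constant with equal means", call = NULL)
    ))
  }
  r <- if (vx > 0 && vy > 0) cxy / sqrt(vx * vy) else NA_real_
  structure(
    list(ccc = 2 * cxy / denom, pearson_r = r,
         mean_x = mx, mean_y = my, var_x = vx, var_y = vy),
    class = "ccc_result"
  )
}

#' Repeated-measures one-way ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject F test over k conditions with the sphericity correction
#' `epsilon = (tr C)^2 / ((k - 1) tr(C^2))`, C the double-centered condition
#' covariance; both uncorrected and corrected p-values (degrees of freedom
#' multiplied by epsilon) are returned.
#'
#' @param values Numeric matrix, `n subjects x k conditions`, complete.
#' @return Object of class `gg_anova_result`: `f_statistic`, `df_condition`,
#'   `df_error`, `epsilon_gg`, `p_uncorrected`, `p_gg_corrected`.
#' @export
repeated_measures_anova_gg <- function(values) {
  y <- as.matrix(values)
  n <- nrow(y)
  k <- ncol(y)
  if (n < 2 || k < 2) stop("repeated-measures ANOVA needs >= 2 subjects and >= 2 conditions")
  if (anyNA(y)) stop("condition matrix must be complete")
  grand <- mean(y)
  cm_ <- colMeans(y)
  rm_ <- rowMeans(y)
  ss_cond <- n * sum((cm_ - grand)^2)
  resid <- y - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  f <- if (ss_cond == 0) 0 else (ss_cond / df1) / (ss_err / df2)
  s <- stats::cov(y)
  cc <- s - matrix(rowMeans(s), k, k) - matrix(colMeans(s), k, k, byrow = TRUE) + mean(s)
  # a zero centered covariance (no within-subject variability at all) is
  # treated as perfectly spherical
  eps <- if (sum(cc^2) == 0) 1 else sum(diag(cc))^2 / ((k - 1) * sum(cc^2))
  eps <- min(1, max(1 / (k - 1), eps))
  structure(
    list(
      f_statistic = f, df_condition = df1, df_error = df2,
      epsilon_gg = eps,
      p_uncorrected = pf(f, df1, df2, lower.tail = FALSE),
      p_gg_corrected = pf(f, eps * df1, eps * df2, lower.tail = FALSE)
    ),
    class = "gg_anova_result"
  )
}

# Parse a mode label like "3D-2cm" into its dim and diameter.
.parse_mode <- function(mode) {
  mode <- match.arg(mode, SEG_MODES)
  list(dim = substr(mode, 1, 2), diameter_cm = as.numeric(substr(mode, 4, 4)))
}

# Wide per-target layout of one segmentation mode: one row per
# (feature, organ, patient, repeat), one column per channel. Errors on gaps.
.mode_wide <- function(ft, mode, channels) {
  p <- .parse_mode(mode)
  sub <- ft[ft$dim == p$dim & ft$diameter_cm == p$diameter_cm &
              ft$channel %in% channels, ]
  if (nrow(sub) == 0L) stop(sprintf("no feature rows for mode %s", mode))
  w <- data.table::dcast(data.table::as.data.table(sub),
                         feature + organ + patient + repeat_id ~ channel,
                         value.var = "value")
  miss <- setdiff(channels, names(w))
  if (length(miss) || anyNA(w[, channels, with = FALSE])) {
    gap <- if (length(miss)) paste(miss, collapse = ", ") else "incomplete target rows"
    stop(sprintf("missing cells in mode %s: %s", mode, gap))
  }
  w
}

#' Per-(feature, organ) ICC(3,1) table
#'
#' For one channel subset and one segmentation mode: targets are the
#' patient-by-repeat ROI instances (20 in the default cohort), raters the
#' subset's channels. Undefined ICCs (zero variance) are reported as `NA` and
#' counted in the `n_undefined` attribute.
#'
#' @param ft Long feature table.
#' @param subset `"ALL"`, `"WITHOUT_IODINE"`, `"VM_ONLY"`, or a character
#'   vector of channel ids.
#' @param mode Segmentation mode label, e.g. `"3D-2cm"`.
#' @return `data.table` with columns `feature`, `organ`, `icc`, `ms_rows`,
#'   `ms_error`, `n_targets`, `k_raters`.
#' @export
icc_stability_table <- function(ft, subset = "ALL", mode = "3D-2cm") {
  channels <- if (length(subset) == 1L && subset %in% c("ALL", "WITHOUT_IODINE", "VM_ONLY")) {
    channel_subset(subset)
  } else {
    subset
  }
  w <- .mode_wide(ft, mode, channels)
  vals <- as.matrix(w[, channels, with = FALSE])
  res <- w[, {
    m <- vals[.I, , drop = FALSE]
    r <- tryCatch(icc_3_1(m), pcctstab_undefined_icc = function(e) NULL)
    if (is.null(r)) {
      list(icc = NA_real_, ms_rows = NA_real_, ms_error = NA_real_,
           n_targets = nrow(m), k_raters = ncol(m))
    } else {
      list(icc = r$icc, ms_rows = r$ms_rows, ms_error = r$ms_error,
           n_targets = r$n_targets, k_raters = r$k_raters)
    }
  }, by = c("feature", "organ")]
  data.table::setattr(res, "n_undefined", sum(is.na(res$icc)))
  res[]
}

#' Segmentation-resegmentation CCC table
#'
#' For each (feature, organ, VM channel): x = repeat-1 values across patients,
#' y = repeat-2 values. Undefined CCCs are `NA` with a count attribute.
#'
#' @param ft Long feature table.
#' @param mode Segmentation mode label.
#' @param channels Channels to evaluate; default the 9 VM channels.
#' @return `data.table` with columns `feature`, `organ`, `channel`, `ccc`,
#'   `pearson_r`.
#' @export
ccc_resegmentation_table <- function(ft, mode = "3D-2cm",
                                     channels = channel_subset("VM_ONLY")) {
  p <- .parse_mode(mode)
  sub <- data.table::as.data.table(
    ft[ft$dim == p$dim & ft$diameter_cm == p$diameter_cm & ft$channel %in% channels, ]
  )
  if (nrow(sub) == 0L) stop(sprintf("no feature rows for mode %s", mode))
  w <- data.table::dcast(sub, feature + organ + channel + patient ~ repeat_id,
                         value.var = "value")
  if (!all(c("1", "2") %in% names(w)) || anyNA(w[["1"]]) || anyNA(w[["2"]])) {
    stop("unpaired data: both repeats are required for every patient")
  }
  res <- w[, {
    r <- tryCatch(ccc(`1`, `2`), pcctstab_undefined_ccc = function(e) NULL)
    if (is.null(r)) {
      list(ccc = NA_real_, pearson_r = NA_real_)
    } else {
      list(ccc = r$ccc, pearson_r = r$pearson_r)
    }
  }, by = c("feature", "organ", "channel")]
  data.table::setattr(res, "n_undefined", sum(is.na(res$ccc)))
  res[]
}

#' Channel-to-channel feature-wise correlation and clustering
#'
#' For every feature, the Pearson correlation between channel columns is
#' computed across all ROIs of the chosen mode; the channel-by-channel matrix
#' is the mean of those per-feature correlations (features are never stacked
#' across scales, so heavy-tailed features cannot dominate). Features with
#' zero variance in any channel are skipped. Channels are clustered with
#' average linkage on the distance `1 - r`.
#'
#' @param ft Long feature table.
#' @param mode Segmentation mode label.
#' @param channels Channels to include (default all 12).
#' @return List: `correlation` (matrix), `n_features_used`, `hclust`,
#'   `newick` (dendrogram as a Newick string).
#' @export
reconstruction_correlation <- function(ft, mode = "3D-2cm", channels = CHANNEL_IDS) {
  p <- .parse_mode(mode)
  sub <- data.table::as.data.table(
    ft[ft$dim == p$dim & ft$diameter_cm == p$diameter_cm & ft$channel %in% channels, ]
  )
  w <- data.table::dcast(sub, feature + organ + patient + repeat_id ~ channel,
                         value.var = "value")
  chans <- intersect(channels, names(w))
  acc <- matrix(0, length(chans), length(chans), dimnames = list(chans, chans))
  used <- 0L
  for (f in unique(w$feature)) {
    m <- as.matrix(w[w$feature == f, chans, with = FALSE])
    if (any(apply(m, 2, stats::sd) == 0)) next
    acc <- acc + cor(m)
    used <- used + 1L
  }
  if (used == 0L) stop("no feature with nonzero variance in every channel")
  cr <- acc / used
  diag(cr) <- 1
  hc <- hclust(as.dist(1 - cr), method = "average")
  list(correlation = cr, n_features_used = used, hclust = hc,
       newick = .hclust_newick(hc))
}

#' Organ-to-organ feature-profile correlation and clustering
#'
#' Each organ's profile is the vector of its mean feature values per
#' (feature, channel), standardized across organs within each
#' (feature, channel) row so every feature contributes on a common scale;
#' organs are Pearson-correlated and clustered with average linkage on `1 - r`.
#'
#' @inheritParams reconstruction_correlation
#' @return List: `correlation`, `hclust`, `newick`.
#' @export
organ_correlation <- function(ft, mode = "3D-2cm", channels = CHANNEL_IDS) {
  p <- .parse_mode(mode)
  sub <- data.table::as.data.table(
    ft[ft$dim == p$dim & ft$diameter_cm == p$diameter_cm & ft$channel %in% channels, ]
  )
  prof <- sub[, list(v = mean(value)), by = c("feature", "channel", "organ")]
  w <- data.table::dcast(prof, feature + channel ~ organ, value.var = "v")
  organs <- setdiff(names(w), c("feature", "channel"))
  m <- as.matrix(w[, organs, with = FALSE])
  m <- m[apply(m, 1, stats::sd) > 0, , drop = FALSE]
  mz <- t(scale(t(m)))  # standardize each (feature, channel) row across organs
  cr <- cor(mz)
  hc <- hclust(as.dist(1 - cr), method = "average")
  list(correlation = cr, hclust = hc, newick = .hclust_newick(hc))
}

.hclust_newick <- function(hc) {
  ph <- ape::as.phylo(hc)
  ape::write.tree(ph)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.4f  (n = %d targets, k = %d raters)\n",
              x$icc, x$n_targets, x$k_raters))
  invisible(x)
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf("CCC = %.4f  (Pearson r = %.4f)\n", x$ccc, x$pearson_r))
  invisible(x)
}

#' @export
print.gg_anova_result <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA: F(%d, %d) = %.3f, p = %.3g; GG epsilon = %.3f, corrected p = %.3g\n",
    x$df_condition, x$df_error, x$f_statistic, x$p_uncorrected,
    x$epsilon_gg, x$p_gg_corrected
  ))
  invisible(x)
}
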