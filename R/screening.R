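# Decision rules of the stability screen: reliability banding, the
# reconstruction-subset and segmentation-mode comparisons, the
# excellent-ICC-in->=4-organs stage, and the CCC resegmentation filter.

#' Reliability bands for ICC values
#'
#' `excellent` >= 0.75, `good` \[0.60, 0.75), `fair` \[0.40, 0.60),
#' `poor` < 0.40. Lower bounds are closed: 0.75 is excellent, 0.60 good,
#' 0.40 fair.
#'
#' @param icc Numeric vector of ICC values (may contain `NA`).
#' @return Factor with levels `poor < fair < good < excellent`.
#' @export
classify_reliability <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.40, 0.60, 0.75, Inf),
      labels = c("poor", "fair", "good", "excellent"),
      right = FALSE, ordered_result = TRUE)
}

#' Stability screening criteria
#'
#' Defaults operationalize the screening rules: stage 1 keeps features with
#' ICC >= 0.75 in at least 4 organs ("more than 3"); stage 2 keeps features
#' with CCC > 0.6 in at least 3 organs within at least 6 VM reconstructions.
#' The CCC quantifier nesting is ambiguous in prose; the default reading counts
#' a channel as passing when >= `min_organs_ccc` organs pass *within* it and
#' requires >= `min_vm_channels` passing channels (`ccc_nesting =
#' "per_channel"`); the per-organ reading is available as an option and the
#' report states which was used.
#'
#' @param icc_threshold Stage-1 ICC threshold (inclusive).
#' @param min_organs_icc Minimum organs at or above the ICC threshold.
#' @param ccc_threshold Stage-2 CCC threshold (exclusive, `>`).
#' @param min_organs_ccc Minimum organs per channel (or channels per organ).
#' @param min_vm_channels Minimum VM channels.
#' @param ccc_nesting `"per_channel"` or `"per_organ"`.
#' @return Object of class `stability_criteria`.
#' @export
stability_criteria <- function(icc_threshold = 0.75, min_organs_icc = 4L,
                               ccc_threshold = 0.6, min_organs_ccc = 3L,
                               min_vm_channels = 6L,
                               ccc_nesting = c("per_channel", "per_organ")) {
  stopifnot(icc_threshold >= 0, icc_threshold <= 1,
            ccc_threshold >= 0, ccc_threshold <= 1)
  structure(
    list(icc_threshold = icc_threshold,
         min_organs_icc = as.integer(min_organs_icc),
         ccc_threshold = ccc_threshold,
         min_organs_ccc = as.integer(min_organs_ccc),
         min_vm_channels = as.integer(min_vm_channels),
         ccc_nesting = match.arg(ccc_nesting)),
    class = "stability_criteria"
  )
}

# Priority orders used to break exact ties between winners.
SUBSET_PRIORITY <- c("VM_ONLY", "WITHOUT_IODINE", "ALL")
MODE_PRIORITY <- c("3D-2cm", "3D-1cm", "2D-2cm", "2D-1cm")

#' ICC tables for every channel subset and segmentation mode
#'
#' @param ft Long feature table.
#' @param subsets,modes Grid axes (defaults: the three subsets, four modes).
#' @return Nested named list `tables[[subset]][[mode]]` of
#'   [icc_stability_table()] results.
#' @export
icc_grid <- function(ft, subsets = SUBSET_PRIORITY, modes = SEG_MODES) {
  out <- lapply(subsets, function(ss) {
    tabs <- lapply(modes, function(md) icc_stability_table(ft, ss, md))
    names(tabs) <- modes
    tabs
  })
  names(out) <- subsets
  out
}

#' Compare reconstruction subsets (and modes) by average ICC
#'
#' Builds the 3 x 4 grid of mean ICCs over (feature, organ) pairs — undefined
#' ICCs excluded with logged counts — and selects the winning subset and mode;
#' exact ties resolve by the documented priority orders (VM_ONLY >
#' WITHOUT_IODINE > ALL; larger/3D modes first).
#'
#' @param tables An [icc_grid()] result (all 12 cells present).
#' @return List: `grid` (matrix subsets x modes of mean ICC), `winner`
#'   (list `subset`, `mode`), `n_undefined` (matrix of excluded counts).
#' @export
compare_reconstruction_sets <- function(tables) {
  subsets <- names(tables)
  modes <- names(tables[[1]])
  if (is.null(subsets) || is.null(modes)) stop("tables must be a named icc_grid")
  if (!all(SUBSET_PRIORITY %in% subsets) || !all(SEG_MODES %in% modes)) {
    stop("missing ICC table: all 3 subsets x 4 modes must be computed")
  }
  g <- matrix(NA_real_, length(subsets), length(modes),
              dimnames = list(subsets, modes))
  u <- matrix(0L, length(subsets), length(modes), dimnames = dimnames(g))
  for (ss in subsets) {
    for (md in modes) {
      tab <- tables[[ss]][[md]]
      if (is.null(tab)) stop(sprintf("missing ICC table for %s / %s", ss, md))
      g[ss, md] <- mean(tab$icc, na.rm = TRUE)
      u[ss, md] <- sum(is.na(tab$icc))
    }
  }
  cells <- expand.grid(subset = subsets, mode = modes, stringsAsFactors = FALSE)
  cells$avg <- g[cbind(cells$subset, cells$mode)]
  cells$sp <- match(cells$subset, SUBSET_PRIORITY)
  cells$mp <- match(cells$mode, MODE_PRIORITY)
  cells <- cells[order(-cells$avg, cells$sp, cells$mp), ]
  list(grid = g, winner = list(subset = cells$subset[1], mode = cells$mode[1]),
       n_undefined = u)
}

#' Compare segmentation modes by repeated-measures ANOVA
#'
#' Subjects are the (feature, organ) pairs, conditions the four segmentation
#' modes, values their ICCs (complete cases only). The winner is the mode with
#' the highest mean ICC; an exact tie across all modes is flagged instead of
#' picking one.
#'
#' @param tables_by_mode Named list of [icc_stability_table()] results, one per
#'   mode (same channel subset).
#' @return List: `anova` ([repeated_measures_anova_gg()] result), `means`
#'   (named vector), `winner` (mode label or `NA` on a tie), `n_subjects`.
#' @export
compare_segmentation_modes <- function(tables_by_mode) {
  modes <- names(tables_by_mode)
  merged <- NULL
  for (md in modes) {
    t_ <- tables_by_mode[[md]][, c("feature", "organ", "icc"), with = FALSE]
    data.table::setnames(t_, "icc", md)
    merged <- if (is.null(merged)) t_ else merge(merged, t_, by = c("feature", "organ"))
  }
  y <- as.matrix(merged[, modes, with = FALSE])
  keep <- stats::complete.cases(y)
  y <- y[keep, , drop = FALSE]
  res <- repeated_measures_anova_gg(y)
  means <- colMeans(y)
  winner <- if (max(means) - min(means) == 0) NA_character_ else modes[which.max(means)]
  list(anova = res, means = means, winner = winner, n_subjects = nrow(y))
}

#' Stage-1 selection: excellent ICC in enough organs
#'
#' Keeps features whose ICC is at or above `icc_threshold` in at least
#' `min_organs_icc` organs of the winning subset/mode table.
#'
#' @param icc_table An [icc_stability_table()] result.
#' @param criteria A [stability_criteria()].
#' @return List: `selected` (feature names), `detail` (wide feature x organ ICC
#'   table with the qualifying-organ count), `criteria`.
#' @export
select_stable_features <- function(icc_table, criteria = stability_criteria()) {
  wide <- data.table::dcast(icc_table, feature ~ organ, value.var = "icc")
  organs <- setdiff(names(wide), "feature")
  m <- as.matrix(wide[, organs, with = FALSE])
  n_ok <- rowSums(m >= criteria$icc_threshold, na.rm = TRUE)
  wide$n_qualifying_organs <- as.integer(n_ok)
  list(
    selected = wide$feature[n_ok >= criteria$min_organs_icc],
    detail = wide[],
    criteria = criteria
  )
}

#' Per-organ counts of excellent-or-good features
#'
#' @param icc_table An [icc_stability_table()] result.
#' @return `data.table` with columns `organ`, `n_stable` (features whose
#'   reliability band is excellent or good).
#' @export
count_stable_per_organ <- function(icc_table) {
  bands <- classify_reliability(icc_table$icc)
  dt <- data.table::data.table(organ = icc_table$organ,
                               ok = bands %in% c("good", "excellent"))
  dt[, .(n_stable = sum(ok)), by = "organ"][order(organ)]
}

#' Stage-2 selection: CCC resegmentation filter
#'
#' Under the default `per_channel` nesting a feature survives when at least
#' `min_vm_channels` VM channels each have CCC > `ccc_threshold` in at least
#' `min_organs_ccc` organs; under `per_organ`, when at least `min_organs_ccc`
#' organs each pass in at least `min_vm_channels` channels.
#'
#' @param stage1 Character vector of stage-1 features.
#' @param ccc_table A [ccc_resegmentation_table()] result covering them.
#' @param criteria A [stability_criteria()].
#' @return List: `selected`, `detail` (per feature the count used by the rule),
#'   `criteria`.
#' @export
ccc_stability_filter <- function(stage1, ccc_table, criteria = stability_criteria()) {
  tab <- ccc_table[ccc_table$feature %in% stage1, ]
  miss <- setdiff(stage1, unique(tab$feature))
  if (length(miss)) {
    stop(sprintf("ccc_table does not cover stage-1 feature(s): %s",
                 paste(miss, collapse = ", ")))
  }
  tab <- data.table::as.data.table(tab)
  tab[, pass := !is.na(ccc) & ccc > criteria$ccc_threshold]
  if (criteria$ccc_nesting == "per_channel") {
    per_ch <- tab[, .(organs_pass = sum(pass)), by = c("feature", "channel")]
    per_ch[, ch_ok := organs_pass >= criteria$min_organs_ccc]
    det <- per_ch[, .(n_passing_channels = sum(ch_ok)), by = "feature"]
    det[, selected := n_passing_channels >= criteria$min_vm_channels]
  } else {
    per_org <- tab[, .(channels_pass = sum(pass)), by = c("feature", "organ")]
    per_org[, org_ok := channels_pass >= criteria$min_vm_channels]
    det <- per_org[, .(n_passing_organs = sum(org_ok)), by = "feature"]
    det[, selected := n_passing_organs >= criteria$min_organs_ccc]
  }
  keep <- stage1[stage1 %in% det$feature[det$selected]]
  list(selected = keep, detail = det[], criteria = criteria)
}

#' Run the full two-stage screen
#'
#' Computes the ICC grid over the three channel subsets and four segmentation
#' modes, selects the winning subset and mode, compares modes by
#' repeated-measures ANOVA, applies the stage-1 ICC rule on the winning table,
#' counts excellent-or-good features per organ, computes the
#' segmentation-resegmentation CCC table on the winning mode and applies the
#' stage-2 filter.
#'
#' @param ft Long feature table.
#' @param criteria A [stability_criteria()].
#' @return Object of class `screening_report`.
#' @export
screen_features <- function(ft, criteria = stability_criteria()) {
  tables <- icc_grid(ft)
  recon <- compare_reconstruction_sets(tables)
  modes_cmp <- compare_segmentation_modes(tables[[recon$winner$subset]])
  win_tab <- tables[[recon$winner$subset]][[recon$winner$mode]]
  stage1 <- select_stable_features(win_tab, criteria)
  per_organ <- count_stable_per_organ(win_tab)
  ccc_tab <- ccc_resegmentation_table(ft, mode = recon$winner$mode)
  final <- ccc_stability_filter(stage1$selected, ccc_tab, criteria)
  build_report(
    criteria = criteria, icc_grid = recon, mode_comparison = modes_cmp,
    winning_icc_table = win_tab, stage1 = stage1, per_organ = per_organ,
    ccc_table = ccc_tab, final = final
  )
}

#' Assemble a screening report
#'
#' @param criteria,icc_grid,mode_comparison,winning_icc_table,stage1,per_organ,ccc_table,final
#'   Stage outputs, see [screen_features()].
#' @return Object of class `screening_report`; `final$selected` is always a
#'   subset of `stage1$selected`.
#' @export
build_report <- function(criteria, icc_grid, mode_comparison, winning_icc_table,
                         stage1, per_organ, ccc_table, final) {
  if (!all(final$selected %in% stage1$selected)) {
    stop("internal error: final set is not a subset of the stage-1 set")
  }
  structure(
    list(
      criteria = criteria,
      icc_grid = icc_grid,
      mode_comparison = mode_comparison,
      winning_icc_table = winning_icc_table,
      stage1 = stage1,
      per_organ = per_organ,
      ccc_table = ccc_table,
      final = final,
      n_undefined_icc = attr(winning_icc_table, "n_undefined"),
      n_undefined_ccc = attr(ccc_table, "n_undefined")
    ),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Radiomics stability screening report\n")
  cat(sprintf("  winning subset/mode : %s / %s\n",
              x$icc_grid$winner$subset, x$icc_grid$winner$mode))
  cat(sprintf("  mean ICC (winner)   : %.3f\n",
              x$icc_grid$grid[x$icc_grid$winner$subset, x$icc_grid$winner$mode]))
  cat(sprintf("  mode ANOVA          : GG-corrected p = %.3g (epsilon %.3f)\n",
              x$mode_comparison$anova$p_gg_corrected,
              x$mode_comparison$anova$epsilon_gg))
  cat(sprintf("  stage-1 features    : %d (ICC >= %.2f in >= %d organs)\n",
              length(x$stage1$selected), x$criteria$icc_threshold,
              x$criteria$min_organs_icc))
  cat(sprintf("  final features      : %d (CCC > %.2f, %s nesting)\n",
              length(x$final$selected), x$criteria$ccc_threshold,
              x$criteria$ccc_nesting))
  if (length(x$final$selected)) {
    cat("  final set           :", paste(x$final$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a screening report to disk
#'
#' Serializes the audit trail as CSV tables plus a human-readable
#' `summary.md`; every number in the summary is traceable to a table row.
#'
#' @param report A `screening_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid_df <- as.data.frame(report$icc_grid$grid)
  grid_df <- cbind(subset = rownames(grid_df), grid_df)
  write.csv(grid_df, file.path(dir, "icc_grid.csv"), row.names = FALSE)
  data.table::fwrite(report$winning_icc_table, file.path(dir, "icc_table.csv"))
  data.table::fwrite(report$ccc_table, file.path(dir, "ccc_table.csv"))
  data.table::fwrite(report$per_organ, file.path(dir, "stable_per_organ.csv"))
  data.table::fwrite(report$stage1$detail, file.path(dir, "stage1_detail.csv"))
  data.table::fwrite(report$final$detail, file.path(dir, "stage2_detail.csv"))
  an <- report$mode_comparison$anova
  write.csv(data.frame(
    f_statistic = an$f_statistic, df_condition = an$df_condition,
    df_error = an$df_error, epsilon_gg = an$epsilon_gg,
    p_uncorrected = an$p_uncorrected, p_gg_corrected = an$p_gg_corrected
  ), file.path(dir, "anova.csv"), row.names = FALSE)
  lines <- c(
    "# Stability screening summary", "",
    sprintf("- Winning subset/mode: %s / %s", report$icc_grid$winner$subset,
            report$icc_grid$winner$mode),
    sprintf("- Mean ICC grid: see icc_grid.csv; winner mean ICC = %.4f",
            report$icc_grid$grid[report$icc_grid$winner$subset,
                                 report$icc_grid$winner$mode]),
    sprintf("- Mode comparison: F(%d, %d) = %.3f, GG epsilon = %.4f, corrected p = %.4g",
            an$df_condition, an$df_error, an$f_statistic, an$epsilon_gg,
            an$p_gg_corrected),
    sprintf("- Stage 1 (ICC >= %.2f in >= %d organs): %d features",
            report$criteria$icc_threshold, report$criteria$min_organs_icc,
            length(report$stage1$selected)),
    sprintf("- Stage 2 (CCC > %.2f, >= %d organs, >= %d VM channels, %s nesting): %d features",
            report$criteria$ccc_threshold, report$criteria$min_organs_ccc,
            report$criteria$min_vm_channels, report$criteria$ccc_nesting,
            length(report$final$selected)),
    sprintf("- Undefined statistics excluded: %d ICC, %d CCC",
            report$n_undefined_icc, report$n_undefined_ccc),
    "",
    "Final stable features:",
    if (length(report$final$selected)) {
      paste0("- ", report$final$selected)
    } else {
      "- (none)"
    }
  )
  writeLines(lines, file.path(dir, "summary.md"))
  invisible(dir)
}
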