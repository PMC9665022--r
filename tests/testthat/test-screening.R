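test_that("reliability bands use closed lower bounds", {
  x <- c(0.75, 0.74, 0.60, 0.59, 0.40, 0.399, -0.2, 1)
  b <- classify_reliability(x)
  expect_identical(as.character(b),
                   c("excellent", "good", "good", "fair", "fair", "poor", "poor",
                     "excellent"))
  expect_true(is.na(classify_reliability(NA_real_)))
})

test_that("stage-1 selection applies the inclusive >= 4 organ rule", {
  # a boundary row pattern (0.40, 0.83, 0.76, 0.75, 0.89): the 0.75 counts,
  # so 4 organs qualify and the feature is selected
  tab <- data.table::data.table(
    feature = rep(c("f_row", "f_three", "f_all"), each = 5),
    organ = rep(c("air", "liver", "psoas", "fat", "spleen"), 3),
    icc = c(0.40, 0.83, 0.76, 0.75, 0.89,
            0.90, 0.80, 0.76, 0.74, 0.20,
            1, 1, 1, 1, 1)
  )
  sel <- select_stable_features(tab, stability_criteria())
  expect_true("f_row" %in% sel$selected)
  expect_false("f_three" %in% sel$selected)  # exactly 3 qualifying organs
  expect_true("f_all" %in% sel$selected)
  expect_identical(
    sel$detail$n_qualifying_organs[match(c("f_row", "f_three", "f_all"), sel$detail$feature)],
    c(4L, 3L, 5L)
  )
})

test_that("per-organ stable counts match a manual band tally", {
  tab <- data.table::data.table(
    feature = rep(paste0("f", 1:5), each = 2),
    organ = rep(c("liver", "air"), 5),
    icc = c(0.80, 0.10, 0.65, 0.59, 0.75, 0.61, 0.40, NA, 0.99, 0.60)
  )
  cnt <- count_stable_per_organ(tab)
  expect_identical(cnt$n_stable[cnt$organ == "liver"], 4L)  # 0.80,0.65,0.75,0.99
  expect_identical(cnt$n_stable[cnt$organ == "air"], 2L)    # 0.61,0.60
  # ceiling: all ICC = 1 counts the full universe per organ
  tab$icc <- 1
  expect_true(all(count_stable_per_organ(tab)$n_stable == 5L))
  tab$icc <- 0.5
  expect_true(all(count_stable_per_organ(tab)$n_stable == 0L))
})

# Direct quantifier evaluation of the stage-2 rule, written independently.
brute_ccc_filter <- function(stage1, tab, crit) {
  keep <- character()
  for (f in stage1) {
    sub <- tab[tab$feature == f, ]
    if (crit$ccc_nesting == "per_channel") {
      n_ch <- 0L
      for (ch in unique(sub$channel)) {
        n_org <- sum(sub$ccc[sub$channel == ch] > crit$ccc_threshold, na.rm = TRUE)
        if (n_org >= crit$min_organs_ccc) n_ch <- n_ch + 1L
      }
      if (n_ch >= crit$min_vm_channels) keep <- c(keep, f)
    } else {
      n_org <- 0L
      for (og in unique(sub$organ)) {
        n_ch <- sum(sub$ccc[sub$organ == og] > crit$ccc_threshold, na.rm = TRUE)
        if (n_ch >= crit$min_vm_channels) n_org <- n_org + 1L
      }
      if (n_org >= crit$min_organs_ccc) keep <- c(keep, f)
    }
  }
  keep
}

test_that("the CCC filter matches brute-force evaluation of the quantified rule", {
  set.seed(201)
  feats <- paste0("f", 1:12)
  organs <- paste0("o", 1:5)
  chans <- paste0("VM", seq(40, 120, 10))
  for (rep_ in 1:10) {
    tab <- data.table::CJ(feature = feats, organ = organs, channel = chans)
    tab$ccc <- runif(nrow(tab), -0.2, 1)
    for (nesting in c("per_channel", "per_organ")) {
      crit <- stability_criteria(ccc_threshold = runif(1, 0.3, 0.8),
                                 min_organs_ccc = sample(1:5, 1),
                                 min_vm_channels = sample(1:9, 1),
                                 ccc_nesting = nesting)
      got <- ccc_stability_filter(feats, tab, crit)$selected
      expect_setequal(got, brute_ccc_filter(feats, tab, crit))
    }
  }
})

test_that("an all-pass CCC table keeps stage 1 intact; 5 channels is not enough", {
  feats <- c("a", "b")
  tab <- data.table::CJ(feature = feats, organ = paste0("o", 1:5),
                        channel = paste0("VM", seq(40, 120, 10)))
  tab$ccc <- 1
  expect_identical(ccc_stability_filter(feats, tab, stability_criteria())$selected, feats)

  # feature "b" passes in only 5 VM channels
  tab2 <- data.table::copy(tab)
  tab2$ccc[tab2$feature == "b" & tab2$channel %in% paste0("VM", seq(80, 120, 10))] <- 0
  got <- ccc_stability_filter(feats, tab2, stability_criteria(min_vm_channels = 6))
  expect_identical(got$selected, "a")
})

test_that("tightening any criterion never grows a selected set", {
  set.seed(202)
  feats <- paste0("f", 1:20)
  organs <- paste0("o", 1:6)
  icc_tab <- data.table::CJ(feature = feats, organ = organs)
  icc_tab$icc <- runif(nrow(icc_tab))
  prev <- NULL
  for (thr in seq(0.2, 0.95, by = 0.15)) {
    cur <- select_stable_features(icc_tab, stability_criteria(icc_threshold = thr))$selected
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  prev <- NULL
  for (norg in 1:6) {
    cur <- select_stable_features(icc_tab, stability_criteria(min_organs_icc = norg))$selected
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  ctab <- data.table::CJ(feature = feats, organ = organs,
                         channel = paste0("VM", seq(40, 120, 10)))
  ctab$ccc <- runif(nrow(ctab))
  for (knob in c("ccc_threshold", "min_organs_ccc", "min_vm_channels")) {
    prev <- NULL
    vals <- switch(knob,
      ccc_threshold = seq(0.2, 0.9, 0.2),
      min_organs_ccc = 1:6,
      min_vm_channels = c(2, 4, 6, 8)
    )
    for (v in vals) {
      args <- list(ccc_threshold = 0.5, min_organs_ccc = 2L, min_vm_channels = 4L)
      args[[knob]] <- v
      cur <- ccc_stability_filter(feats, ctab, do.call(stability_criteria, args))$selected
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("subset comparison grids are 3 x 4 with documented tie-breaks", {
  # all channels carrying identical ratings: every cell ties at ICC 1
  ft <- simulate_feature_table(
    stable_features = c("A", "B", "C"), features = c("A", "B", "C"),
    organs = c("o1", "o2"), n_patients = 5, stable_noise_sd = 0, seed = 7
  )
  g <- icc_grid(ft)
  cmp <- compare_reconstruction_sets(g)
  expect_identical(dim(cmp$grid), c(3L, 4L))
  expect_true(all(abs(cmp$grid - 1) < 1e-12))
  expect_identical(cmp$winner$subset, "VM_ONLY")
  expect_identical(cmp$winner$mode, "3D-2cm")
  expect_error(compare_reconstruction_sets(list(VM_ONLY = g$VM_ONLY)), "missing ICC table")
  g2 <- g
  g2$ALL$`3D-2cm` <- NULL
  expect_error(compare_reconstruction_sets(g2), "missing ICC table")
})

test_that("mode comparison reports both p-values and flags exact ties", {
  ft <- simulate_feature_table(
    stable_features = "A", features = c("A", "B", "C", "D", "E"),
    organs = c("o1", "o2", "o3"), n_patients = 8, seed = 8
  )
  tabs <- icc_grid(ft, subsets = "VM_ONLY")[["VM_ONLY"]]
  cmp <- compare_segmentation_modes(tabs)
  expect_s3_class(cmp$anova, "gg_anova_result")
  expect_true(is.finite(cmp$anova$p_uncorrected))
  expect_true(is.finite(cmp$anova$p_gg_corrected))
  expect_identical(cmp$winner, "3D-2cm")  # noisier small modes lose

  # identical values in every mode: a tie, F = 0
  t1 <- tabs[["3D-2cm"]]
  same <- list(`2D-1cm` = t1, `2D-2cm` = t1, `3D-1cm` = t1, `3D-2cm` = t1)
  cmp2 <- compare_segmentation_modes(same)
  expect_true(is.na(cmp2$winner))
  expect_equal(cmp2$anova$f_statistic, 0)
})

test_that("the assembled report is internally consistent and reproducible", {
  ft <- simulate_feature_table(
    stable_features = c("A", "B"), features = c("A", "B", "C", "D"),
    organs = paste0("o", 1:5), n_patients = 8, seed = 9
  )
  rep1 <- screen_features(ft)
  expect_s3_class(rep1, "screening_report")
  expect_true(all(rep1$final$selected %in% rep1$stage1$selected))
  expect_setequal(rep1$final$selected, c("A", "B"))

  out <- capture.output(print(rep1))
  expect_true(any(grepl(rep1$icc_grid$winner$mode, out)))
  expect_true(any(grepl(rep1$icc_grid$winner$subset, out)))

  d1 <- file.path(tempdir(), "rep1")
  d2 <- file.path(tempdir(), "rep2")
  write_report(rep1, d1)
  write_report(screen_features(ft), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     info = f)
  }
  expect_true(file.exists(file.path(d1, "summary.md")))
})
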