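test_that("ICC(3,1) is exact on canonical cases", {
  # identical raters, varying targets: perfect consistency
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc_3_1(m)$icc, 1)

  # per-rater additive offsets leave the consistency ICC at 1
  m2 <- cbind(1:4, 1:4 + 10, 1:4 - 5)
  expect_equal(icc_3_1(m2)$icc, 1)

  # hand matrix against the aov-based oracle
  m3 <- matrix(c(1, 3, 2, 5, 2, 5, 2, 6), 4, 2)
  r <- icc_3_1(m3)
  expect_equal(r$icc, oracle_icc(m3), tolerance = 1e-12)
  # stored components reconstruct the statistic exactly
  expect_equal(r$icc, (r$ms_rows - r$ms_error) /
                 (r$ms_rows + (r$k_raters - 1) * r$ms_error))
})

test_that("ICC(3,1) matches the ANOVA oracle on 50 random matrices", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(3:8, 1)
    k <- sample(2:6, 1)
    m <- matrix(rnorm(n * k), n, k) + outer(rnorm(n, sd = 2), rep(1, k))
    expect_equal(icc_3_1(m)$icc, oracle_icc(m), tolerance = 1e-12)
  }
})

test_that("ICC(3,1) is invariant under affine transforms and rater offsets", {
  set.seed(102)
  m <- matrix(rnorm(20), 5, 4) + outer(rnorm(5, sd = 2), rep(1, 4))
  base <- icc_3_1(m)$icc
  expect_equal(icc_3_1(3.2 * m - 17)$icc, base, tolerance = 1e-9)
  off <- matrix(rep(c(5, -2, 0.5, 100), each = 5), 5, 4)
  expect_equal(icc_3_1(m + off)$icc, base, tolerance = 1e-9)
})

test_that("degenerate ICC inputs raise classed conditions", {
  expect_error(icc_3_1(matrix(1, 4, 3)), class = "pcctstab_undefined_icc")
  # rater offsets only (no target variance, no residual): undefined
  m <- matrix(rep(c(0, 10), each = 4), 4, 2)
  expect_error(icc_3_1(m), class = "pcctstab_undefined_icc")
  expect_error(icc_3_1(matrix(1:3, 3, 1)), "2 targets and 2 raters")
  expect_error(icc_3_1(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("CCC matches closed forms, the oracle, and its Pearson bound", {
  expect_equal(ccc(1:5, 1:5)$ccc, 1)
  r <- ccc(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$ccc, 4 / 7, tolerance = 1e-15)
  expect_lt(ccc(c(1, 2, 3), c(-1, -2, -3))$ccc, 0)

  set.seed(103)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n, sd = 0.5) + 0.3
    cr <- ccc(x, y)
    expect_equal(cr$ccc, oracle_ccc(x, y), tolerance = 1e-12)
    expect_lte(abs(cr$ccc), abs(cr$pearson_r) + 1e-12)
  }

  # equal means and variances: CCC equals Pearson r
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  cr <- ccc(x, y)
  expect_equal(cr$ccc, cr$pearson_r, tolerance = 1e-12)

  expect_error(ccc(1:3, 1:4), "equal length")
  expect_error(ccc(1:2, 1:2), "at least 3")
  expect_error(ccc(rep(1, 5), rep(1, 5)), class = "pcctstab_undefined_ccc")
})

test_that("the GG ANOVA matches its eigen-decomposition and aov oracles", {
  set.seed(104)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    k <- sample(3:6, 1)
    y <- matrix(rnorm(n * k), n, k) + outer(rnorm(n), rep(1, k)) +
      outer(rep(1, n), rnorm(k))  # real condition effects
    r <- repeated_measures_anova_gg(y)
    expect_equal(r$epsilon_gg, min(1, max(1 / (k - 1), oracle_gg_epsilon(y))),
                 tolerance = 1e-12)
    expect_gte(r$epsilon_gg, 1 / (k - 1))
    expect_lte(r$epsilon_gg, 1)
    if (i <= 5) {
      expect_equal(r$f_statistic, oracle_rm_f(y), tolerance = 1e-8)
    }
    # deflating both degrees of freedom is conservative for clearly
    # significant F (near F = 1 the two tail probabilities can cross)
    if (r$epsilon_gg < 1 && r$f_statistic >= 2) {
      expect_gte(r$p_gg_corrected, r$p_uncorrected)
    }
  }
})

test_that("pure subject effects give F = 0 and sphericity holds under compound symmetry", {
  y <- outer(rnorm(6), rep(1, 4))  # identical condition means by construction
  r <- repeated_measures_anova_gg(y)
  expect_equal(r$f_statistic, 0)
  expect_equal(r$p_uncorrected, 1)

  set.seed(105)
  y2 <- outer(rnorm(500, sd = 2), rep(1, 4)) + matrix(rnorm(2000), 500, 4)
  expect_gt(repeated_measures_anova_gg(y2)$epsilon_gg, 0.95)
})

test_that("ICC tables have the right raters and flag undefined rows", {
  ft <- simulate_feature_table(
    stable_features = c("A", "B"), features = c("A", "B", "C", "D"),
    organs = c("o1", "o2"), n_patients = 5, seed = 3
  )
  tab <- icc_stability_table(ft, "VM_ONLY", "3D-2cm")
  expect_identical(unique(tab$k_raters), 9L)
  expect_identical(unique(tab$n_targets), 10L)
  expect_identical(nrow(tab), 8L)  # 4 features x 2 organs
  expect_true(all(tab$icc[tab$feature %in% c("A", "B")] > 0.9))

  # one cell recomputed from the raw table with the standalone statistic
  sub <- ft[ft$feature == "C" & ft$organ == "o1" & ft$dim == "3D" &
              ft$diameter_cm == 2 & ft$channel %in% channel_subset("VM_ONLY"), ]
  m <- matrix(NA_real_, 10, 9)
  targets <- unique(sub[, c("patient", "repeat_id")])
  for (t_ in seq_len(nrow(targets))) {
    for (c_ in seq_along(channel_subset("VM_ONLY"))) {
      ch <- channel_subset("VM_ONLY")[c_]
      m[t_, c_] <- sub$value[sub$patient == targets$patient[t_] &
                               sub$repeat_id == targets$repeat_id[t_] &
                               sub$channel == ch]
    }
  }
  expect_equal(tab$icc[tab$feature == "C" & tab$organ == "o1"],
               icc_3_1(m)$icc, tolerance = 1e-12)

  # a feature constant across channels and targets is undefined and counted
  ftc <- data.table::copy(ft)
  ftc[feature == "C", value := 7]
  tabc <- icc_stability_table(ftc, "VM_ONLY", "3D-2cm")
  expect_true(all(is.na(tabc$icc[tabc$feature == "C"])))
  expect_identical(attr(tabc, "n_undefined"), 2L)

  # missing cells are named
  ftm <- ft[!(ft$channel == "VM40" & ft$patient == "P01"), ]
  expect_error(icc_stability_table(ftm, "VM_ONLY", "3D-2cm"), "missing cells")
})

test_that("resegmentation CCC is 1 for identical repeats and spans the VM grid", {
  ft <- simulate_feature_table(
    stable_features = c("A", "B", "C"), features = c("A", "B", "C"),
    organs = c("o1", "o2"), n_patients = 6, stable_noise_sd = 0, seed = 4
  )
  tab <- ccc_resegmentation_table(ft, "3D-2cm")
  expect_identical(nrow(tab), 3L * 2L * 9L)  # feature x organ x VM channel
  expect_true(all(abs(tab$ccc - 1) < 1e-12))

  ftu <- ft[ft$repeat_id == 1, ]
  expect_error(ccc_resegmentation_table(ftu, "3D-2cm"), "unpaired")
})

test_that("air repeats are discordant (pure noise) while liver repeats agree", {
  spec <- tiny_spec(n_patients = 6, master_seed = 17L)
  tabs <- list()
  for (i in seq_len(spec$n_patients)) {
    st <- generate_patient_stack(spec, i)
    segs <- place_segmentations(st$material, spec$jitter_mm, seed = 100L + i)
    segs <- segs[segs$dim == "3D" & segs$diameter_cm == 2 &
                   segs$organ %in% c("air", "liver"), ]
    tab <- extract_features(st, segs)
    tabs[[i]] <- tab
  }
  ft <- data.table::rbindlist(tabs)

  # resegmentation concordance: both repeats are cut from the same image, so
  # overlapping masks share their noise and even air is concordant — the
  # air-is-only-noise signature shows up across channels, not across repeats
  cc <- ccc_resegmentation_table(ft, "3D-2cm")
  air_ccc <- mean(cc$ccc[cc$organ == "air" & cc$feature == "firstorder_Mean"],
                  na.rm = TRUE)
  liver_ccc <- mean(cc$ccc[cc$organ == "liver" & cc$feature == "firstorder_Mean"],
                    na.rm = TRUE)
  expect_gt(air_ccc, 0.5)
  expect_gt(liver_ccc, 0.5)

  # across channels each air ROI sees a fresh noise field, so air is the less
  # consistent organ; liver ratings ride on the frozen patient texture
  icc_tab <- icc_stability_table(ft, "VM_ONLY", "3D-2cm")
  expect_lt(mean(icc_tab$icc[icc_tab$organ == "air"], na.rm = TRUE),
            mean(icc_tab$icc[icc_tab$organ == "liver"], na.rm = TRUE))
})

test_that("channel correlation is symmetric with unit diagonal; duplicates merge first", {
  ft <- simulate_feature_table(
    stable_features = "A", features = c("A", "B", "C", "D", "E"),
    organs = c("o1", "o2"), n_patients = 6, seed = 5
  )
  # duplicate a channel's values exactly
  dup <- ft[ft$channel == "VM40", ]
  dup$channel <- "T3D"
  ft2 <- rbind(ft[ft$channel != "T3D", ], dup)
  rc <- reconstruction_correlation(ft2, "3D-2cm")
  expect_equal(rc$correlation, t(rc$correlation), tolerance = 1e-12)
  expect_equal(unname(diag(rc$correlation)), rep(1, ncol(rc$correlation)))
  expect_equal(rc$correlation["VM40", "T3D"], 1, tolerance = 1e-12)
  cp <- stats::cophenetic(rc$hclust)
  cp <- as.matrix(cp)
  expect_equal(min(cp[upper.tri(cp)]), cp["VM40", "T3D"], tolerance = 1e-12)
  expect_true(grepl("VM40", rc$newick))
})

test_that("organs with identical generative parameters merge first", {
  set.seed(6)
  ft <- simulate_feature_table(
    stable_features = "A", features = c("A", "B", "C", "D"),
    organs = c("o1", "o2", "o3"), n_patients = 6, seed = 6
  )
  # make o3 a near-copy of o1
  f1 <- ft[ft$organ == "o1", ]
  f1$organ <- "o3"
  f1$value <- f1$value + rnorm(nrow(f1), sd = 1e-3)
  ft2 <- rbind(ft[ft$organ != "o3", ], f1)
  oc <- organ_correlation(ft2, "3D-2cm")
  expect_identical(sort(rownames(oc$correlation)), c("o1", "o2", "o3"))
  cp <- as.matrix(stats::cophenetic(oc$hclust))
  expect_equal(min(cp[upper.tri(cp)]), cp["o1", "o3"], tolerance = 1e-12)
  # dendrogram leaf count equals organ count
  expect_identical(length(oc$hclust$labels), 3L)
})
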