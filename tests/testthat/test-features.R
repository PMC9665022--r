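test_that("first-order features match direct arithmetic", {
  img <- array(c(1, 2, 3, 4), dim = c(4, 1, 1))
  m <- pcctstab:::.new_voxel_mask(1:4, c(4, 1, 1), c(1, 1, 1))
  f <- firstorder_features(discretize_roi(img, m, 25))
  expect_equal(unname(f["firstorder_Mean"]), 2.5)
  expect_equal(unname(f["firstorder_RootMeanSquared"]), sqrt(30 / 4))
  expect_equal(unname(f["firstorder_Energy"]), 30)
  expect_equal(unname(f["firstorder_Variance"]), mean((1:4 - 2.5)^2))
  expect_equal(unname(f["firstorder_Range"]), 3)

  # constant ROI: zero entropy, unit uniformity, zero variance
  fc <- firstorder_features(discretize_roi(array(5, dim = c(3, 2, 1)),
                                           pcctstab:::.new_voxel_mask(1:6, c(3, 2, 1), c(1, 1, 1)), 25))
  expect_equal(unname(fc["firstorder_Entropy"]), 0, tolerance = 1e-12)
  expect_equal(unname(fc["firstorder_Uniformity"]), 1)
  expect_equal(unname(fc["firstorder_Variance"]), 0)

  # two equally likely levels: fair-coin entropy of 1 bit
  img2 <- array(rep(c(0, 30), each = 4), dim = c(8, 1, 1))
  f2 <- firstorder_features(discretize_roi(img2, pcctstab:::.new_voxel_mask(1:8, c(8, 1, 1), c(1, 1, 1)), 25))
  expect_equal(unname(f2["firstorder_Entropy"]), 1, tolerance = 1e-9)
})

test_that("GLCM entropies match closed forms on tiny matrices", {
  # uniform 2x2 joint distribution: 2 bits
  f <- pcctstab:::.glcm_single(matrix(0.25, 2, 2))
  expect_equal(unname(f["glcm_JointEntropy"]), 2, tolerance = 1e-9)
  # difference distribution (0.5, 0.5): 1 bit
  expect_equal(unname(f["glcm_DifferenceEntropy"]), 1, tolerance = 1e-9)
  expect_equal(unname(f["glcm_DifferenceAverage"]), 0.5)
  expect_equal(unname(f["glcm_Contrast"]), 0.5)
})

test_that("single-run and alternating run matrices give textbook GLRLM values", {
  # one run of length 3: SRE = 1/9
  P1 <- matrix(c(0, 0, 1), 1, 3)
  f1 <- pcctstab:::.glrlm_single(P1, np = 3)
  expect_equal(unname(f1["glrlm_ShortRunEmphasis"]), 1 / 9)
  expect_equal(unname(f1["glrlm_GrayLevelNonUniformity"]), 1)
  # four runs of length 1 over two levels: SRE = 1, GLN = 2
  P2 <- matrix(c(2, 2), 2, 1)
  f2 <- pcctstab:::.glrlm_single(P2, np = 4)
  expect_equal(unname(f2["glrlm_ShortRunEmphasis"]), 1)
  expect_equal(unname(f2["glrlm_GrayLevelNonUniformity"]), 2)
  expect_equal(unname(f2["glrlm_RunPercentage"]), 1)
})

test_that("constant ROIs give degenerate GLSZM/GLDM/NGTDM values", {
  lev <- array(1L, dim = c(3, 3, 1))
  d <- droi_from_levels(lev)
  fz <- glszm_features(d)
  expect_equal(unname(fz["glszm_SizeZoneNonUniformity"]), 1)  # a single zone
  expect_equal(unname(fz["glszm_ZonePercentage"]), 1 / 9)
  fd <- gldm_features(d)
  # constant 1x1x3 line: dependences (2,3,2) -> GLN = 3
  d3 <- droi_from_levels(array(1L, dim = c(1, 1, 3)))
  expect_equal(unname(gldm_features(d3)["gldm_GrayLevelNonUniformity"]), 3)
  fn <- ngtdm_features(d)
  expect_equal(unname(fn["ngtdm_Coarseness"]), 1e6)  # zero-contrast cap
  # two voxels, levels 1 and 2: sum p_i s_i = 1 -> coarseness 1
  d2 <- droi_from_levels(array(c(1L, 2L), dim = c(2, 1, 1)))
  expect_equal(unname(ngtdm_features(d2)["ngtdm_Coarseness"]), 1)
})

test_that("dependence entropy of a constant ROI is the dependence-size entropy", {
  d3 <- droi_from_levels(array(1L, dim = c(1, 1, 3)))
  P <- gldm_matrix(d3)
  p <- c(2, 1) / 3  # dependence sizes 2,2,3
  expect_equal(unname(gldm_features(d3)["gldm_DependenceEntropy"]),
               -sum(p * log2(p)), tolerance = 1e-9)
})

test_that("the full bank returns exactly the 93 frozen names, all finite", {
  expect_length(feature_names(), 93L)
  expect_identical(length(unique(feature_names())), 93L)
  fams <- table(sub("_.*", "", feature_names()))
  expect_identical(as.integer(fams[c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm")]),
                   c(18L, 24L, 16L, 16L, 14L, 5L))

  set.seed(9)
  img <- array(rnorm(6 * 6 * 4, sd = 40), dim = c(6, 6, 4))
  m <- pcctstab:::.new_voxel_mask(seq_len(144), c(6, 6, 4), c(1, 1, 1))
  fv <- compute_features(img, m, 25)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
})

test_that("adding whole bins shifts location features and nothing else", {
  set.seed(10)
  img <- array(rnorm(100, sd = 40), dim = c(5, 5, 4))
  m <- pcctstab:::.new_voxel_mask(seq_len(100), c(5, 5, 4), c(1, 1, 1))
  f1 <- compute_features(img, m, 25)
  f2 <- compute_features(img + 3 * 25, m, 25)
  shifted <- c("firstorder_Minimum", "firstorder_10Percentile",
               "firstorder_90Percentile", "firstorder_Maximum",
               "firstorder_Mean", "firstorder_Median")
  energetic <- c("firstorder_Energy", "firstorder_TotalEnergy",
                 "firstorder_RootMeanSquared")
  invariant <- setdiff(feature_names(), c(shifted, energetic))
  expect_equal(f1[invariant], f2[invariant], tolerance = 1e-9)
  expect_equal(unname(f2[shifted] - f1[shifted]), rep(75, length(shifted)),
               tolerance = 1e-9)
})

test_that("direction-averaged features are invariant to in-plane 90-degree rotation", {
  set.seed(11)
  img <- array(rnorm(5 * 5 * 3, sd = 40), dim = c(5, 5, 3))
  rot <- aperm(img, c(2, 1, 3))[, 5:1, , drop = FALSE]  # 90-degree rotation
  m <- pcctstab:::.new_voxel_mask(seq_len(75), c(5, 5, 3), c(1, 1, 1))
  f1 <- compute_features(img, m, 25)
  f2 <- compute_features(rot, m, 25)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("texture feature values equal the same formulas applied to oracle matrices", {
  set.seed(12)
  for (i in 1:10) {
    lev <- random_level_array()
    d <- droi_from_levels(lev)
    expect_equal(glcm_features(d), glcm_features(d, matrices = oracle_glcm(lev)),
                 tolerance = 1e-12)
    expect_equal(glrlm_features(d), glrlm_features(d, matrices = oracle_glrlm(lev)),
                 tolerance = 1e-12)
    expect_equal(glszm_features(d), glszm_features(d, P = oracle_glszm(lev)),
                 tolerance = 1e-12)
    expect_equal(gldm_features(d), gldm_features(d, P = oracle_gldm(lev)),
                 tolerance = 1e-12)
    expect_equal(ngtdm_features(d), ngtdm_features(d, M = oracle_ngtdm(lev)),
                 tolerance = 1e-12)
  }
})
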