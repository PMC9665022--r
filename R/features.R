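# The 93-feature non-shape radiomics bank: 18 first-order, 24 GLCM, 16 GLRLM,
# 16 GLSZM, 14 GLDM, 5 NGTDM, following the reference (IBSI-aligned) default
# definitions. Matrix features are computed per direction and averaged; all
# logarithms are base 2 with an additive machine-epsilon guard.

#' The frozen 93-feature name list
#'
#' Read from the versioned text resource shipped with the package; every
#' feature vector is validated against it.
#'
#' @return Character vector of 93 feature names.
#' @export
feature_names <- function() {
  nm <- .glcm_aux_cache[[".feature_names"]]
  if (is.null(nm)) {
    path <- system.file("extdata", "radiomics_feature_names.txt", package = "pcctstab")
    nm <- readLines(path)
    nm <- nm[nzchar(nm)]
    .glcm_aux_cache[[".feature_names"]] <- nm
  }
  nm
}

#' First-order intensity features (18)
#'
#' Computed on the raw ROI intensities; `Entropy` and `Uniformity` use the
#' fixed-bin-width discretized histogram. Energy uses a voxel array shift of 0.
#'
#' @param droi A [discretize_roi()] result.
#' @return Named numeric vector of 18 features.
#' @export
firstorder_features <- function(droi) {
  x <- droi$values
  n <- droi$n
  p <- tabulate(droi$levels_vec, droi$ng) / n
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  xs <- sort(x)
  # type-7 (linear interpolation) quantiles on the pre-sorted vector
  q7 <- function(prob) {
    h <- (n - 1) * prob + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
  }
  q <- vapply(c(0.10, 0.25, 0.50, 0.75, 0.90), q7, 0)
  sel <- x[x >= q[1] & x <= q[5]]
  energy <- sum(x^2)
  c(
    firstorder_Energy = energy,
    firstorder_TotalEnergy = energy * prod(droi$spacing),
    firstorder_Entropy = -sum(p * log2(p + EPS)),
    firstorder_Minimum = xs[1],
    `firstorder_10Percentile` = q[1],
    `firstorder_90Percentile` = q[5],
    firstorder_Maximum = xs[n],
    firstorder_Mean = mu,
    firstorder_Median = q[3],
    firstorder_InterquartileRange = q[4] - q[2],
    firstorder_Range = xs[n] - xs[1],
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation = mean(abs(sel - mean(sel))),
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Skewness = if (m2 == 0) 0 else m3 / m2^1.5,
    firstorder_Kurtosis = if (m2 == 0) 0 else m4 / m2^2,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2)
  )
}

# Cached per-ng index grids for the GLCM feature sums (flat vectors over the
# ng x ng cell grid, plus the difference/sum group indices).
.glcm_aux_cache <- new.env(parent = emptyenv())
.glcm_aux <- function(ng) {
  key <- as.character(ng)
  aux <- .glcm_aux_cache[[key]]
  if (is.null(aux)) {
    iv <- seq_len(ng)
    I <- rep(iv, times = ng)
    J <- rep(iv, each = ng)
    kabs <- abs(I - J)
    ksum <- I + J
    aux <- list(
      iv = iv, I = I, J = J, IJ = I * J, IpJ = I + J,
      ImJ2 = (I - J)^2,
      kd = 0:(ng - 1), ks = 2:(2 * ng),
      ord_d = order(kabs), ends_d = cumsum(tabulate(kabs + 1L, ng)),
      ord_s = order(ksum), ends_s = cumsum(tabulate(ksum - 1L, 2L * ng - 1L))
    )
    .glcm_aux_cache[[key]] <- aux
  }
  aux
}

# 24 GLCM features of one normalized symmetric co-occurrence matrix.
.glcm_single <- function(p) {
  ng <- nrow(p)
  aux <- .glcm_aux(ng)
  pv <- as.vector(p)
  px <- .rowSums(p, ng, ng)
  py <- px  # symmetry
  ux <- sum(aux$iv * px)
  sigx2 <- sum(px * (aux$iv - ux)^2)
  # grouped sums over |i-j| (0..ng-1) and i+j (2..2ng) via cached orderings
  pd <- diff(c(0, cumsum(pv[aux$ord_d])[aux$ends_d]))
  ps <- diff(c(0, cumsum(pv[aux$ord_s])[aux$ends_s]))
  kd <- aux$kd
  da <- sum(kd * pd)
  hxy <- -sum(pv * log2(pv + EPS))
  pxy <- outer(px, py)
  lpxy <- log2(pxy + EPS)
  hxy1 <- -sum(p * lpxy)
  hxy2 <- -sum(pxy * lpxy)
  hx <- -sum(px * log2(px + EPS))
  autoc <- sum(pv * aux$IJ)
  corr <- if (sigx2 < EPS) 1 else (autoc - ux * ux) / sigx2
  imc1 <- if (hx == 0) 0 else (hxy - hxy1) / hx
  v2 <- 1 - exp(-2 * (hxy2 - hxy))
  mcc <- {
    nz <- which(px > 0)
    if (length(nz) < 2) 1 else {
      psub <- p[nz, nz, drop = FALSE]
      q <- (psub %*% (t(psub) / py[nz])) / px[nz]
      ev <- Re(eigen(q, only.values = TRUE, symmetric = FALSE)$values)
      ev2 <- max(ev[-which.max(ev)])  # second-largest eigenvalue
      sqrt(max(0, min(1, ev2)))
    }
  }
  ct <- aux$IpJ - 2 * ux
  ct2 <- sum(pv * ct^2)
  c(
    glcm_Autocorrelation = autoc,
    glcm_JointAverage = ux,
    glcm_ClusterProminence = sum(pv * ct^4),
    glcm_ClusterShade = sum(pv * ct^3),
    glcm_ClusterTendency = ct2,
    glcm_Contrast = sum(pv * aux$ImJ2),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = -sum(pd * log2(pd + EPS)),
    glcm_DifferenceVariance = sum(pd * (kd - da)^2),
    glcm_JointEnergy = sum(pv^2),
    glcm_JointEntropy = hxy,
    glcm_Imc1 = imc1,
    glcm_Imc2 = if (v2 < 0) 0 else sqrt(v2),
    glcm_Idm = sum(pd / (1 + kd^2)),
    glcm_MCC = mcc,
    glcm_Idmn = sum(pd / (1 + (kd / ng)^2)),
    glcm_Id = sum(pd / (1 + kd)),
    glcm_Idn = sum(pd / (1 + kd / ng)),
    glcm_InverseVariance = sum(pd[-1] / kd[-1]^2),
    glcm_MaximumProbability = max(pv),
    glcm_SumAverage = sum(aux$ks * ps),
    glcm_SumEntropy = -sum(ps * log2(ps + EPS)),
    glcm_SumSquares = sigx2  # variance of the gray-level marginal
  )
}

#' GLCM features (24), averaged over directions
#'
#' @param droi A [discretize_roi()] result.
#' @param matrices Optional precomputed [glcm_matrix()] array of symmetrized
#'   per-direction matrices.
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(droi, matrices = NULL) {
  if (is.null(matrices)) {
    dirs <- .glcm_dirs(droi$planar)
    counts <- cpp_glcm_counts(as.integer(droi$levels), droi$dim,
                              storage_mode_int(dirs), droi$ng)
    sym <- FALSE
  } else {
    counts <- matrices
    sym <- TRUE
  }
  ng <- dim(counts)[1]
  acc <- NULL
  nd <- 0L
  for (a in seq_len(dim(counts)[3])) {
    P <- matrix(counts[, , a], ng, ng)
    if (!sym) P <- P + t(P)
    s <- sum(P)
    if (s == 0) next
    f <- .glcm_single(P / s)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  if (nd == 0L) stop("no populated co-occurrence direction")
  acc / nd
}

# 16 run-length features of one direction's count matrix. All sums reduce to
# the gray-level / run-length marginals plus two matrix-vector products.
.glrlm_single <- function(P, np) {
  nr <- sum(P)
  ng <- nrow(P)
  lmax <- ncol(P)
  iv <- seq_len(ng)
  jv <- seq_len(lmax)
  ri <- .rowSums(P, ng, lmax)
  rj <- .colSums(P, ng, lmax)
  mu_i <- sum(iv * ri) / nr
  mu_j <- sum(jv * rj) / nr
  pnz <- P[P > 0] / nr
  u_short <- as.numeric(P %*% (1 / jv^2))  # per gray level
  u_long <- as.numeric(P %*% (jv^2))
  c(
    glrlm_ShortRunEmphasis = sum(rj / jv^2) / nr,
    glrlm_LongRunEmphasis = sum(rj * jv^2) / nr,
    glrlm_GrayLevelNonUniformity = sum(ri^2) / nr,
    glrlm_GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    glrlm_RunLengthNonUniformity = sum(rj^2) / nr,
    glrlm_RunLengthNonUniformityNormalized = sum(rj^2) / nr^2,
    glrlm_RunPercentage = nr / np,
    glrlm_GrayLevelVariance = sum(ri * (iv - mu_i)^2) / nr,
    glrlm_RunVariance = sum(rj * (jv - mu_j)^2) / nr,
    glrlm_RunEntropy = -sum(pnz * log2(pnz + EPS)),
    glrlm_LowGrayLevelRunEmphasis = sum(ri / iv^2) / nr,
    glrlm_HighGrayLevelRunEmphasis = sum(ri * iv^2) / nr,
    glrlm_ShortRunLowGrayLevelEmphasis = sum(u_short / iv^2) / nr,
    glrlm_ShortRunHighGrayLevelEmphasis = sum(u_short * iv^2) / nr,
    glrlm_LongRunLowGrayLevelEmphasis = sum(u_long / iv^2) / nr,
    glrlm_LongRunHighGrayLevelEmphasis = sum(u_long * iv^2) / nr
  )
}

#' GLRLM features (16), averaged over directions
#'
#' @inheritParams glcm_features
#' @param matrices Optional precomputed [glrlm_matrix()] array.
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(droi, matrices = glrlm_matrix(droi)) {
  dm <- dim(matrices)
  acc <- NULL
  nd <- 0L
  for (a in seq_len(dm[3])) {
    P <- matrix(matrices[, , a], dm[1], dm[2])
    if (sum(P) == 0) next
    f <- .glrlm_single(P, droi$n)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  if (nd == 0L) stop("no populated run direction")
  acc / nd
}

#' GLSZM features (16)
#'
#' @inheritParams glcm_features
#' @param P Optional precomputed [glszm_matrix()].
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(droi, P = glszm_matrix(droi)) {
  nz <- sum(P)
  np <- droi$n
  ng <- nrow(P)
  smax <- ncol(P)
  iv <- seq_len(ng)
  jv <- seq_len(smax)
  ri <- .rowSums(P, ng, smax)
  rj <- .colSums(P, ng, smax)
  mu_i <- sum(iv * ri) / nz
  mu_j <- sum(jv * rj) / nz
  pnz <- P[P > 0] / nz
  u_small <- as.numeric(P %*% (1 / jv^2))
  u_large <- as.numeric(P %*% (jv^2))
  c(
    glszm_SmallAreaEmphasis = sum(rj / jv^2) / nz,
    glszm_LargeAreaEmphasis = sum(rj * jv^2) / nz,
    glszm_GrayLevelNonUniformity = sum(ri^2) / nz,
    glszm_GrayLevelNonUniformityNormalized = sum(ri^2) / nz^2,
    glszm_SizeZoneNonUniformity = sum(rj^2) / nz,
    glszm_SizeZoneNonUniformityNormalized = sum(rj^2) / nz^2,
    glszm_ZonePercentage = nz / np,
    glszm_GrayLevelVariance = sum(ri * (iv - mu_i)^2) / nz,
    glszm_ZoneVariance = sum(rj * (jv - mu_j)^2) / nz,
    glszm_ZoneEntropy = -sum(pnz * log2(pnz + EPS)),
    glszm_LowGrayLevelZoneEmphasis = sum(ri / iv^2) / nz,
    glszm_HighGrayLevelZoneEmphasis = sum(ri * iv^2) / nz,
    glszm_SmallAreaLowGrayLevelEmphasis = sum(u_small / iv^2) / nz,
    glszm_SmallAreaHighGrayLevelEmphasis = sum(u_small * iv^2) / nz,
    glszm_LargeAreaLowGrayLevelEmphasis = sum(u_large / iv^2) / nz,
    glszm_LargeAreaHighGrayLevelEmphasis = sum(u_large * iv^2) / nz
  )
}

#' GLDM features (14)
#'
#' @inheritParams glcm_features
#' @param P Optional precomputed [gldm_matrix()].
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(droi, P = gldm_matrix(droi)) {
  nz <- sum(P)  # equals the voxel count
  ng <- nrow(P)
  dmax <- ncol(P)
  iv <- seq_len(ng)
  jv <- seq_len(dmax)
  ri <- .rowSums(P, ng, dmax)
  rj <- .colSums(P, ng, dmax)
  mu_i <- sum(iv * ri) / nz
  mu_j <- sum(jv * rj) / nz
  pnz <- P[P > 0] / nz
  u_small <- as.numeric(P %*% (1 / jv^2))
  u_large <- as.numeric(P %*% (jv^2))
  c(
    gldm_SmallDependenceEmphasis = sum(rj / jv^2) / nz,
    gldm_LargeDependenceEmphasis = sum(rj * jv^2) / nz,
    gldm_GrayLevelNonUniformity = sum(ri^2) / nz,
    gldm_DependenceNonUniformity = sum(rj^2) / nz,
    gldm_DependenceNonUniformityNormalized = sum(rj^2) / nz^2,
    gldm_GrayLevelVariance = sum(ri * (iv - mu_i)^2) / nz,
    gldm_DependenceVariance = sum(rj * (jv - mu_j)^2) / nz,
    gldm_DependenceEntropy = -sum(pnz * log2(pnz + EPS)),
    gldm_LowGrayLevelEmphasis = sum(ri / iv^2) / nz,
    gldm_HighGrayLevelEmphasis = sum(ri * iv^2) / nz,
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(u_small / iv^2) / nz,
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(u_small * iv^2) / nz,
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(u_large / iv^2) / nz,
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(u_large * iv^2) / nz
  )
}

#' NGTDM features (5)
#'
#' Coarseness is capped at 1e6 when its denominator vanishes (constant ROI),
#' matching reference behaviour; the cap is recorded in the methods vignette.
#'
#' @inheritParams glcm_features
#' @param M Optional precomputed [ngtdm_matrix()].
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(droi, M = ngtdm_matrix(droi)) {
  n_i <- M[, 1]
  s_i <- M[, 2]
  nvp <- sum(n_i)
  if (nvp == 0) {
    return(c(ngtdm_Coarseness = 1e6, ngtdm_Contrast = 0, ngtdm_Busyness = 0,
             ngtdm_Complexity = 0, ngtdm_Strength = 0))
  }
  p <- n_i / nvp
  present <- which(p > 0)
  ngp <- length(present)
  iv <- present
  pi_ <- p[present]
  si_ <- s_i[present]
  dI <- outer(iv, iv, "-")
  coarse_den <- sum(p * s_i)
  coarseness <- if (coarse_den == 0) 1e6 else min(1 / coarse_den, 1e6)
  contrast <- if (ngp == 1) 0 else {
    sum(outer(pi_, pi_) * dI^2) / (ngp * (ngp - 1)) * sum(s_i) / nvp
  }
  busy_den <- sum(abs(outer(iv * pi_, iv * pi_, "-")))
  busyness <- if (busy_den == 0) 0 else sum(p * s_i) / busy_den
  complexity <- sum(abs(dI) * (outer(pi_ * si_, pi_ * si_, "+")) /
                      outer(pi_, pi_, "+")) / nvp
  strength_den <- sum(s_i)
  strength <- if (strength_den == 0) 0 else {
    sum(outer(pi_, pi_, "+") * dI^2) / strength_den
  }
  c(ngtdm_Coarseness = coarseness, ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness, ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}

#' Compute the full 93-feature vector of one image/mask pair
#'
#' @param image Numeric array.
#' @param mask A `voxel_mask`.
#' @param bin_width Discretization bin width (default 25 intensity units).
#' @return Named numeric vector of 93 finite values, in the canonical order of
#'   [feature_names()].
#' @export
compute_features <- function(image, mask, bin_width = 25) {
  droi <- discretize_roi(image, mask, bin_width)
  fv <- c(
    firstorder_features(droi),
    glcm_features(droi),
    glrlm_features(droi),
    glszm_features(droi),
    gldm_features(droi),
    ngtdm_features(droi)
  )
  ref <- feature_names()
  if (!identical(names(fv), ref)) {
    stop("feature vector does not match the frozen 93-name reference list")
  }
  if (any(!is.finite(fv))) {
    stop(sprintf("non-finite feature value(s): %s",
                 paste(names(fv)[!is.finite(fv)], collapse = ", ")))
  }
  fv
}
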