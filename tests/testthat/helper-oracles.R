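# Independent brute-force oracles. Deliberately naive (plain loops, different
# algorithms from the package internals) so they can arbitrate correctness.

# Build a discretized-ROI object directly from an integer level array
# (0 = outside mask), bypassing image discretization.
droi_from_levels <- function(lev, spacing = c(1, 1, 1), bin_width = 25) {
  lev <- array(as.integer(lev), dim = dim(lev))
  lv <- lev[lev > 0]
  structure(
    list(
      levels = lev, dim = dim(lev), spacing = spacing,
      values = as.numeric(lv) * bin_width, levels_vec = lv,
      ng = max(lv), n = length(lv), bin_width = bin_width,
      bin_edges = (0:max(lv)) * bin_width, planar = dim(lev)[3] == 1L
    ),
    class = "discretized_roi"
  )
}

random_level_array <- function(max_dim = 6, max_ng = 4, p_masked = 0.8) {
  d <- c(sample(2:max_dim, 1), sample(2:max_dim, 1), sample(1:max_dim, 1))
  lev <- array(0L, dim = d)
  inside <- runif(prod(d)) < p_masked
  if (!any(inside)) inside[sample(prod(d), 2)] <- TRUE
  lev[inside] <- sample.int(max_ng, sum(inside), replace = TRUE)
  if (all(lev == 0)) lev[1] <- 1L
  # renumber so levels are 1..ng with max attained
  lev
}

dirs_for <- function(lev) {
  d3 <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0),
    c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
  if (dim(lev)[3] == 1L) d3[d3[, 3] == 0, , drop = FALSE] else d3
}

nbrs_for <- function(lev) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (dim(lev)[3] == 1L) g[g[, 3] == 0, , drop = FALSE] else g
}

in_box <- function(v, d) all(v >= 1) && all(v <= d)

# Symmetrized co-occurrence counts by exhaustive voxel-pair enumeration.
oracle_glcm <- function(lev, dirs = dirs_for(lev)) {
  d <- dim(lev)
  ng <- max(lev)
  out <- array(0L, dim = c(ng, ng, nrow(dirs)))
  for (a in seq_len(nrow(dirs))) {
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      li <- lev[x, y, z]
      if (li == 0) next
      v2 <- c(x, y, z) + dirs[a, ]
      if (!in_box(v2, d)) next
      lj <- lev[v2[1], v2[2], v2[3]]
      if (lj == 0) next
      out[li, lj, a] <- out[li, lj, a] + 1L
      out[lj, li, a] <- out[lj, li, a] + 1L
    }
  }
  out
}

# Run-length counts by grouping voxels into lines and run-length encoding;
# a different algorithm from the implementation's start-and-walk scan.
oracle_glrlm <- function(lev, dirs = dirs_for(lev)) {
  d <- dim(lev)
  ng <- max(lev)
  lmax <- max(d)
  out <- array(0L, dim = c(ng, lmax, nrow(dirs)))
  co <- as.matrix(expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3]))
  for (a in seq_len(nrow(dirs))) {
    dv <- dirs[a, ]
    t_ <- co %*% dv
    anchor <- co * sum(dv^2) - as.vector(t_) %*% t(dv)
    key <- apply(anchor, 1, paste, collapse = ",")
    for (line in split(seq_len(nrow(co)), key)) {
      ord <- line[order(t_[line])]
      r <- rle(lev[co[ord, , drop = FALSE]])
      for (i in seq_along(r$values)) {
        if (r$values[i] > 0) {
          out[r$values[i], r$lengths[i], a] <- out[r$values[i], r$lengths[i], a] + 1L
        }
      }
    }
  }
  out
}

# Size zones by repeated flood fill.
oracle_glszm <- function(lev, nbrs = nbrs_for(lev)) {
  d <- dim(lev)
  ng <- max(lev)
  seen <- array(FALSE, dim = d)
  zones <- list()
  co_all <- as.matrix(expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3]))
  for (r in seq_len(nrow(co_all))) {
    v <- co_all[r, ]
    if (seen[v[1], v[2], v[3]] || lev[v[1], v[2], v[3]] == 0) next
    li <- lev[v[1], v[2], v[3]]
    queue <- list(v)
    seen[v[1], v[2], v[3]] <- TRUE
    size <- 0L
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1L
      for (o in seq_len(nrow(nbrs))) {
        w <- cur + nbrs[o, ]
        if (!in_box(w, d)) next
        if (!seen[w[1], w[2], w[3]] && lev[w[1], w[2], w[3]] == li) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue <- c(queue, list(w))
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(li, size)
  }
  zm <- do.call(rbind, zones)
  P <- matrix(0L, ng, max(zm[, 2]))
  for (i in seq_len(nrow(zm))) P[zm[i, 1], zm[i, 2]] <- P[zm[i, 1], zm[i, 2]] + 1L
  P
}

oracle_gldm <- function(lev, nbrs = nbrs_for(lev)) {
  d <- dim(lev)
  ng <- max(lev)
  P <- matrix(0L, ng, nrow(nbrs) + 1)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    li <- lev[x, y, z]
    if (li == 0) next
    dep <- 1L
    for (o in seq_len(nrow(nbrs))) {
      w <- c(x, y, z) + nbrs[o, ]
      if (in_box(w, d) && lev[w[1], w[2], w[3]] == li) dep <- dep + 1L
    }
    P[li, dep] <- P[li, dep] + 1L
  }
  P
}

oracle_ngtdm <- function(lev, nbrs = nbrs_for(lev)) {
  d <- dim(lev)
  ng <- max(lev)
  M <- matrix(0, ng, 2)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    li <- lev[x, y, z]
    if (li == 0) next
    vals <- c()
    for (o in seq_len(nrow(nbrs))) {
      w <- c(x, y, z) + nbrs[o, ]
      if (in_box(w, d) && lev[w[1], w[2], w[3]] > 0) {
        vals <- c(vals, lev[w[1], w[2], w[3]])
      }
    }
    if (length(vals) == 0) next
    M[li, 1] <- M[li, 1] + 1
    M[li, 2] <- M[li, 2] + abs(li - mean(vals))
  }
  M
}

# ICC(3,1) via a stats::aov two-way decomposition.
oracle_icc <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  df <- data.frame(
    value = as.vector(m),
    target = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(value ~ target + rater, data = df))[[1]]
  ms_t <- tab["target", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  (ms_t - ms_e) / (ms_t + (k - 1) * ms_e)
}

# Lin's CCC via the r * C_b factorization (population moments).
oracle_ccc <- function(x, y) {
  n <- length(x)
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  r <- stats::cor(x, y)
  cb <- 2 * sx * sy / (sx^2 + sy^2 + (mean(x) - mean(y))^2)
  r * cb
}

# Greenhouse-Geisser epsilon via the eigenvalues of the double-centered
# condition covariance, built with explicit loops.
oracle_gg_epsilon <- function(y) {
  k <- ncol(y)
  s <- stats::cov(y)
  cc <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    cc[i, j] <- s[i, j] - mean(s[i, ]) - mean(s[, j]) + mean(s)
  }
  lam <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  sum(lam)^2 / ((k - 1) * sum(lam^2))
}

# Within-subject F via aov with an Error stratum.
oracle_rm_f <- function(y) {
  n <- nrow(y)
  k <- ncol(y)
  df <- data.frame(
    value = as.vector(y),
    subj = factor(rep(seq_len(n), times = k)),
    cond = factor(rep(seq_len(k), each = n))
  )
  fit <- summary(stats::aov(value ~ cond + Error(subj / cond), data = df))
  tab <- fit[["Error: subj:cond"]][[1]]
  tab["cond", "F value"]
}

# A tiny fixed cohort spec that keeps unit tests fast: coarse voxels so the
# 2 cm sphere plus jitter still fits each tissue block.
tiny_spec <- function(n_patients = 2, master_seed = 1L) {
  cohort_spec(
    n_patients = n_patients, master_seed = master_seed,
    shape = c(32L, 48L, 12L), spacing = c(2, 2, 3)
  )
}

# Reduced cohort used for the seeded ordering checks.
reduced_spec <- function(master_seed) {
  cohort_spec(
    n_patients = 10L, master_seed = master_seed,
    shape = c(64L, 96L, 24L), spacing = c(1.4, 1.4, 2.5)
  )
}
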