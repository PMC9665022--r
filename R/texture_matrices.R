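# Texture-matrix builders. Counting runs in compiled code; these wrappers fix
# the direction/neighbourhood conventions (distance 1, 13 unique directions in
# 3D / 4 in-plane, 26/8-connectivity) and return plain R matrices.

#' Gray level co-occurrence matrices
#'
#' Symmetrized co-occurrence counts at distance 1, one matrix per direction
#' (13 unique directions in 3D, 4 in-plane for single-slice masks). Features
#' are computed per direction and averaged, so the per-direction matrices are
#' retained.
#'
#' @param droi A [discretize_roi()] result.
#' @return Integer array `ng x ng x n_directions`; each slice equals its
#'   transpose.
#' @export
glcm_matrix <- function(droi) {
  dirs <- .glcm_dirs(droi$planar)
  counts <- cpp_glcm_counts(as.integer(droi$levels), droi$dim,
                            storage_mode_int(dirs), droi$ng)
  for (a in seq_len(dim(counts)[3])) {
    counts[, , a] <- counts[, , a] + t(counts[, , a])
  }
  counts
}

#' Gray level run length matrices
#'
#' Counts of maximal equal-level runs per direction; `P[i, j]` is the number
#' of runs of gray level `i` and length `j`.
#'
#' @param droi A [discretize_roi()] result.
#' @return Integer array `ng x max_run_length x n_directions`.
#' @export
glrlm_matrix <- function(droi) {
  dirs <- .glcm_dirs(droi$planar)
  cpp_glrlm_counts(as.integer(droi$levels), droi$dim,
                   storage_mode_int(dirs), droi$ng)
}

#' Gray level size zone matrix
#'
#' Zones are connected components of equal gray level under 26-connectivity
#' (8 in-plane for single-slice masks); `P[i, j]` counts zones of level `i`
#' and size `j` voxels.
#'
#' @param droi A [discretize_roi()] result.
#' @return Integer matrix `ng x max_zone_size`.
#' @export
glszm_matrix <- function(droi) {
  off <- .neighbor_offsets(droi$planar)
  z <- cpp_glszm_zones(as.integer(droi$levels), droi$dim, storage_mode_int(off))
  smax <- max(z$size)
  cnt <- tabulate(z$level + droi$ng * (z$size - 1L), nbins = droi$ng * smax)
  matrix(cnt, droi$ng, smax)
}

#' Gray level dependence matrix
#'
#' The dependence of a voxel is 1 plus the number of neighbours (distance 1,
#' exact level equality) sharing its gray level; `P[i, j]` counts voxels of
#' level `i` with dependence `j`. Column totals sum to the voxel count.
#'
#' @param droi A [discretize_roi()] result.
#' @return Integer matrix `ng x (n_neighbors + 1)`.
#' @export
gldm_matrix <- function(droi) {
  off <- .neighbor_offsets(droi$planar)
  cpp_gldm_counts(as.integer(droi$levels), droi$dim, storage_mode_int(off), droi$ng)
}

#' Neighbourhood gray tone difference accumulators
#'
#' Per gray level `i`: `n_i`, the number of masked voxels of level `i` with at
#' least one masked neighbour, and `s_i`, the summed absolute difference
#' between `i` and the mean level of the voxel's masked neighbours.
#'
#' @param droi A [discretize_roi()] result.
#' @return Numeric matrix `ng x 2` with columns `n_i`, `s_i`.
#' @export
ngtdm_matrix <- function(droi) {
  off <- .neighbor_offsets(droi$planar)
  m <- cpp_ngtdm_counts(as.integer(droi$levels), droi$dim,
                        storage_mode_int(off), droi$ng)
  colnames(m) <- c("n_i", "s_i")
  m
}

# Rcpp expects integer matrices; expand.grid/rbind produce doubles.
storage_mode_int <- function(m) {
  storage.mode(m) <- "integer"
  m
}
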