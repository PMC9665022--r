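# Direction sets at distance 1. In 3D the 13 unique voxel directions (the 26
# neighbours modulo sign); for single-slice masks the 4 unique in-plane
# directions. Out-of-plane directions would be empty on a one-slice mask; they
# are removed explicitly so that per-direction feature averaging runs over
# populated directions only.
.DIRS3 <- local({
  m <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0),
    c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
  storage.mode(m) <- "integer"
  m
})
.DIRS2 <- .DIRS3[.DIRS3[, 3] == 0, , drop = FALSE]

.NBR3 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
})
.NBR2 <- .NBR3[.NBR3[, 3] == 0, , drop = FALSE]

.glcm_dirs <- function(planar) if (planar) .DIRS2 else .DIRS3

# Full neighbourhoods (26-connectivity in 3D, 8 in-plane) used by GLSZM zones,
# GLDM dependences and NGTDM neighbourhood means.
.neighbor_offsets <- function(planar) if (planar) .NBR2 else .NBR3

#' Fixed-bin-width discretization of a region of interest
#'
#' Maps ROI intensities to integer gray levels with bins of constant width
#' anchored at the ROI minimum: `level(v) = floor((I(v) - min I) / bin_width) + 1`.
#' Adding an exact multiple of the bin width to all intensities leaves the
#' levels unchanged. The discretized ROI is cropped to its bounding box, with
#' level 0 marking voxels outside the mask.
#'
#' @param image Numeric array (the reconstruction volume).
#' @param mask A `voxel_mask` with the image's geometry.
#' @param bin_width Bin width in intensity units (> 0); the extraction default
#'   is 25.
#' @return Object of class `discretized_roi`: `levels` (integer array over the
#'   bounding box), `dim`, `spacing`, `values` (raw intensities),
#'   `levels_vec`, `ng`, `n`, `bin_width`, `bin_edges`, `planar`.
#' @export
discretize_roi <- function(image, mask, bin_width = 25) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (!identical(as.integer(dim(image)), mask$shape)) {
    stop("geometry error: image shape does not match the mask's recorded shape")
  }
  if (length(mask$idx) == 0L) stop("empty mask")
  vals <- image[mask$idx]
  co <- if (is.null(mask$coords)) arrayInd(mask$idx, .dim = mask$shape) else mask$coords
  lo <- c(min(co[, 1]), min(co[, 2]), min(co[, 3]))
  hi <- c(max(co[, 1]), max(co[, 2]), max(co[, 3]))
  bdim <- hi - lo + 1L
  minv <- min(vals)
  lv <- as.integer(floor((vals - minv) / bin_width)) + 1L
  ng <- max(lv)
  lev <- array(0L, dim = bdim)
  lev[cbind(co[, 1] - lo[1] + 1L, co[, 2] - lo[2] + 1L, co[, 3] - lo[3] + 1L)] <- lv
  structure(
    list(
      levels = lev, dim = bdim, spacing = mask$spacing,
      values = vals, levels_vec = lv, ng = ng, n = length(vals),
      bin_width = bin_width, bin_edges = minv + bin_width * (0:ng),
      planar = bdim[3] == 1L
    ),
    class = "discretized_roi"
  )
}
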