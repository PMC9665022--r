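# Voxel masks are lists: shape, spacing, idx (1-based linear indices into the
# image array), and the provenance fields of the segmentation spec that built
# them. Voxel indices are 1-based (x, y, z); the physical position of a voxel
# is (index - 1) * spacing, with phantom axes grid-aligned (no origin or
# direction handling).

.new_voxel_mask <- function(idx, shape, spacing, provenance = NULL, coords = NULL) {
  if (length(idx) == 0L) stop("mask is empty")
  structure(
    list(idx = as.integer(idx), shape = as.integer(shape),
         spacing = as.numeric(spacing), provenance = provenance,
         coords = coords),
    class = "voxel_mask"
  )
}

#' Disk (2D) brush mask
#'
#' All voxels on the centre slice whose in-plane physical distance from the
#' centre voxel is at most `diameter_cm / 2`. Boundary voxels whose centres lie
#' exactly on the radius are included (deterministic `<=` tie-break).
#'
#' @param center Voxel index `c(x, y, z)`, 1-based.
#' @param diameter_cm Maximum diameter in cm; must be at least twice the
#'   largest in-plane spacing.
#' @param spacing Voxel spacing `c(sx, sy, sz)` in mm.
#' @param shape Image grid `c(nx, ny, nz)` in voxels.
#' @return A `voxel_mask`.
#' @export
disk_mask <- function(center, diameter_cm, spacing, shape) {
  r_mm <- diameter_cm * 10 / 2
  if (r_mm < max(spacing[1:2])) {
    stop("degenerate diameter: disk must span at least twice the in-plane spacing")
  }
  rx <- floor(r_mm / spacing[1])
  ry <- floor(r_mm / spacing[2])
  dx <- seq(-rx, rx)
  dy <- seq(-ry, ry)
  g <- expand.grid(dx = dx, dy = dy)
  keep <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 <= r_mm^2 + 1e-9
  g <- g[keep, , drop = FALSE]
  x <- center[1] + g$dx
  y <- center[2] + g$dy
  z <- rep(center[3], nrow(g))
  if (any(x < 1 | x > shape[1] | y < 1 | y > shape[2] | z < 1 | z > shape[3])) {
    stop("placement error: disk extends outside the volume")
  }
  idx <- x + shape[1] * (y - 1) + shape[1] * shape[2] * (z - 1)
  .new_voxel_mask(idx, shape, spacing, coords = cbind(x, y, z))
}

#' Sphere (3D) brush mask
#'
#' All voxels whose physical distance from the centre voxel is at most
#' `diameter_cm / 2`, spacing-aware on anisotropic grids (fewer slices than
#' in-plane voxels when the slice spacing is larger).
#'
#' @inheritParams disk_mask
#' @return A `voxel_mask`.
#' @export
sphere_mask <- function(center, diameter_cm, spacing, shape) {
  r_mm <- diameter_cm * 10 / 2
  if (r_mm < max(spacing)) {
    stop("degenerate diameter: sphere must span at least twice the largest spacing")
  }
  rr <- floor(r_mm / spacing)
  g <- expand.grid(dx = seq(-rr[1], rr[1]), dy = seq(-rr[2], rr[2]),
                   dz = seq(-rr[3], rr[3]))
  keep <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2 <=
    r_mm^2 + 1e-9
  g <- g[keep, , drop = FALSE]
  x <- center[1] + g$dx
  y <- center[2] + g$dy
  z <- center[3] + g$dz
  if (any(x < 1 | x > shape[1] | y < 1 | y > shape[2] | z < 1 | z > shape[3])) {
    stop("placement error: sphere extends outside the volume")
  }
  idx <- x + shape[1] * (y - 1) + shape[1] * shape[2] * (z - 1)
  .new_voxel_mask(idx, shape, spacing, coords = cbind(x, y, z))
}

#' Build the mask of one segmentation spec row
#'
#' @param seg One row of a [place_segmentations()] plan.
#' @param shape,spacing Image geometry.
#' @return A `voxel_mask` carrying the spec row as provenance.
#' @export
build_mask <- function(seg, shape, spacing) {
  center <- c(seg$cx, seg$cy, seg$cz)
  m <- if (seg$dim == "2D") {
    disk_mask(center, seg$diameter_cm, spacing, shape)
  } else {
    sphere_mask(center, seg$diameter_cm, spacing, shape)
  }
  m$provenance <- as.list(seg)
  m
}

#' Place the 48-segmentation plan of one patient
#'
#' For every tissue, dimensionality (2D disk / 3D sphere), maximum diameter
#' (1 or 2 cm) and repeat (1, 2): repeat 1 is centred in the tissue block,
#' repeat 2 displaces the centre by a random offset of magnitude at most
#' `jitter_mm`, emulating an independent manual redraw. Every mask is
#' re-checked to lie entirely inside its organ's label region.
#'
#' @param mv A [build_material_volume()] result.
#' @param jitter_mm Maximum physical displacement (mm) of the repeat centre.
#' @param seed Integer seed; the plan is deterministic given it.
#' @return data.frame with 48 rows: `organ`, `dim`, `diameter_cm`,
#'   `repeat_id`, `cx`, `cy`, `cz` (voxel centre, 1-based).
#' @export
place_segmentations <- function(mv, jitter_mm = 3, seed = 1L) {
  stopifnot(inherits(mv, "material_volume"))
  set.seed(seed)
  blocks <- mv$blocks
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    organ <- blocks$tissue[i]
    base_center <- round(c(
      (blocks$x0[i] + blocks$x1[i]) / 2,
      (blocks$y0[i] + blocks$y1[i]) / 2,
      (blocks$z0[i] + blocks$z1[i]) / 2
    ))
    for (dim_ in c("2D", "3D")) {
      for (diam in c(1, 2)) {
        for (rep_ in 1:2) {
          center <- base_center
          if (rep_ == 2L && jitter_mm > 0) {
            center <- .jittered_center(mv, i, base_center, dim_, diam, jitter_mm)
          }
          seg <- data.frame(
            organ = organ, dim = dim_, diameter_cm = diam, repeat_id = rep_,
            cx = center[1], cy = center[2], cz = center[3],
            stringsAsFactors = FALSE
          )
          .check_containment(mv, i, seg)
          out[[length(out) + 1L]] <- seg
        }
      }
    }
  }
  do.call(rbind, out)
}

# Draw a jittered centre whose mask stays inside the organ block; retries a
# bounded number of times before raising a placement error naming the organ.
.jittered_center <- function(mv, organ_index, base_center, dim_, diam, jitter_mm) {
  for (attempt in 1:50) {
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    off_mm <- dir * runif(1, 0, jitter_mm)
    center <- base_center + round(off_mm / mv$spacing)
    seg <- data.frame(
      organ = mv$blocks$tissue[organ_index], dim = dim_, diameter_cm = diam,
      repeat_id = 2L, cx = center[1], cy = center[2], cz = center[3],
      stringsAsFactors = FALSE
    )
    ok <- tryCatch({
      .check_containment(mv, organ_index, seg)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(center)
  }
  stop(sprintf("placement error: no contained jittered mask found for organ '%s'",
               mv$blocks$tissue[organ_index]))
}

.check_containment <- function(mv, organ_index, seg) {
  m <- build_mask(seg, mv$shape, mv$spacing)
  if (!all(mv$label_map[m$idx] == organ_index)) {
    stop(sprintf("placement error: mask leaves organ '%s'", seg$organ))
  }
  invisible(m)
}

#' Collapse a patient's masks into one label map
#'
#' Writes the 48 segmentations into a single integer volume (label = spec row
#' index, later rows win on overlap) together with a legend table. Suitable
#' for NIfTI export next to the channel volumes.
#'
#' @param segs A [place_segmentations()] plan.
#' @param shape,spacing Image geometry.
#' @return List with `label_map` (integer array) and `legend` (data.frame:
#'   label, organ, dim, diameter_cm, repeat_id).
#' @export
masks_to_labelmap <- function(segs, shape, spacing) {
  lm <- array(0L, dim = shape)
  for (k in seq_len(nrow(segs))) {
    m <- build_mask(segs[k, ], shape, spacing)
    lm[m$idx] <- k
  }
  legend <- data.frame(
    label = seq_len(nrow(segs)),
    organ = segs$organ, dim = segs$dim,
    diameter_cm = segs$diameter_cm, repeat_id = segs$repeat_id
  )
  list(label_map = lm, legend = legend)
}
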