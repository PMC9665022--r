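#' Default tissue spectral models
#'
#' One row per tissue class with its water-equivalent base attenuation at the
#' reference (virtual non-contrast) energy, the amplitude and correlation
#' length of the patient-fixed spatial texture field, and the mean/spatial
#' spread of iodine uptake in the portal-venous phase. Air is pure noise
#' (no intrinsic texture, no iodine); lung is modelled as low-attenuation
#' perfused parenchyma.
#'
#' @return A `data.frame` with columns `tissue`, `hu_vnc` (HU),
#'   `hu_sigma_texture` (HU), `texture_correlation_length` (mm),
#'   `iodine_mgml` (mg/ml) and `iodine_sigma` (mg/ml).
#' @export
default_tissues <- function() {
  data.frame(
    tissue = c("air", "lung", "fat", "muscle", "liver", "spleen"),
    hu_vnc = c(-1000, -900, -105, 55, 60, 50),
    hu_sigma_texture = c(0, 10, 12, 18, 22, 24),
    texture_correlation_length = c(4, 1, 5, 6, 6, 6),
    iodine_mgml = c(0, 0.2, 0, 0.8, 2.0, 2.4),
    iodine_sigma = c(0, 0.08, 0, 0.25, 0.5, 0.6),
    stringsAsFactors = FALSE
  )
}

#' Iodine enhancement versus photon energy
#'
#' Attenuation added per mg/ml of iodine at each virtual monoenergetic energy.
#' Iodine enhancement falls steeply with keV; only the strict monotonicity of
#' the curve (not its absolute scale) is load-bearing for the stability
#' analysis.
#'
#' @return List with `energies` (keV) and `enhancement_per_mgml`
#'   (HU per mg/ml), both length 9, strictly decreasing in energy.
#' @export
default_iodine_curve <- function() {
  list(
    energies = VM_ENERGIES,
    enhancement_per_mgml = c(30, 21, 15, 11, 8.5, 6.8, 5.6, 4.7, 4.0)
  )
}

#' Cohort specification
#'
#' Parameters of the synthetic multi-reconstruction cohort. Defaults emulate
#' the study conditions: 10 patients, 12 reconstruction channels each, noise
#' that decreases with virtual monoenergetic energy, and a reduced
#' 128 x 128 x 40 grid at 0.7 x 0.7 x 1.5 mm spacing (1.5 mm is the acquisition
#' slice thickness; 0.7 mm is a plausible abdominal in-plane value, recorded in
#' the manifest).
#'
#' @param n_patients Number of patients (>= 2; the ICC needs between-target
#'   variance).
#' @param master_seed Integer master seed; every stochastic draw in the cohort
#'   derives from it.
#' @param shape Grid size in voxels, `c(nx, ny, nz)`.
#' @param spacing Voxel spacing in mm, `c(sx, sy, sz)`.
#' @param noise_sigma_vm Noise standard deviation (HU) per VM energy, length 9,
#'   aligned with 40...120 keV. Default decreases linearly 25 -> 9 HU.
#' @param noise_sigma_t3d,noise_sigma_vnc Noise (HU) of the polyenergetic and
#'   virtual non-contrast channels; the VNC default is higher than mid-keV VM
#'   noise because material decomposition amplifies noise.
#' @param noise_sigma_iodine Noise of the iodine map in mg/ml.
#' @param artifact_sigma_vnc,artifact_sigma_t3d Amplitude (HU) of the
#'   spatially correlated reconstruction residue specific to the derived
#'   channels (decomposition / beam-hardening artifacts); unlike white noise
#'   it does not average out over an ROI.
#' @param artifact_corr_mm Correlation length (mm) of those residue fields.
#' @param iodine_display_scale Iodine-map display units per mg/ml. The default
#'   of 100 makes one 25-unit gray bin correspond to 0.25 mg/ml.
#' @param t3d_weights Weights of the VM energies in the polyenergetic average;
#'   must sum to 1. Default uniform.
#' @param jitter_mm Magnitude bound (mm) of the repeat-segmentation centre
#'   displacement emulating an independent manual redraw.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 10L,
                        master_seed = 1L,
                        shape = c(128L, 128L, 40L),
                        spacing = c(0.7, 0.7, 1.5),
                        noise_sigma_vm = seq(25, 9, length.out = 9),
                        noise_sigma_t3d = 12,
                        noise_sigma_vnc = 15,
                        noise_sigma_iodine = 0.3,
                        iodine_display_scale = 100,
                        t3d_weights = rep(1 / 9, 9),
                        jitter_mm = 3,
                        artifact_sigma_vnc = 12,
                        artifact_sigma_t3d = 8,
                        artifact_corr_mm = 8) {
  if (n_patients < 2) {
    stop("n_patients must be >= 2: the ICC requires at least two targets")
  }
  if (length(shape) != 3L || any(shape < 8)) stop("shape must be 3 positive voxel counts")
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive lengths (mm)")
  if (length(noise_sigma_vm) != 9L || any(noise_sigma_vm < 0)) {
    stop("noise_sigma_vm must give one non-negative sigma per VM energy")
  }
  if (abs(sum(t3d_weights) - 1) > 1e-6 || length(t3d_weights) != 9L) {
    stop("t3d_weights must be 9 weights summing to 1")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      master_seed = as.integer(master_seed),
      shape = as.integer(shape),
      spacing = as.numeric(spacing),
      noise_sigma_vm = as.numeric(noise_sigma_vm),
      noise_sigma_t3d = noise_sigma_t3d,
      noise_sigma_vnc = noise_sigma_vnc,
      noise_sigma_iodine = noise_sigma_iodine,
      iodine_display_scale = iodine_display_scale,
      t3d_weights = as.numeric(t3d_weights),
      jitter_mm = jitter_mm,
      artifact_sigma_vnc = artifact_sigma_vnc,
      artifact_sigma_t3d = artifact_sigma_t3d,
      artifact_corr_mm = artifact_corr_mm
    ),
    class = "cohort_spec"
  )
}

# Smallest block extent (mm) able to host the 2 cm sphere plus the repeat
# jitter allowance on both sides.
.min_block_extent_mm <- function(jitter_mm) 20 + 2 * jitter_mm

# Axis-aligned tissue block layout: 2 columns (x) by 3 rows (y), full z with a
# one-voxel margin. Returns one row per tissue with inclusive voxel ranges.
.block_layout <- function(spec, tissues) {
  shape <- spec$shape
  spacing <- spec$spacing
  bx <- shape[1] %/% 2L
  by <- shape[2] %/% 3L
  blocks <- data.frame(
    tissue = tissues$tissue,
    x0 = integer(6), x1 = integer(6),
    y0 = integer(6), y1 = integer(6),
    z0 = integer(6), z1 = integer(6)
  )
  need <- .min_block_extent_mm(spec$jitter_mm)
  for (i in seq_len(6L)) {
    col <- (i - 1L) %% 2L
    row <- (i - 1L) %/% 2L
    blocks$x0[i] <- col * bx + 2L
    blocks$x1[i] <- (col + 1L) * bx - 1L
    blocks$y0[i] <- row * by + 2L
    blocks$y1[i] <- (row + 1L) * by - 1L
    blocks$z0[i] <- 2L
    blocks$z1[i] <- shape[3] - 1L
    ext <- c(
      (blocks$x1[i] - blocks$x0[i]) * spacing[1],
      (blocks$y1[i] - blocks$y0[i]) * spacing[2],
      (blocks$z1[i] - blocks$z0[i]) * spacing[3]
    )
    if (any(ext < need)) {
      stop(sprintf(
        "grid too small: block for tissue '%s' spans %.1f x %.1f x %.1f mm but %.1f mm is required per axis",
        blocks$tissue[i], ext[1], ext[2], ext[3], need
      ))
    }
  }
  blocks
}

# Stationary Gaussian random field on a grid: white noise smoothed by a
# separable Gaussian kernel (sigma = correlation length in voxels per axis),
# then standardized to zero mean / unit variance.
.gaussian_field <- function(dims, corr_len_mm, spacing) {
  x <- array(rnorm(prod(dims)), dim = dims)
  for (axis in 1:3) {
    sigma_vox <- corr_len_mm / spacing[axis]
    if (dims[axis] > 1 && sigma_vox > 0.3) {
      x <- .smooth_axis(x, sigma_vox, axis)
    }
  }
  s <- sd(x)
  if (s == 0) array(0, dim = dims) else (x - mean(x)) / s
}

# Gaussian smoothing along one axis with edge renormalization. The
# normalization profile depends only on the position along the axis, so it is
# computed once as a vector and recycled down the columns.
.smooth_axis <- function(a, sigma_vox, axis) {
  d <- dim(a)
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  w <- dnorm(seq(-r, r), sd = sigma_vox)
  w <- w / sum(w)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- d[axis]
  m <- matrix(ap, nrow = n)
  pad <- matrix(0, nrow = r, ncol = ncol(m))
  mp <- rbind(pad, m, pad)
  sm <- matrix(as.numeric(stats::filter(mp, w, sides = 2)), nrow = n + 2 * r)
  sm <- sm[(r + 1):(r + n), , drop = FALSE]
  ones <- c(rep(0, r), rep(1, n), rep(0, r))
  nm <- as.numeric(stats::filter(ones, w, sides = 2))[(r + 1):(r + n)]
  res <- array(sm / nm, dim = d[perm])
  aperm(res, order(perm))
}

#' Build the material volume of one phantom patient
#'
#' Lays out six axis-aligned tissue blocks on the grid and freezes, per
#' patient, a base attenuation map (tissue HU plus a Gaussian random texture
#' field with the tissue's correlation length) and an iodine concentration map
#' (mean uptake plus an independent field, clamped at zero). The anatomy is a
#' deterministic function of `patient_seed` and is shared by all reconstruction
#' channels of the patient.
#'
#' @param spec A [cohort_spec()].
#' @param tissues Tissue model table, see [default_tissues()].
#' @param patient_seed Integer seed fixing this patient's anatomy.
#' @return Object of class `material_volume` with fields `shape`, `spacing`,
#'   `label_map` (integer array, 0 = background, 1..6 = tissue index),
#'   `base_hu_map`, `iodine_map_mgml`, `patient_seed`, `tissues`, `blocks`.
#' @export
build_material_volume <- function(spec, tissues = default_tissues(), patient_seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!all(c("tissue", "hu_vnc", "hu_sigma_texture", "texture_correlation_length",
             "iodine_mgml", "iodine_sigma") %in% names(tissues)) ||
      nrow(tissues) != 6L) {
    stop("tissues must be a 6-row tissue model table")
  }
  if (any(tissues$iodine_mgml < 0) || any(tissues$texture_correlation_length <= 0)) {
    stop("tissue model invalid: iodine_mgml >= 0 and texture_correlation_length > 0 required")
  }
  blocks <- .block_layout(spec, tissues)
  shape <- spec$shape
  set.seed(patient_seed)
  label <- array(0L, dim = shape)
  base <- array(-1000, dim = shape)  # background behaves like air
  iod <- array(0, dim = shape)
  for (i in seq_len(6L)) {
    xs <- blocks$x0[i]:blocks$x1[i]
    ys <- blocks$y0[i]:blocks$y1[i]
    zs <- blocks$z0[i]:blocks$z1[i]
    bd <- c(length(xs), length(ys), length(zs))
    label[xs, ys, zs] <- i
    hu <- tissues$hu_vnc[i]
    if (tissues$hu_sigma_texture[i] > 0) {
      f <- .gaussian_field(bd, tissues$texture_correlation_length[i], spec$spacing)
      base[xs, ys, zs] <- hu + tissues$hu_sigma_texture[i] * f
    } else {
      base[xs, ys, zs] <- hu
    }
    if (tissues$iodine_mgml[i] > 0 || tissues$iodine_sigma[i] > 0) {
      g <- .gaussian_field(bd, tissues$texture_correlation_length[i], spec$spacing)
      iod[xs, ys, zs] <- pmax(0, tissues$iodine_mgml[i] + tissues$iodine_sigma[i] * g)
    }
  }
  structure(
    list(
      shape = shape, spacing = spec$spacing,
      label_map = label, base_hu_map = base, iodine_map_mgml = iod,
      patient_seed = as.integer(patient_seed),
      tissues = tissues, blocks = blocks
    ),
    class = "material_volume"
  )
}

#' Render one reconstruction channel from a material volume
#'
#' Applies the channel's intensity transform to the frozen anatomy and adds
#' independent Gaussian noise:
#' \itemize{
#'   \item `VM`: `base + iodine * enhancement(keV) + noise`
#'   \item `VNC`: `base + noise`
#'   \item `IODINE`: `iodine * iodine_scale + noise * iodine_scale`
#'   \item `T3D`: weighted average of the noiseless VM channels `+ noise`
#' }
#'
#' @param mv A [build_material_volume()] result.
#' @param kind One of `"VM"`, `"T3D"`, `"VNC"`, `"IODINE"`.
#' @param keV VM energy in keV; required iff `kind == "VM"` and must lie on the
#'   curve's energy grid.
#' @param curve Iodine enhancement curve, see [default_iodine_curve()].
#' @param noise_seed Integer seed of this channel's noise and artifact fields.
#' @param noise_sigma Noise standard deviation, in HU (VM/T3D/VNC) or mg/ml
#'   (iodine map, scaled to display units internally).
#' @param iodine_scale Iodine-map display units per mg/ml.
#' @param t3d_weights VM weights of the polyenergetic average.
#' @param artifact_sigma Amplitude (HU) of a channel-specific spatially
#'   correlated reconstruction residue added before the white noise; models
#'   decomposition/beam-hardening artifacts of derived channels (VNC, T3D).
#' @param artifact_corr_mm Correlation length of the residue field.
#' @return Numeric array with the volume's shape.
#' @export
render_channel <- function(mv, kind, keV = NULL, curve = default_iodine_curve(),
                           noise_seed = 1L, noise_sigma = 0,
                           iodine_scale = 100, t3d_weights = rep(1 / 9, 9),
                           artifact_sigma = 0, artifact_corr_mm = 8) {
  stopifnot(inherits(mv, "material_volume"))
  kind <- match.arg(kind, c("VM", "T3D", "VNC", "IODINE"))
  if (any(diff(curve$enhancement_per_mgml) >= 0) || any(curve$enhancement_per_mgml <= 0)) {
    stop("iodine curve must be positive and strictly decreasing in energy")
  }
  img <- switch(kind,
    VM = {
      if (is.null(keV)) stop("keV is required for VM channels")
      j <- match(keV, curve$energies)
      if (is.na(j)) {
        stop(sprintf("unsupported energy: %s keV is not on the curve grid (%s)",
                     keV, paste(curve$energies, collapse = ", ")))
      }
      mv$base_hu_map + mv$iodine_map_mgml * curve$enhancement_per_mgml[j]
    },
    VNC = mv$base_hu_map,
    IODINE = mv$iodine_map_mgml * iodine_scale,
    T3D = {
      enh <- sum(t3d_weights * curve$enhancement_per_mgml)
      mv$base_hu_map + mv$iodine_map_mgml * enh
    }
  )
  sigma <- if (kind == "IODINE") noise_sigma * iodine_scale else noise_sigma
  if (sigma > 0 || artifact_sigma > 0) set.seed(noise_seed)
  if (artifact_sigma > 0) {
    img <- img + artifact_sigma * .gaussian_field(mv$shape, artifact_corr_mm, mv$spacing)
  }
  if (sigma > 0) {
    img <- img + array(rnorm(prod(mv$shape), sd = sigma), dim = mv$shape)
  }
  img
}

# Per-channel noise sigma lookup for a cohort spec.
.channel_noise_sigma <- function(spec, channel_id) {
  if (startsWith(channel_id, "VM")) {
    keV <- as.integer(sub("VM", "", channel_id))
    spec$noise_sigma_vm[match(keV, VM_ENERGIES)]
  } else {
    switch(channel_id,
      T3D = spec$noise_sigma_t3d,
      VNC = spec$noise_sigma_vnc,
      IODINE = spec$noise_sigma_iodine
    )
  }
}

#' Generate the 12-channel reconstruction stack of one patient
#'
#' @param spec A [cohort_spec()].
#' @param patient_index Patient number (1-based); fixes the anatomy and noise
#'   seeds through the spec's master seed.
#' @param tissues,curve Tissue models and iodine curve.
#' @return Object of class `reconstruction_stack`: `patient_id`, `spacing`,
#'   `channels` (named list of 12 arrays in canonical order), `channel_info`
#'   (data.frame: id, kind, keV, noise_sigma, noise_seed), and the underlying
#'   `material` volume.
#' @export
generate_patient_stack <- function(spec, patient_index,
                                   tissues = default_tissues(),
                                   curve = default_iodine_curve()) {
  stopifnot(inherits(spec, "cohort_spec"))
  pseed <- derive_seed(spec$master_seed, 1L, patient_index)
  mv <- build_material_volume(spec, tissues, pseed)
  info <- data.frame(
    id = CHANNEL_IDS,
    kind = c(rep("VM", 9L), "T3D", "VNC", "IODINE"),
    keV = c(VM_ENERGIES, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  info$noise_sigma <- vapply(info$id, function(ch) .channel_noise_sigma(spec, ch), 0)
  info$noise_seed <- vapply(seq_len(nrow(info)), function(c_idx) {
    derive_seed(spec$master_seed, 2L, patient_index, c_idx)
  }, 0L)
  info$artifact_sigma <- ifelse(info$id == "VNC", spec$artifact_sigma_vnc,
                                ifelse(info$id == "T3D", spec$artifact_sigma_t3d, 0))
  channels <- vector("list", nrow(info))
  names(channels) <- info$id
  for (c_idx in seq_len(nrow(info))) {
    channels[[c_idx]] <- render_channel(
      mv,
      kind = info$kind[c_idx],
      keV = if (is.na(info$keV[c_idx])) NULL else info$keV[c_idx],
      curve = curve,
      noise_seed = info$noise_seed[c_idx],
      noise_sigma = info$noise_sigma[c_idx],
      iodine_scale = spec$iodine_display_scale,
      t3d_weights = spec$t3d_weights,
      artifact_sigma = info$artifact_sigma[c_idx],
      artifact_corr_mm = spec$artifact_corr_mm
    )
  }
  structure(
    list(
      patient_id = sprintf("P%02d", patient_index),
      spacing = spec$spacing,
      channels = channels,
      channel_info = info,
      material = mv
    ),
    class = "reconstruction_stack"
  )
}

#' Generate the full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @param tissues,curve Tissue models and iodine curve.
#' @return List with `stacks` (one [generate_patient_stack()] result per
#'   patient) and `manifest`, a fully reproducible record of the spec, tissue
#'   parameters, iodine curve and every seed used.
#' @export
generate_cohort <- function(spec, tissues = default_tissues(),
                            curve = default_iodine_curve()) {
  stopifnot(inherits(spec, "cohort_spec"))
  stacks <- lapply(seq_len(spec$n_patients), function(i) {
    generate_patient_stack(spec, i, tissues, curve)
  })
  manifest <- cohort_manifest(spec, tissues, curve)
  list(stacks = stacks, manifest = manifest)
}

#' Cohort manifest
#'
#' Deterministic record of everything needed to regenerate a cohort
#' bit-identically: spec fields, tissue parameters, iodine curve, and the
#' derived per-patient / per-channel seeds.
#'
#' @inheritParams generate_cohort
#' @return Nested list, serializable to JSON.
#' @export
cohort_manifest <- function(spec, tissues = default_tissues(),
                            curve = default_iodine_curve()) {
  patients <- lapply(seq_len(spec$n_patients), function(i) {
    list(
      patient_id = sprintf("P%02d", i),
      patient_seed = derive_seed(spec$master_seed, 1L, i),
      noise_seeds = stats::setNames(
        vapply(seq_along(CHANNEL_IDS), function(c_idx) {
          derive_seed(spec$master_seed, 2L, i, c_idx)
        }, 0L),
        CHANNEL_IDS
      )
    )
  })
  list(
    spec = unclass(spec),
    tissues = tissues,
    iodine_curve = curve,
    channels = CHANNEL_IDS,
    patients = patients
  )
}
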