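# NIfTI volume I/O and YAML pipeline configuration.

#' Read / write a NIfTI volume
#'
#' Round-trips values and voxel spacing to float32 precision. Volumes are plain
#' numeric arrays with spacing carried alongside; phantom axes are grid-aligned
#' so no origin/direction handling is applied.
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return `read_volume()`: list with `image` (numeric array) and `spacing`
#'   (mm per axis).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  list(image = array(as.numeric(img), dim = dim(img)), spacing = spacing)
}

#' @rdname read_volume
#' @param image Numeric array.
#' @param spacing Voxel spacing in mm, length 3.
#' @export
write_volume <- function(image, spacing, path) {
  nim <- RNifti::asNifti(image)
  RNifti::pixdim(nim) <- spacing
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' Check that an image and a mask share geometry
#'
#' @param image Numeric array.
#' @param mask A `voxel_mask` (or a second array).
#' @param spacing,mask_spacing Optional spacings to compare.
#' @return Invisibly `TRUE`; raises a geometry error otherwise.
#' @export
check_geometry <- function(image, mask, spacing = NULL, mask_spacing = NULL) {
  mshape <- if (inherits(mask, "voxel_mask")) mask$shape else dim(mask)
  if (!identical(as.integer(dim(image)), as.integer(mshape))) {
    stop(sprintf("geometry error: image is %s but mask is %s",
                 paste(dim(image), collapse = "x"),
                 paste(mshape, collapse = "x")))
  }
  if (!is.null(spacing) && !is.null(mask_spacing) &&
      any(abs(spacing - mask_spacing) > 1e-5)) {
    stop("geometry error: image and mask spacing differ")
  }
  invisible(TRUE)
}

#' Write a cohort's volumes to NIfTI
#'
#' One volume per channel (`{patient}_{channel}.nii.gz`), one segmentation
#' label map per patient plus a CSV legend, and the JSON manifest.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory.
#' @param tissues,curve Tissue models and iodine curve.
#' @param verbose Log per-patient progress.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(spec, dir, tissues = default_tissues(),
                         curve = default_iodine_curve(), verbose = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(spec$n_patients)) {
    stack <- generate_patient_stack(spec, i, tissues, curve)
    for (ch in names(stack$channels)) {
      write_volume(stack$channels[[ch]], spec$spacing,
                   file.path(dir, sprintf("%s_%s.nii.gz", stack$patient_id, ch)))
    }
    segs <- place_segmentations(stack$material, spec$jitter_mm,
                                seed = derive_seed(spec$master_seed, 3L, i))
    lab <- masks_to_labelmap(segs, spec$shape, spec$spacing)
    write_volume(lab$label_map, spec$spacing,
                 file.path(dir, sprintf("%s_masks.nii.gz", stack$patient_id)))
    write.csv(lab$legend,
              file.path(dir, sprintf("%s_mask_legend.csv", stack$patient_id)),
              row.names = FALSE)
    if (verbose) message(sprintf("wrote %s", stack$patient_id))
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(cohort_manifest(spec, tissues, curve), mpath,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mpath)
}

# Known configuration keys, mirroring cohort_spec + extraction + criteria.
.config_keys <- function() {
  c("n_patients", "master_seed", "shape", "spacing", "noise_sigma_vm",
    "noise_sigma_t3d", "noise_sigma_vnc", "noise_sigma_iodine",
    "iodine_display_scale", "t3d_weights", "jitter_mm",
    "artifact_sigma_vnc", "artifact_sigma_t3d", "artifact_corr_mm", "bin_width",
    "icc_threshold", "min_organs_icc", "ccc_threshold", "min_organs_ccc",
    "min_vm_channels", "ccc_nesting", "out_dir", "write_volumes")
}

#' Pipeline configuration
#'
#' Bundles the cohort spec, extraction settings, screening criteria and output
#' directory; losslessly serializable to YAML with unknown keys rejected on
#' read.
#'
#' @param spec A [cohort_spec()].
#' @param bin_width Discretization bin width.
#' @param criteria A [stability_criteria()].
#' @param out_dir Output directory of [run_pipeline()].
#' @param write_volumes Also write the NIfTI volumes (off by default; the CSV
#'   tables are the inter-stage format).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = cohort_spec(), bin_width = 25,
                            criteria = stability_criteria(),
                            out_dir = "pcctstab_run", write_volumes = FALSE) {
  structure(
    list(spec = spec, bin_width = bin_width, criteria = criteria,
         out_dir = out_dir, write_volumes = write_volumes),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config()` returns the `pipeline_config`; unknown keys raise an
#'   error.
#' @export
write_config <- function(config, path) {
  flat <- c(unclass(config$spec),
            list(bin_width = config$bin_width),
            unclass(config$criteria),
            list(out_dir = config$out_dir, write_volumes = config$write_volumes))
  yaml::write_yaml(flat, path, precision = 12L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  flat <- yaml::read_yaml(path)
  unknown <- setdiff(names(flat), .config_keys())
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  }
  spec <- cohort_spec(
    n_patients = flat$n_patients, master_seed = flat$master_seed,
    shape = unlist(flat$shape), spacing = unlist(flat$spacing),
    noise_sigma_vm = unlist(flat$noise_sigma_vm),
    noise_sigma_t3d = flat$noise_sigma_t3d, noise_sigma_vnc = flat$noise_sigma_vnc,
    noise_sigma_iodine = flat$noise_sigma_iodine,
    iodine_display_scale = flat$iodine_display_scale,
    t3d_weights = unlist(flat$t3d_weights), jitter_mm = flat$jitter_mm,
    artifact_sigma_vnc = flat$artifact_sigma_vnc,
    artifact_sigma_t3d = flat$artifact_sigma_t3d,
    artifact_corr_mm = flat$artifact_corr_mm
  )
  criteria <- stability_criteria(
    icc_threshold = flat$icc_threshold, min_organs_icc = flat$min_organs_icc,
    ccc_threshold = flat$ccc_threshold, min_organs_ccc = flat$min_organs_ccc,
    min_vm_channels = flat$min_vm_channels, ccc_nesting = flat$ccc_nesting
  )
  pipeline_config(spec = spec, bin_width = flat$bin_width, criteria = criteria,
                  out_dir = flat$out_dir, write_volumes = isTRUE(flat$write_volumes))
}
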