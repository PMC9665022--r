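# The long-format feature table is the pipeline's central exchange object:
# one row per (patient, organ, segmentation mode, repeat, channel, feature).

#' Extract the feature table of one patient
#'
#' Computes the 93-feature vector of every segmentation in every reconstruction
#' channel of a patient's stack. No resampling or interpolation is applied.
#'
#' @param stack A [generate_patient_stack()] result (or any list with the same
#'   fields built from read volumes).
#' @param segs Segmentation plan, see [place_segmentations()].
#' @param bin_width Discretization bin width.
#' @return `data.table` with columns `patient`, `organ`, `dim`, `diameter_cm`,
#'   `repeat_id`, `channel`, `channel_kind`, `keV`, `feature`, `value`.
#' @export
extract_features <- function(stack, segs, bin_width = 25) {
  stopifnot(is.data.frame(segs), nrow(segs) >= 1L)
  shape <- dim(stack$channels[[1]])
  for (ch in stack$channels) {
    if (!identical(dim(ch), shape)) {
      stop("geometry error: reconstruction channels differ in shape")
    }
  }
  info <- stack$channel_info
  fnames <- feature_names()
  nfeat <- length(fnames)
  ncomb <- nrow(segs) * nrow(info)
  vals <- matrix(NA_real_, nfeat, ncomb)
  k <- 0L
  for (s in seq_len(nrow(segs))) {
    m <- build_mask(segs[s, ], shape, stack$spacing)
    for (c_idx in seq_len(nrow(info))) {
      k <- k + 1L
      vals[, k] <- compute_features(stack$channels[[c_idx]], m, bin_width)
    }
  }
  comb_seg <- rep(seq_len(nrow(segs)), each = nrow(info))
  comb_ch <- rep(seq_len(nrow(info)), times = nrow(segs))
  data.table::data.table(
    patient = stack$patient_id,
    organ = rep(segs$organ[comb_seg], each = nfeat),
    dim = rep(segs$dim[comb_seg], each = nfeat),
    diameter_cm = rep(segs$diameter_cm[comb_seg], each = nfeat),
    repeat_id = rep(segs$repeat_id[comb_seg], each = nfeat),
    channel = rep(info$id[comb_ch], each = nfeat),
    channel_kind = rep(info$kind[comb_ch], each = nfeat),
    keV = rep(info$keV[comb_ch], each = nfeat),
    feature = rep(fnames, times = ncomb),
    value = as.vector(vals)
  )
}

#' Simulate and extract the full cohort feature table
#'
#' Streams over patients (one 12-channel stack in memory at a time): generates
#' the anatomy, places the 48-segmentation plan, extracts all features, and
#' binds the per-patient tables.
#'
#' @param spec A [cohort_spec()].
#' @param tissues,curve Tissue models and iodine curve.
#' @param bin_width Discretization bin width.
#' @param verbose Log per-patient progress via `message()`.
#' @return List with `features` (the long `data.table`), `segmentations`
#'   (per-patient plans) and `manifest`.
#' @export
extract_cohort_features <- function(spec, tissues = default_tissues(),
                                    curve = default_iodine_curve(),
                                    bin_width = 25, verbose = FALSE) {
  tabs <- vector("list", spec$n_patients)
  plans <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    stack <- generate_patient_stack(spec, i, tissues, curve)
    segs <- place_segmentations(stack$material, spec$jitter_mm,
                                seed = derive_seed(spec$master_seed, 3L, i))
    tabs[[i]] <- extract_features(stack, segs, bin_width)
    segs$patient <- stack$patient_id
    plans[[i]] <- segs
    if (verbose) {
      message(sprintf("patient %s: %d segmentations, %d feature values",
                      stack$patient_id, nrow(segs), nrow(tabs[[i]])))
    }
  }
  list(
    features = data.table::rbindlist(tabs),
    segmentations = do.call(rbind, plans),
    manifest = cohort_manifest(spec, tissues, curve)
  )
}

#' Write / read a feature table as CSV
#'
#' CSV is the auditable inter-stage format of the pipeline.
#'
#' @param ft Feature table (`data.table`).
#' @param path File path.
#' @return `read_feature_table()` returns the `data.table`.
#' @export
write_feature_table <- function(ft, path) {
  data.table::fwrite(ft, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ft <- data.table::fread(path)
  req <- c("patient", "organ", "dim", "diameter_cm", "repeat_id",
           "channel", "feature", "value")
  miss <- setdiff(req, names(ft))
  if (length(miss)) {
    stop(sprintf("feature table is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  ft
}
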