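#' Simulate a feature table with a planted stable subset
#'
#' Generative model of the long-format feature table used to validate the
#' two-stage screen end to end: every (feature, organ) pair has a base level
#' and i.i.d. standard-normal patient effects; features in `stable_features`
#' are channel-invariant and resegmentation-robust (only a small measurement
#' noise on top of the patient effect), all other features receive strong
#' channel-by-target interaction noise that destroys both the ICC across
#' channels and the repeat-to-repeat concordance. Smaller segmentation modes
#' get proportionally noisier values, so the 3D-2cm mode wins the mode
#' comparison by construction.
#'
#' @param stable_features Character vector of planted stable feature names
#'   (subset of `features`).
#' @param features Feature universe (default the 93-name bank).
#' @param organs Organ labels.
#' @param n_patients Number of patients.
#' @param channels Channel ids (default the 12 reconstruction channels).
#' @param modes Segmentation modes to emulate.
#' @param stable_noise_sd Measurement noise of stable features (3D-2cm scale).
#' @param unstable_noise_sd Channel-interaction noise of unstable features.
#' @param unstable_signal Attenuation of the patient effect in unstable
#'   features (keeps their ICC near zero).
#' @param seed Integer seed.
#' @return Long `data.table` in the [extract_features()] column layout.
#' @export
simulate_feature_table <- function(stable_features,
                                   features = feature_names(),
                                   organs = default_tissues()$tissue,
                                   n_patients = 10L,
                                   channels = CHANNEL_IDS,
                                   modes = SEG_MODES,
                                   stable_noise_sd = 0.05,
                                   unstable_noise_sd = 1.0,
                                   unstable_signal = 0.3,
                                   seed = 1L) {
  stopifnot(all(stable_features %in% features))
  set.seed(seed)
  mode_noise <- c("2D-1cm" = 2.0, "2D-2cm" = 1.5, "3D-1cm" = 1.3, "3D-2cm" = 1.0)
  grid <- data.table::CJ(
    feature = features, organ = organs, patient = sprintf("P%02d", seq_len(n_patients)),
    repeat_id = 1:2, channel = channels, mode = modes, sorted = FALSE
  )
  base <- data.table::CJ(feature = features, organ = organs, sorted = FALSE)
  base[, base_level := runif(.N, -1, 1) * 5]
  pat <- data.table::CJ(feature = features, organ = organs,
                        patient = sprintf("P%02d", seq_len(n_patients)), sorted = FALSE)
  pat[, patient_effect := rnorm(.N)]
  grid <- merge(grid, base, by = c("feature", "organ"), sort = FALSE)
  grid <- merge(grid, pat, by = c("feature", "organ", "patient"), sort = FALSE)
  grid[, stable := feature %in% stable_features]
  grid[, mnoise := mode_noise[mode]]
  n <- nrow(grid)
  eps_meas <- rnorm(n)
  grid[, value := ifelse(
    stable,
    base_level + patient_effect + stable_noise_sd * mnoise * eps_meas,
    base_level + unstable_signal * patient_effect +
      unstable_noise_sd * mnoise * eps_meas
  )]
  grid[, `:=`(
    dim = substr(mode, 1, 2),
    diameter_cm = as.numeric(substr(mode, 4, 4)),
    channel_kind = ifelse(startsWith(channel, "VM"), "VM", channel),
    keV = ifelse(startsWith(channel, "VM"),
                 suppressWarnings(as.integer(sub("VM", "", channel))), NA_integer_)
  )]
  grid[, c("base_level", "patient_effect", "stable", "mnoise", "mode") := NULL]
  data.table::setcolorder(grid, c("patient", "organ", "dim", "diameter_cm",
                                  "repeat_id", "channel", "channel_kind", "keV",
                                  "feature", "value"))
  grid[]
}
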