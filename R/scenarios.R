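# Named study scenarios: the fixed synthetic-data conditions under which
# the pipeline's statistical properties (calibration, specificity, power)
# are evaluated. Each returns a sim_config; sizes and effect parameters are
# design choices documented in the methods vignette and are not meant to be
# tuned per run.

#' Study scenarios for pipeline validation
#'
#' * `scenario_oracle()`: tiny noise-free instance (6 repeated-music
#'   scenes, 2 songs, 3 participants per group) on which the optimized
#'   pipeline must reproduce the straight-line reference implementation
#'   exactly. Encoding spread is kept positive so scene patterns differ and
#'   the permutation null is non-degenerate.
#' * `scenario_null()`: exchangeable null (no reactivation, no
#'   reactivation-recall channel) at full study size, used for false-positive
#'   calibration of the remembered-versus-forgotten test and of the
#'   permutation z pool; also serves the baseline-correction check since
#'   both groups are generated identically when `react_gain = 0`.
#' * `scenario_planted()`: reactivation planted in parcels 1-5 of 50 with
#'   the reactivation-recall channel switched on; the gain is calibrated so
#'   the raw pair-level correlation uplift in affected parcels is ~0.15.
#' * `scenario_encoding_only()`: recall driven purely by encoding strength
#'   (`c = 0`) while reactivation amplitude is coupled to encoding, so the
#'   reactivation-recall association is entirely a third-variable artifact
#'   that ISC residualization should remove.
#' * `scenario_encoding_plus_react()`: same, plus an independent
#'   reactivation-to-recall channel (`c > 0`) that must survive
#'   residualization.
#'
#' @param seed integer seed for the generator.
#' @param n_parcels number of parcels (defaults are the scenario's study
#'   size).
#' @return a [sim_config()].
#' @export
scenario_oracle <- function(seed = 1) {
  sim_config(
    n_per_group = 3, n_parcels = 2, voxels_per_parcel = 12,
    scenes = sim_scene_table(n_songs = 2, n_occurrences = 2,
                             scenes_per_block = c(2, 1)),
    signature_gain = 1, encoding_sd = 0.4, react_gain = 0.5,
    react_sd = 0.5, noise_sd = 0, recall_intercept = 0, seed = seed
  )
}

#' @rdname scenario_oracle
#' @export
scenario_null <- function(seed = 1, n_parcels = 500) {
  sim_config(
    n_per_group = 24, n_parcels = n_parcels, voxels_per_parcel = 12,
    scenes = sim_scene_table(n_songs = 2, n_occurrences = 2,
                             scenes_per_block = 3),
    react_gain = 0, recall_c_react = 0,
    recall_b_encoding = 1, recall_intercept = -1, seed = seed
  )
}

#' @rdname scenario_oracle
#' @export
scenario_planted <- function(seed = 1, n_parcels = 50) {
  g <- 0.9; cc <- 3
  sim_config(
    n_per_group = 24, n_parcels = n_parcels, voxels_per_parcel = 40,
    scenes = sim_scene_table(n_songs = 2, n_occurrences = 2,
                             scenes_per_block = 5),
    react_gain = g, react_sd = 1, react_encoding_coupling = 1,
    affected_parcels = 1:5,
    recall_b_encoding = 1, recall_c_react = cc,
    recall_intercept = -(cc * g + 1), seed = seed
  )
}

#' @rdname scenario_oracle
#' @param with_react_channel include the independent reactivation-to-recall
#'   channel (`c > 0`)?
#' @export
scenario_encoding_only <- function(seed = 1, n_parcels = 20,
                                   with_react_channel = FALSE) {
  g <- 0.9; cc <- if (with_react_channel) 3 else 0
  sim_config(
    n_per_group = 24, n_parcels = n_parcels, voxels_per_parcel = 40,
    scenes = sim_scene_table(n_songs = 6, n_occurrences = 2,
                             scenes_per_block = 10),
    react_gain = g, react_sd = if (with_react_channel) 0.75 else 0.3,
    react_encoding_coupling = 1, encoding_sd = 0.5,
    affected_parcels = 1:5,
    recall_b_encoding = 2, recall_c_react = cc,
    recall_intercept = -(2 + cc * g), seed = seed
  )
}

#' @rdname scenario_oracle
#' @export
scenario_encoding_plus_react <- function(seed = 1, n_parcels = 20) {
  scenario_encoding_only(seed, n_parcels, with_react_channel = TRUE)
}
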