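# Small fixtures shared across test files; everything is built in code.

# 6 scenes, one song repeated with a gap, one song in a single run.
toy_scenes <- function() {
  scene_table(1:6, (0:5) * 10, (1:6) * 10,
              c("a", "a", NA, "b", "a", "b"))
}

# scene table used by pattern tests: 3 scenes tiling [0, 9) seconds
tiling_scenes <- function() {
  scene_table(1:3, c(0, 3, 6), c(3, 6, 9), c("a", NA, "a"))
}

quick_dataset <- function(seed = 1, n_per_group = 4, n_parcels = 2,
                          noise_sd = 0.5, react_gain = 0, ...) {
  simulate_dataset(sim_config(
    n_per_group = n_per_group, n_parcels = n_parcels,
    voxels_per_parcel = 8,
    scenes = sim_scene_table(n_songs = 2, n_occurrences = 2,
                             scenes_per_block = 2),
    noise_sd = noise_sd, react_gain = react_gain, seed = seed, ...
  ))
}

# deterministic per-participant score tibble over given scenes/parcels
score_grid <- function(participants, scenes, parcels, values) {
  g <- tidyr::expand_grid(participant_id = participants,
                          parcel_id = parcels, scene_id = scenes)
  g$z <- values
  g
}
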