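# Demonstration pipeline configuration for inst/scripts/run-pipeline.R:
# a small two-group study with reactivation planted in the default-mode
# parcels and a reactivation-to-recall channel.
n_perm: 200
seed: 21
q_threshold: 0.1
screen_p: 0.05
test: paired
sim:
  n_per_group: 12
  n_parcels: 34
  voxels_per_parcel: 24
  react_gain: 0.9
  react_sd: 1.0
  recall_c_react: 3
  recall_intercept: -3.7
  affected_parcels: [14, 15, 16, 31, 32, 33]
  seed: 20
  scene_layout:
    n_songs: 2
    n_occurrences: 2
    scenes_per_block: 4
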