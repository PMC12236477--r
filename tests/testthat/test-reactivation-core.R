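test_that("raw scores are Pearson correlations across voxels", {
  # hand-computed Pearson for a 4-voxel toy
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(cross_cor(cbind(x), cbind(y))[1, 1]), r_hand)
  expect_equal(unname(cross_cor(cbind(x), cbind(x))[1, 1]), 1)
  expect_equal(unname(cross_cor(cbind(x), cbind(-x))[1, 1]), -1)
  expect_error(cross_cor(cbind(c(1, 1, 1)), cbind(c(1, 2, 3))),
               "zero-variance")
})

test_that("leave-one-out baseline equals a hand-built oracle", {
  # 3 no-music participants, 2 voxels, 1 mega (scene 3), 1 earlier scene
  sc <- scene_table(1:3, c(0, 2, 4), c(2, 4, 6), c("a", NA, "a"))
  # scene patterns chosen directly (V x S x N x K)
  pats <- array(NA_real_, c(2, 2, 3, 1),
                dimnames = list(NULL, c(1, 3), c("n1", "n2", "n3"), NULL))
  set.seed(5)
  pats[] <- rnorm(length(pats))
  pp <- structure(list(
    pool = repeated_music_scenes(sc),
    megas = build_megascenes(sc),
    pairs = enumerate_pairs(sc),
    parcel_ids = 1L,
    groups = list(music = pats, nomusic = pats)
  ), class = "pool_patterns")
  r <- reactivation_scores(pp, n_perm = 100, seed = 2)
  # oracle: mega pattern is scene 3's pattern; baseline over held-out j
  bl_oracle <- mean(sapply(1:3, function(j) {
    loo <- rowMeans(pats[, 1, setdiff(1:3, j), 1])
    cor(pats[, 2, j, 1], loo)
  }))
  raw_oracle <- sapply(1:3, function(p) {
    cor(pats[, 2, p, 1], rowMeans(pats[, 1, , 1]))
  })
  expect_equal(r$contrast, raw_oracle - bl_oracle, tolerance = 1e-12)
})

test_that("too few no-music participants for a baseline errors", {
  ds <- quick_dataset(n_per_group = 2)
  expect_error(reactivation_scores(pool_patterns(ds), n_perm = 100, seed = 1),
               ">= 3 no-music")
  ds3 <- quick_dataset(n_per_group = 3)
  expect_error(
    reactivation_scores(pool_patterns(ds3), n_perm = 100, seed = 1,
                        mode = "nomusic_control"),
    ">= 4 no-music"
  )
})

test_that("permutation z-scores follow their definition", {
  # engineered contrast matrix: one cueing mega, pool of 4 scenes
  geom <- list(S = 4, M = 1, m_idx = 1L, s_idx = 2L,
               earlier_scene = 10L, cued = 10L,
               agg = matrix(1, 1, 1), n_pairs_per_scene = 1L)
  D <- matrix(c(1, 2, 3, 4), 1, 4)
  perms <- rbind(c(1, 2, 3, 4), c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 4, 1, 2))
  # null draws for the pair are D[1, perms[, 2]] = 2, 1, 3, 4
  z <- reverie:::permutation_z_cell(D, geom, perms)
  expect_equal(z, (2 - mean(c(2, 1, 3, 4))) / sd(c(2, 1, 3, 4)))
  # true value equal to the null mean gives z = 0
  D0 <- matrix(c(3, 2.5, 2, 2.5), 1, 4)
  z0 <- reverie:::permutation_z_cell(D0, geom, perms)
  expect_equal(z0, 0)
  # degenerate null errors
  expect_error(
    reverie:::permutation_z_cell(matrix(1, 1, 4), geom, perms),
    "degenerate"
  )
})

test_that("n_perm below 100 is rejected", {
  ds <- quick_dataset()
  expect_error(reactivation_scores(pool_patterns(ds), n_perm = 50, seed = 1),
               "n_perm")
})

test_that("pipeline equals the straight-line reference implementation", {
  ds <- simulate_dataset(scenario_oracle(13))
  a <- reactivation_scores(pool_patterns(ds), n_perm = 150, seed = 4)
  b <- reference_reactivation_scores(ds, n_perm = 150, seed = 4)
  m <- dplyr::inner_join(a, b,
                         by = c("participant_id", "parcel_id", "scene_id"))
  expect_equal(nrow(m), nrow(a))
  expect_lt(max(abs(m$z.x - m$z.y)), 1e-10)
  expect_lt(max(abs(m$raw.x - m$raw.y)), 1e-10)
  expect_lt(max(abs(m$contrast.x - m$contrast.y)), 1e-10)
  # and for the within-group control variant
  cfg <- sim_config(n_per_group = 4, n_parcels = 2, voxels_per_parcel = 10,
                    scenes = sim_scene_table(2, 2, c(2, 1)),
                    encoding_sd = 0.4, noise_sd = 0.5, seed = 9)
  ds2 <- simulate_dataset(cfg)
  a2 <- reactivation_scores(pool_patterns(ds2), n_perm = 120, seed = 4,
                            mode = "nomusic_control")
  b2 <- reference_reactivation_scores(ds2, n_perm = 120, seed = 4,
                                      mode = "nomusic_control")
  m2 <- dplyr::inner_join(a2, b2,
                          by = c("participant_id", "parcel_id", "scene_id"))
  expect_lt(max(abs(m2$z.x - m2$z.y)), 1e-10)
})

test_that("scores carry the pairing structure", {
  ds <- quick_dataset(seed = 6)
  r <- reactivation_scores(pool_patterns(ds), n_perm = 100, seed = 1)
  pairs <- enumerate_pairs(ds$scenes)
  expect_setequal(unique(r$scene_id), unique(pairs$earlier_scene))
  expect_true(all(r$n_pairs >= 1))
  expect_true(all(abs(r$raw) <= 1))
  expect_true(all(is.finite(r$z)))
})
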