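test_that("scene table validation enforces ordering and disjointness", {
  expect_s3_class(toy_scenes(), "scene_table")
  expect_error(scene_table(1:2, c(0, 5), c(10, 15), NA), "overlap")
  expect_error(scene_table(1:2, c(0, 10), c(0, 20), NA), "start_s >= end_s")
  expect_error(scene_table(c(1, 1), c(0, 10), c(10, 20), NA), "duplicated")
  expect_error(scene_table(1:2, c(10, 0), c(20, 10), NA), "temporal order")
})

test_that("repeated songs are songs with >= 2 occurrence blocks", {
  sc <- toy_scenes()
  # "a" occurs in blocks {1,2} and {5}; "b" in {4} and {6}
  expect_equal(repeated_songs(sc), c("a", "b"))
  # one single-block song is not repeated
  sc2 <- scene_table(1:3, c(0, 10, 20), c(10, 20, 30), c("a", "a", NA))
  expect_equal(repeated_songs(sc2), character(0))
  expect_equal(nrow(repeated_music_scenes(sc2)), 0)
})

test_that("consensus boundary density peaks where raters agree", {
  # a lone boundary yields a single consensus peak at its location
  out <- consensus_boundaries(list(10), sigma_s = 3, percentile = 90)
  expect_length(out, 1)
  expect_equal(out, 10, tolerance = 0.05)

  # 8 raters near 100 s beat a stray boundary at 300 s from one rater
  set.seed(42)
  raters <- c(lapply(1:8, function(i) 100 + runif(1, -0.5, 0.5)),
              list(300))
  out <- consensus_boundaries(raters, sigma_s = 3, percentile = 90,
                              grid_step_s = 0.1)
  expect_true(any(abs(out - 100) < 1))
  expect_false(any(abs(out - 300) < 5))

  # invariant to rater ordering
  out2 <- consensus_boundaries(rev(raters), sigma_s = 3, percentile = 90,
                               grid_step_s = 0.1)
  expect_equal(out, out2)
})

test_that("consensus boundary edge cases error or return empty", {
  expect_equal(consensus_boundaries(list(numeric(0), numeric(0))),
               numeric(0))
  expect_error(consensus_boundaries(list()), "rater")
  expect_error(consensus_boundaries(list(c(1, NA))), "non-finite")
  expect_error(consensus_boundaries(list(1), percentile = 101), "percentile")
})

test_that("snap rule keeps confirmed boundaries and merges the rest", {
  sc <- scene_table(1:3, c(0, 10, 20), c(10, 20, 30), NA)
  # consensus confirms the boundary at 10 (within 3 s) but not at 20
  out <- snap_scene_boundaries(sc, consensus = c(11), snap_tolerance_s = 3)
  expect_equal(nrow(out), 2)
  expect_equal(out$start_s, c(0, 10))
  expect_equal(out$end_s, c(10, 30))
  # no consensus at all collapses everything into one scene
  out2 <- snap_scene_boundaries(sc, consensus = numeric(0))
  expect_equal(nrow(out2), 1)
  # all boundaries confirmed leaves the table unchanged
  out3 <- snap_scene_boundaries(sc, consensus = c(10, 20))
  expect_equal(out3$end_s, sc$end_s)
})

test_that("recall labelling marks any labelled scene as remembered", {
  sc <- toy_scenes()
  utt <- tibble::tibble(
    participant_id = c("p1", "p1", "p2"),
    utterance_id = 1:3,
    scene_ids = list(7L[0], c(3L, 4L), 1L)
  )
  utt$scene_ids[[1]] <- 2L
  out <- label_recall(utt, sc, participants = c("p1", "p2", "p3"))
  expect_equal(nrow(out), 3 * 6)  # participants x scenes
  get <- function(p, s) out$remembered[out$participant_id == p &
                                         out$scene_id == s]
  # multi-scene utterance marks both scenes
  expect_true(get("p1", 3) && get("p1", 4))
  expect_true(get("p1", 2))
  expect_false(get("p1", 1))
  # participant with zero utterances forgets everything
  expect_false(any(out$remembered[out$participant_id == "p3"]))
  # unknown scene id errors with the id named
  utt$scene_ids[[1]] <- 99L
  expect_error(label_recall(utt, sc), "99")
})

test_that("mega-scenes are maximal same-song runs and pairs are strictly earlier", {
  sc <- scene_table(1:4, (0:3) * 10, (1:4) * 10, c("a", "a", NA, "a"))
  m <- build_megascenes(sc, songs = "a")
  expect_equal(lapply(m$members, as.integer), list(c(1L, 2L), 4L))
  expect_equal(m$occurrence, 1:2)

  # no two consecutive music scenes -> one mega per scene
  sc2 <- scene_table(1:4, (0:3) * 10, (1:4) * 10, c("a", NA, "a", NA))
  m2 <- build_megascenes(sc2, songs = "a")
  expect_equal(lengths(m2$members), c(1L, 1L))

  # partition property: members partition the repeated-music scenes
  sc3 <- toy_scenes()
  m3 <- build_megascenes(sc3)
  members <- sort(unlist(m3$members))
  expect_equal(members, sort(repeated_music_scenes(sc3)$scene_id))
  expect_equal(anyDuplicated(members), 0L)

  # pairs respect the strictly-earlier predicate
  pr <- enumerate_pairs(sc3, m3)
  first <- m3$first_scene[match(pr$mega_id, m3$mega_id)]
  expect_true(all(pr$earlier_scene < first))
  # exact expected pairing: later blocks vs strictly-earlier same-song scenes
  expect_equal(pr$mega_id, c("a.2", "a.2", "b.2"))
  expect_equal(pr$earlier_scene, c(1L, 2L, 4L))
  # first occurrences never cue
  expect_false(any(pr$mega_id %in% c("a.1", "b.1")))
})

test_that("scene table TSV round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scene_table(toy_scenes(), path)
  back <- read_scene_table(path)
  expect_equal(as.data.frame(back), as.data.frame(toy_scenes()))
})
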