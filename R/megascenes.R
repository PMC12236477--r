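#' Collapse successive same-song scenes into mega-scenes
#'
#' When one song plays across several successive scenes, their patterns are
#' analysed as a single unit (a *mega-scene*). Each maximal run of
#' consecutive scene ids sharing one song id becomes one mega-scene; a run
#' broken by a scene without that song splits. Scenes without a repeated
#' song never appear.
#'
#' @param scenes a [scene_table()].
#' @param songs songs to include; defaults to [repeated_songs()] of the
#'   table, since only repeated songs can cue earlier scenes.
#' @return tibble with one row per mega-scene: `mega_id` (e.g. `"theme1.2"`
#'   for the second occurrence block of theme1), `song_id`, `occurrence`
#'   (block index within song), `first_scene` and a list-column `members`
#'   of member scene ids.
#' @examples
#' sc <- scene_table(1:4, 0:3 * 10, 1:4 * 10, c("a", "a", NA, "a"))
#' build_megascenes(sc, songs = "a")
#' @export
build_megascenes <- function(scenes, songs = repeated_songs(scenes)) {
  scenes <- validate_scene_table(scenes)
  music <- scenes[!is.na(scenes$song_id) & scenes$song_id %in% songs, ]
  if (nrow(music) == 0) {
    return(tibble::tibble(mega_id = character(0), song_id = character(0),
                          occurrence = integer(0), first_scene = integer(0),
                          members = list()))
  }
  out <- lapply(split(music$scene_id, music$song_id), function(ids) {
    ids <- sort(ids)
    run <- cumsum(c(TRUE, diff(ids) > 1L))
    unname(lapply(split(ids, run), unname))
  })
  rows <- dplyr::bind_rows(lapply(names(out), function(song) {
    blocks <- out[[song]]
    tibble::tibble(
      song_id = song,
      occurrence = seq_along(blocks),
      first_scene = vapply(blocks, min, integer(1)),
      members = blocks
    )
  }))
  rows <- dplyr::arrange(rows, .data$first_scene)
  rows$mega_id <- paste0(rows$song_id, ".", rows$occurrence)
  rows[, c("mega_id", "song_id", "occurrence", "first_scene", "members")]
}

#' Enumerate strictly-earlier cue pairs
#'
#' A later mega-scene (second or later occurrence block of a song) is
#' compared only against same-song scenes that are *strictly earlier* than
#' the mega-scene, i.e. whose scene id is below the smallest member id; a
#' scene inside the mega-scene's own run is never its comparison target
#' (within-run similarity could reflect working memory rather than
#' retrieval).
#'
#' @param scenes a [scene_table()].
#' @param megas output of [build_megascenes()]; recomputed when omitted.
#' @return tibble with one row per (mega-scene, earlier scene) pair:
#'   `mega_id`, `song_id`, `earlier_scene`; deterministic order by
#'   mega-scene then scene.
#' @export
enumerate_pairs <- function(scenes, megas = build_megascenes(scenes)) {
  scenes <- validate_scene_table(scenes)
  music <- scenes[!is.na(scenes$song_id), ]
  rows <- lapply(seq_len(nrow(megas)), function(i) {
    song <- megas$song_id[i]
    lo <- megas$first_scene[i]
    earlier <- sort(music$scene_id[music$song_id == song &
                                     music$scene_id < lo])
    if (length(earlier) == 0) return(NULL)
    tibble::tibble(mega_id = megas$mega_id[i], song_id = song,
                   earlier_scene = earlier)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(mega_id = character(0), song_id = character(0),
                          earlier_scene = integer(0)))
  }
  ord <- order(match(out$mega_id, megas$mega_id), out$earlier_scene)
  out[ord, ]
}
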