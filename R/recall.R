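#' Label scenes as remembered or forgotten from recall utterances
#'
#' Raters assign one or more scene labels to each free-recall utterance; a
#' scene counts as remembered by a participant when at least one of that
#' participant's utterances carries its label. Every other scene is
#' forgotten, including all scenes of participants with no utterances.
#'
#' @param utterances a data frame with columns `participant_id`,
#'   `utterance_id` and a list-column `scene_ids` (integer vectors; an
#'   utterance may be labelled with several scenes). Plain integer
#'   `scene_ids` columns are accepted for single-label utterances.
#' @param scenes a [scene_table()].
#' @param participants optional character vector of all participant ids;
#'   defaults to the participants present in `utterances`. Supply it to get
#'   all-forgotten rows for participants who recalled nothing.
#' @return a recall table: tibble with `participant_id`, `scene_id`,
#'   `remembered` (logical), one row per participant x scene.
#' @export
label_recall <- function(utterances, scenes, participants = NULL) {
  scenes <- validate_scene_table(scenes)
  if (!all(c("participant_id", "scene_ids") %in% names(utterances))) {
    abort("utterances need columns participant_id, scene_ids")
  }
  ids <- unlist(utterances$scene_ids, use.names = FALSE)
  unknown <- setdiff(ids, scenes$scene_id)
  if (length(unknown) > 0) {
    abort(sprintf("unknown scene_id in utterance labels: %s",
                  paste(sort(unknown), collapse = ", ")))
  }
  participants <- participants %||% unique(utterances$participant_id)
  long <- tibble::tibble(
    participant_id = rep(utterances$participant_id,
                         lengths(utterances$scene_ids)),
    scene_id = as.integer(ids)
  )
  grid <- tidyr::expand_grid(participant_id = participants,
                             scene_id = scenes$scene_id)
  remembered <- dplyr::distinct(long)
  remembered$remembered <- TRUE
  out <- dplyr::left_join(grid, remembered,
                          by = c("participant_id", "scene_id"))
  out$remembered <- !is.na(out$remembered)
  out
}

#' Read / write recall tables as TSV
#'
#' @param path file path; columns `participant_id`, `scene_id`,
#'   `remembered` (logical or 0/1).
#' @export
read_recall_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           participant_id = readr::col_character(),
                           scene_id = readr::col_integer(),
                           remembered = readr::col_logical()
                         ))
  validate_recall_table(tbl)
}

#' @rdname read_recall_table
#' @param recall a recall table.
#' @export
write_recall_table <- function(recall, path) {
  readr::write_tsv(validate_recall_table(recall), path)
  invisible(path)
}

#' @rdname read_recall_table
#' @export
validate_recall_table <- function(recall) {
  req <- c("participant_id", "scene_id", "remembered")
  if (!all(req %in% names(recall))) {
    abort(paste("recall table needs columns", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(recall[, c("participant_id", "scene_id")])) {
    abort("recall table has duplicated (participant, scene) rows")
  }
  tibble::as_tibble(recall)
}
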