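#' A single participant-by-parcel time series
#'
#' Light container for one voxels x TRs matrix, the raw substrate of
#' pattern extraction.
#'
#' @param participant_id,group,parcel_id identifiers (`group` is `"music"`
#'   or `"nomusic"`).
#' @param mat numeric matrix, voxels x TRs; must be finite.
#' @param TR_s repetition time in seconds.
#' @export
parcel_series <- function(participant_id, group = c("music", "nomusic"),
                          parcel_id, mat, TR_s) {
  group <- match.arg(group)
  if (!is.matrix(mat) || !is.numeric(mat)) abort("`mat` must be a matrix")
  if (any(!is.finite(mat))) abort("non-finite values in time series")
  assert_scalar_number(TR_s, "TR_s", positive = TRUE)
  structure(list(participant_id = participant_id, group = group,
                 parcel_id = parcel_id, mat = mat, TR_s = TR_s),
            class = "parcel_series")
}

#' Time-averaged spatial pattern of one scene
#'
#' Averages the voxel time series over the TRs whose onset falls in the
#' half-open, lag-shifted interval `[start_s + lag_s, end_s + lag_s)`.
#'
#' @param series a [parcel_series()].
#' @param scene one row of a [scene_table()].
#' @param lag_s hemodynamic shift in seconds applied to the interval
#'   (default 0).
#' @return numeric vector of per-voxel means.
#' @export
scene_pattern <- function(series, scene, lag_s = 0) {
  stopifnot(inherits(series, "parcel_series"))
  onsets <- (seq_len(ncol(series$mat)) - 1) * series$TR_s
  sel <- onsets >= scene$start_s + lag_s & onsets < scene$end_s + lag_s
  if (!any(sel)) {
    abort(sprintf("scene %s covers no TRs after lag %.3g s",
                  scene$scene_id, lag_s))
  }
  rowMeans(series$mat[, sel, drop = FALSE])
}

#' Pattern of a mega-scene
#'
#' Unweighted mean of the member scenes' patterns (each member scene counts
#' equally regardless of its duration).
#'
#' @param series a [parcel_series()].
#' @param mega one row of [build_megascenes()] output.
#' @param scenes the [scene_table()].
#' @inheritParams scene_pattern
#' @export
megascene_pattern <- function(series, mega, scenes, lag_s = 0) {
  members <- mega$members[[1]] %||% mega$members
  pats <- vapply(members, function(sid) {
    scene_pattern(series, scenes[scenes$scene_id == sid, ], lag_s)
  }, numeric(nrow(series$mat)))
  rowMeans(as.matrix(pats))
}

#' Voxelwise group-average pattern
#'
#' @param patterns matrix voxels x participants with participant ids as
#'   column names, or a named list of pattern vectors.
#' @param exclude_participant id to leave out (leave-one-out average), or
#'   `NULL` for the full average. An id not present among the columns is a
#'   no-op with a warning.
#' @return numeric vector; the excluded id is recorded in attribute
#'   `"excluded"`.
#' @export
group_average <- function(patterns, exclude_participant = NULL) {
  if (is.list(patterns)) patterns <- do.call(cbind, patterns)
  stopifnot(is.matrix(patterns))
  excluded <- NULL
  if (!is.null(exclude_participant)) {
    hit <- colnames(patterns) == exclude_participant
    if (!any(hit)) {
      warn(sprintf("participant '%s' not present; averaging all %d patterns",
                   exclude_participant, ncol(patterns)))
    } else {
      patterns <- patterns[, !hit, drop = FALSE]
      excluded <- exclude_participant
    }
  }
  if (ncol(patterns) < (if (is.null(excluded)) 1 else 2)) {
    abort("too few patterns remain after exclusion")
  }
  structure(rowMeans(patterns), excluded = excluded)
}

#' Extract repeated-music scene patterns for a whole dataset
#'
#' Computes, for every group, participant and parcel, the time-averaged
#' spatial pattern of each repeated-music scene, the substrate of all
#' reactivation and ISC analyses.
#'
#' @param dataset a `sim_dataset` (or any list with the same `series`,
#'   `scenes`, `config$TR_s` layout).
#' @param lag_s hemodynamic shift in seconds (default 0; the pipeline's
#'   scene intervals are interpreted without a shift unless requested).
#' @return list of class `pool_patterns`: `pool` (scene rows), `megas`,
#'   `pairs`, `parcel_ids`, and `groups`, a list with one
#'   voxels x scenes x participants x parcels array per group.
#' @export
pool_patterns <- function(dataset, lag_s = 0) {
  scenes <- dataset$scenes
  pool <- repeated_music_scenes(scenes)
  TR_s <- dataset$config$TR_s
  groups <- list()
  for (grp in names(dataset$series)) {
    plist <- dataset$series[[grp]]
    dims <- dim(plist[[1]])
    V <- dims[1]; n_tr <- dims[2]; K <- dims[3]
    A <- averaging_matrix(n_tr, TR_s, pool, lag_s)
    S <- ncol(A); N <- length(plist)
    arr <- array(NA_real_, dim = c(V, S, N, K),
                 dimnames = list(NULL, pool$scene_id, names(plist), NULL))
    for (p in seq_len(N)) {
      m2 <- matrix(aperm(plist[[p]], c(1, 3, 2)), V * K, n_tr)
      pat <- m2 %*% A                       # (V*K) x S
      arr[, , p, ] <- aperm(array(pat, dim = c(V, K, S)), c(1, 3, 2))
    }
    groups[[grp]] <- arr
  }
  structure(list(pool = pool, megas = build_megascenes(scenes),
                 pairs = enumerate_pairs(scenes), lag_s = lag_s,
                 parcel_ids = seq_len(dim(groups[[1]])[4]),
                 groups = groups),
            class = "pool_patterns")
}

#' TR-averaging matrix (internal)
#'
#' Column s holds weight 1/n_s on the TRs belonging to scene s, so that
#' `mat %*% A` yields time-averaged scene patterns. Errors when a scene
#' covers no TRs.
#' @noRd
averaging_matrix <- function(n_tr, TR_s, scenes, lag_s = 0) {
  idx <- scene_tr_index(n_tr, TR_s, scenes, lag_s)
  empty <- lengths(idx) == 0
  if (any(empty)) {
    abort(sprintf("scene(s) %s cover no TRs after lag %.3g s",
                  paste(scenes$scene_id[empty], collapse = ", "), lag_s))
  }
  A <- matrix(0, n_tr, nrow(scenes))
  for (s in seq_along(idx)) A[idx[[s]], s] <- 1 / length(idx[[s]])
  A
}
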