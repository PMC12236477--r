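#' Consensus event boundaries from multiple raters
#'
#' Pools every rater's boundary timestamps, smooths them with a Gaussian
#' kernel (one unit-mass Gaussian per boundary, summed over raters), finds
#' the local maxima of the pooled density on a regular time grid, and keeps
#' the peaks whose height reaches the given percentile of the peak heights.
#' Thresholding over peak heights (rather than over all grid values, most of
#' which are near zero between boundary clusters) is what discards a stray
#' boundary marked by a single rater while keeping locations where raters
#' agree. This converts noisy individual annotations into a consensus set
#' of event boundaries.
#'
#' @param raters list of numeric vectors, one per rater, each the rater's
#'   boundary times in seconds (unordered; may be empty).
#' @param sigma_s Gaussian kernel standard deviation in seconds (default 3).
#' @param percentile density percentile (0--100) a peak must exceed
#'   (default 90).
#' @param grid_step_s evaluation grid step in seconds (default 0.1).
#' @return numeric vector of consensus boundary times, sorted ascending;
#'   empty when no rater marked any boundary.
#' @examples
#' consensus_boundaries(list(c(10, 100), c(11, 99)), sigma_s = 3)
#' @export
consensus_boundaries <- function(raters, sigma_s = 3, percentile = 90,
                                 grid_step_s = 0.1) {
  if (!is.list(raters) || length(raters) == 0) {
    abort("need at least one rater")
  }
  assert_scalar_number(sigma_s, "sigma_s", positive = TRUE)
  assert_scalar_number(percentile, "percentile")
  if (percentile <= 0 || percentile >= 100) {
    abort("`percentile` must be strictly between 0 and 100")
  }
  assert_scalar_number(grid_step_s, "grid_step_s", positive = TRUE)
  times <- unlist(raters, use.names = FALSE)
  if (length(times) == 0) return(numeric(0))
  if (any(!is.finite(times))) abort("non-finite boundary times")

  grid <- seq(min(times) - 4 * sigma_s, max(times) + 4 * sigma_s,
              by = grid_step_s)
  dens <- rowSums(dnorm(outer(grid, times, "-"), sd = sigma_s))
  k <- length(dens)
  is_peak <- c(FALSE, dens[2:(k - 1)] > dens[1:(k - 2)] &
                 dens[2:(k - 1)] >= dens[3:k], FALSE)
  heights <- dens[is_peak]
  thr <- quantile(heights, probs = percentile / 100, names = FALSE)
  sort(grid[is_peak & dens >= thr])
}

#' Snap first-rater scene boundaries to consensus boundaries
#'
#' The scene inventory comes from a single rater's fine-grained segmentation;
#' the other raters only vote on boundary locations. Each internal first-rater
#' boundary is kept when a consensus boundary lies within `snap_tolerance_s`
#' of it; otherwise the two flanking scenes merge (the first rater
#' over-segmented relative to the group). Song labels of merged scenes must
#' agree or be absorbed: the merged scene keeps the song id if all merged
#' members share one, otherwise the label of the longest member.
#'
#' @param scenes a [scene_table()] from the first rater.
#' @param consensus numeric vector of consensus boundary times (seconds).
#' @param snap_tolerance_s maximal distance (seconds) for a first-rater
#'   boundary to be confirmed (default 3).
#' @return a [scene_table()] with merged scenes renumbered 1..n.
#' @export
snap_scene_boundaries <- function(scenes, consensus, snap_tolerance_s = 3) {
  scenes <- validate_scene_table(scenes)
  assert_scalar_number(snap_tolerance_s, "snap_tolerance_s", positive = TRUE)
  n <- nrow(scenes)
  if (n == 1) return(scenes)
  inner <- scenes$end_s[-n]  # boundaries between successive scenes
  keep <- vapply(inner, function(b) {
    length(consensus) > 0 && min(abs(consensus - b)) <= snap_tolerance_s
  }, logical(1))
  grp <- cumsum(c(TRUE, keep))  # merged-scene membership
  merged <- lapply(split(seq_len(n), grp), function(idx) {
    songs <- scenes$song_id[idx]
    song <- if (length(unique(songs)) == 1) {
      songs[1]
    } else {
      lens <- scenes$end_s[idx] - scenes$start_s[idx]
      songs[which.max(lens)]
    }
    tibble::tibble(start_s = scenes$start_s[idx[1]],
                   end_s = scenes$end_s[idx[length(idx)]],
                   song_id = song)
  })
  out <- dplyr::bind_rows(merged)
  scene_table(seq_len(nrow(out)), out$start_s, out$end_s, out$song_id)
}

#' Read rater boundaries from TSV
#'
#' Expects a header with columns `rater_id` and `time_s`; returns a list of
#' numeric vectors named by rater, the input format of
#' [consensus_boundaries()].
#'
#' @param path file path.
#' @export
read_rater_boundaries <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           rater_id = readr::col_character(),
                           time_s = readr::col_double()
                         ))
  split(tbl$time_s, tbl$rater_id)
}
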