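#' Bin scene scores into remembered and forgotten averages
#'
#' Per participant (and parcel, when present), averages the scene-level
#' scores over subsequently remembered scenes and over forgotten scenes.
#' Participants with an empty bin have no defined paired difference; they
#' are returned with `complete = FALSE` and dropped listwise by the tests.
#'
#' @param scores tibble with `participant_id`, `scene_id`, the value column,
#'   and optionally `parcel_id`.
#' @param recall a recall table ([label_recall()] format); must label every
#'   scored scene.
#' @param value column name of the score (default `"z"`).
#' @return tibble with `participant_id` (and `parcel_id`), `mean_r`,
#'   `mean_f`, `n_r`, `n_f`, `complete`.
#' @export
bin_scores <- function(scores, recall, value = "z") {
  if (!value %in% names(scores)) abort(sprintf("no `%s` column", value))
  key <- intersect(c("participant_id", "parcel_id"), names(scores))
  recall <- validate_recall_table(recall)
  joined <- dplyr::left_join(scores,
                             recall[, c("participant_id", "scene_id",
                                        "remembered")],
                             by = c("participant_id", "scene_id"))
  if (any(is.na(joined$remembered))) {
    miss <- joined[is.na(joined$remembered), ]
    abort(sprintf("missing recall label for participant %s scene %s",
                  miss$participant_id[1], miss$scene_id[1]))
  }
  joined$..v <- joined[[value]]
  out <- dplyr::summarise(
    dplyr::group_by(joined, dplyr::across(dplyr::all_of(key))),
    mean_r = mean(.data$..v[.data$remembered]),
    mean_f = mean(.data$..v[!.data$remembered]),
    n_r = sum(.data$remembered),
    n_f = sum(!.data$remembered),
    .groups = "drop"
  )
  out$complete <- out$n_r > 0 & out$n_f > 0
  out
}

#' Remembered-versus-forgotten test
#'
#' One-tailed (remembered > forgotten) t-test on per-participant binned
#' scores. The default is a paired t-test on the within-participant
#' differences; an independent-samples variant (treating the remembered and
#' forgotten bin means as two samples) is exposed for fidelity experiments.
#' Incomplete participants (empty bin) are dropped listwise.
#'
#' @param bins output of [bin_scores()] (for a single parcel/ROI).
#' @param test `"paired"` (default) or `"independent"`.
#' @return one-row tibble: `t`, `p`, `df`, `n`, `mean_r`, `mean_f`,
#'   `n_dropped`, `degenerate`.
#' @export
remembered_vs_forgotten <- function(bins, test = c("paired", "independent")) {
  test <- match.arg(test)
  keep <- bins[bins$complete, ]
  n_dropped <- sum(!bins$complete)
  if (nrow(keep) < 3) abort("fewer than 3 complete remembered/forgotten pairs")
  res <- if (test == "paired") {
    t_one_sample(keep$mean_r - keep$mean_f, tail = "greater")
  } else {
    t_two_sample(keep$mean_r, keep$mean_f, tail = "greater")
  }
  tibble::tibble(t = res$t, p = res$p, df = res$df, n = nrow(keep),
                 mean_r = mean(keep$mean_r), mean_f = mean(keep$mean_f),
                 n_dropped = n_dropped, degenerate = res$degenerate)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity (the
#' standard BH procedure, via [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Parcel-based searchlight of the subsequent-memory effect
#'
#' Runs [remembered_vs_forgotten()] in every parcel and corrects the
#' one-tailed p-values across the stated correction set (for the reference
#' analysis, the default-mode parcels). Parcels outside the correction set
#' are reported with `q = NA`.
#'
#' @param scores score tibble (`participant_id`, `parcel_id`, `scene_id`,
#'   value column).
#' @param recall recall table.
#' @param parcel_set parcels to test; default all present.
#' @param correction_set parcels whose p-values enter the FDR correction;
#'   default `parcel_set`.
#' @param q_threshold significance threshold on q (default 0.1).
#' @param value score column (default `"z"`).
#' @inheritParams remembered_vs_forgotten
#' @return tibble of per-parcel effects (`parcel_id`, `t`, `p`, `q`, `n`,
#'   `mean_r`, `mean_f`, `significant`), sorted by parcel.
#' @export
searchlight_memory <- function(scores, recall, parcel_set = NULL,
                               correction_set = NULL, q_threshold = 0.1,
                               value = "z", test = c("paired", "independent")) {
  test <- match.arg(test)
  parcel_set <- sort(parcel_set %||% unique(scores$parcel_id))
  missing <- setdiff(parcel_set, unique(scores$parcel_id))
  if (length(missing) > 0) {
    abort(sprintf("no scores for parcel(s) %s",
                  paste(missing, collapse = ", ")))
  }
  correction_set <- correction_set %||% parcel_set
  bins <- bin_scores(scores[scores$parcel_id %in% parcel_set, ],
                     recall, value = value)
  eff <- dplyr::bind_rows(lapply(parcel_set, function(k) {
    res <- remembered_vs_forgotten(bins[bins$parcel_id == k, ], test = test)
    res$parcel_id <- k
    res
  }))
  eff$q <- NA_real_
  in_corr <- eff$parcel_id %in% correction_set
  eff$q[in_corr] <- fdr_adjust(eff$p[in_corr])
  eff$significant <- !is.na(eff$q) & eff$q <= q_threshold
  eff[, c("parcel_id", "t", "p", "q", "df", "n", "mean_r", "mean_f",
          "n_dropped", "degenerate", "significant")]
}

#' ROI-level subsequent-memory effects
#'
#' Scene scores are first averaged over a ROI's member parcels within each
#' participant, then tested with [remembered_vs_forgotten()]; q-values are
#' corrected across ROIs.
#'
#' @param scores score tibble as in [searchlight_memory()].
#' @param recall recall table.
#' @param roi_map tibble with `parcel_id`, `roi_id` (a parcel may belong to
#'   at most one ROI).
#' @inheritParams searchlight_memory
#' @return tibble of per-ROI effects.
#' @export
roi_memory <- function(scores, recall, roi_map, q_threshold = 0.1,
                       value = "z", test = c("paired", "independent")) {
  test <- match.arg(test)
  if (nrow(roi_map) == 0) abort("empty ROI map")
  counts <- table(roi_map$roi_id)
  if (any(counts == 0)) abort("ROI with no member parcels")
  joined <- dplyr::inner_join(scores, roi_map, by = "parcel_id")
  joined$..v <- joined[[value]]
  roi_scores <- dplyr::summarise(
    dplyr::group_by(joined, .data$roi_id, .data$participant_id,
                    .data$scene_id),
    ..v = mean(.data$..v), .groups = "drop"
  )
  names(roi_scores)[names(roi_scores) == "..v"] <- value
  rois <- sort(unique(roi_map$roi_id))
  eff <- dplyr::bind_rows(lapply(rois, function(r) {
    sub <- roi_scores[roi_scores$roi_id == r, ]
    res <- remembered_vs_forgotten(bin_scores(sub, recall, value = value),
                                   test = test)
    res$roi_id <- r
    res
  }))
  eff$q <- fdr_adjust(eff$p)
  eff$significant <- eff$q <= q_threshold
  eff[, c("roi_id", "t", "p", "q", "df", "n", "mean_r", "mean_f",
          "n_dropped", "degenerate", "significant")]
}
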