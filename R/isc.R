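#' Spatial intersubject correlation per scene and parcel
#'
#' Correlates each participant's time-averaged scene pattern with the
#' average pattern of the other N-1 participants of the *same* condition
#' (leave-one-out), per repeated-music scene and parcel. High spatial ISC
#' indicates that the participant encoded the scene like the rest of the
#' group; it serves as the pipeline's proxy for initial encoding strength.
#'
#' @param pp a [pool_patterns()] object or `sim_dataset`.
#' @param condition `"music"`, `"nomusic"`, or `"both"` (both conditions
#'   computed within-condition and stacked).
#' @param parcels parcel ids (default all).
#' @return tibble with `condition`, `participant_id`, `scene_id`,
#'   `parcel_id`, `r`.
#' @export
spatial_isc <- function(pp, condition = c("both", "music", "nomusic"),
                        parcels = NULL) {
  condition <- match.arg(condition)
  if (inherits(pp, "sim_dataset")) pp <- pool_patterns(pp)
  stopifnot(inherits(pp, "pool_patterns"))
  conds <- if (condition == "both") c("music", "nomusic") else condition
  parcels <- parcels %||% pp$parcel_ids
  out <- list()
  for (grp in conds) {
    arr <- pp$groups[[grp]]
    V <- dim(arr)[1]; S <- dim(arr)[2]; N <- dim(arr)[3]
    if (N < 3) abort("need >= 3 participants per condition for N-1 ISC")
    pid <- dimnames(arr)[[3]]
    for (k in parcels) {
      a_k <- array(arr[, , , k], dim = c(V, S, N))
      tot <- rowSums(a_k, dims = 2)
      for (p in seq_len(N)) {
        own <- matrix(a_k[, , p], V, S)
        loo <- (tot - own) / (N - 1)
        out[[length(out) + 1]] <- tibble::tibble(
          condition = grp, participant_id = pid[p],
          scene_id = pp$pool$scene_id, parcel_id = k,
          r = colwise_cor(own, loo, "scene pattern", "group-average pattern")
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Screen parcels where ISC predicts subsequent recall
#'
#' Runs the remembered-versus-forgotten machinery on binned spatial ISC
#' scores in every parcel and selects the parcels whose one-tailed p falls
#' below a liberal uncorrected threshold. The selected region set drives
#' the sequential residualization; the full effect table (with q-values
#' over all parcels) is returned alongside for the corrected report.
#'
#' @param isc output of [spatial_isc()] (already restricted to the
#'   condition(s) the screen should use).
#' @param recall recall table covering the scored participants.
#' @param p_threshold uncorrected selection threshold (default 0.05).
#' @inheritParams searchlight_memory
#' @return list of class `isc_region_set`: `regions` (parcel ids, sorted —
#'   the deterministic residualization order), `p_threshold`, `effects`
#'   (full per-parcel table).
#' @export
isc_memory_screen <- function(isc, recall, p_threshold = 0.05,
                              test = c("paired", "independent")) {
  test <- match.arg(test)
  eff <- searchlight_memory(isc, recall, value = "r", test = test)
  regions <- sort(eff$parcel_id[!is.na(eff$p) & eff$p < p_threshold])
  structure(list(regions = regions, p_threshold = p_threshold,
                 effects = eff),
            class = "isc_region_set")
}

#' Sequentially regress ISC out of scene scores
#'
#' Within each participant, performs one ordinary-least-squares step per
#' selected region, in deterministic region order: the region's ISC values
#' (over the participant's scored scenes) predict the current residuals,
#' and the residuals are updated after each step. Every step includes an
#' intercept. A constant predictor leaves the residuals unchanged for that
#' step (slope undefined) with a warning. With correlated predictors the
#' result depends on the step order; `order_seed` permutes the region order
#' reproducibly for sensitivity checks.
#'
#' @param scores score tibble (`participant_id`, `parcel_id`, `scene_id`,
#'   value column) whose value will be residualized, for every parcel.
#' @param isc [spatial_isc()] output for the same participants and scenes.
#' @param regions an `isc_region_set` or integer vector of predictor
#'   parcel ids; empty means no-op.
#' @param value score column to residualize (default `"z"`).
#' @param order_seed optional seed to randomize the step order.
#' @return `scores` with the value column replaced by the final residuals.
#' @export
sequential_residualize <- function(scores, isc, regions, value = "z",
                                   order_seed = NULL) {
  if (inherits(regions, "isc_region_set")) regions <- regions$regions
  regions <- as.integer(regions)
  if (length(regions) == 0) return(scores)
  if (!is.null(order_seed)) {
    set.seed(order_seed)
    regions <- sample(regions)
  }
  isc_wide <- tidyr::pivot_wider(
    isc[isc$parcel_id %in% regions,
        c("participant_id", "scene_id", "parcel_id", "r")],
    names_from = "parcel_id", values_from = "r"
  )
  out <- scores
  warned <- FALSE
  for (pid in unique(scores$participant_id)) {
    rows <- which(out$participant_id == pid)
    pred_rows <- isc_wide[isc_wide$participant_id == pid, ]
    if (any(is.na(match(unique(out$scene_id[rows]),
                        pred_rows$scene_id)))) {
      abort(sprintf("ISC predictors missing for participant %s", pid))
    }
    # residualize every parcel's score vector with the same predictors
    for (k in unique(out$parcel_id[rows])) {
      rk <- rows[out$parcel_id[rows] == k]
      r <- out[[value]][rk]
      sc <- out$scene_id[rk]
      for (reg in regions) {
        x <- pred_rows[[as.character(reg)]][match(sc, pred_rows$scene_id)]
        if (sd(x) == 0) {
          if (!warned) {
            warn(sprintf("constant ISC predictor (parcel %d); step skipped",
                         reg))
            warned <- TRUE
          }
          next
        }
        fit <- lm.fit(cbind(1, x), r)
        r <- unname(fit$residuals)
      }
      out[[value]][rk] <- r
    }
  }
  out
}

#' Subsequent-memory statistics on residualized scores
#'
#' Applies [sequential_residualize()] and re-runs the parcel searchlight on
#' the residuals, returning the post-regression effects together with a
#' pre/post comparison table.
#'
#' @param scores reactivation score tibble.
#' @param recall recall table.
#' @param isc [spatial_isc()] output used for the predictors.
#' @param regions an `isc_region_set` or parcel id vector.
#' @inheritParams searchlight_memory
#' @return list with `effects` (post-regression per-parcel table),
#'   `pre_effects`, and `comparison` (parcel, t_pre, t_post).
#' @export
residual_memory <- function(scores, recall, isc, regions,
                            parcel_set = NULL, correction_set = NULL,
                            q_threshold = 0.1, value = "z",
                            test = c("paired", "independent")) {
  test <- match.arg(test)
  resid <- sequential_residualize(scores, isc, regions, value = value)
  post <- searchlight_memory(resid, recall, parcel_set, correction_set,
                             q_threshold, value = value, test = test)
  pre <- searchlight_memory(scores, recall, parcel_set, correction_set,
                            q_threshold, value = value, test = test)
  comparison <- tibble::tibble(parcel_id = pre$parcel_id,
                               t_pre = pre$t, t_post = post$t)
  list(effects = post, pre_effects = pre, comparison = comparison,
       residuals = resid)
}
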