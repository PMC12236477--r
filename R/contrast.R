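#' Convert a t statistic to a standard-normal z score
#'
#' Quantile matching through the tail probability: the returned z has the
#' same one-tailed tail area under the standard normal as `t` has under its
#' t distribution. Computed on the log scale so extreme statistics stay
#' finite and monotone. For large df, z approaches t.
#'
#' @param t t statistic(s).
#' @param df degrees of freedom (>= 1).
#' @return z score(s), same sign as `t`.
#' @examples
#' t_to_z(2, df = 10)
#' @export
t_to_z <- function(t, df) {
  if (any(df < 1)) abort("`df` must be >= 1")
  if (any(!is.finite(t))) abort("`t` must be finite")
  qnorm(pt(t, df = df, log.p = TRUE), log.p = TRUE)
}

#' Per-parcel subsequent-memory z maps for both conditions
#'
#' For each parcel and condition, runs the remembered-versus-forgotten test
#' and converts the t statistic to a z score with [t_to_z()], yielding the
#' per-parcel map whose music-minus-no-music difference the condition
#' contrasts operate on.
#'
#' @param scores_music,scores_nomusic score tibbles for the two conditions
#'   (cross-group reactivation for music; the no-music control pipeline for
#'   nomusic).
#' @param recall recall table covering both groups' participants.
#' @param parcel_set parcels to map (default: parcels present in both).
#' @inheritParams searchlight_memory
#' @return tibble with `parcel_id`, `z_music`, `z_nomusic`, `dz`.
#' @export
condition_zmap <- function(scores_music, scores_nomusic, recall,
                           parcel_set = NULL, value = "z",
                           test = c("paired", "independent")) {
  test <- match.arg(test)
  parcel_set <- sort(parcel_set %||%
                       intersect(unique(scores_music$parcel_id),
                                 unique(scores_nomusic$parcel_id)))
  zs <- lapply(list(scores_music, scores_nomusic), function(sc) {
    eff <- searchlight_memory(sc, recall, parcel_set, value = value,
                              test = test)
    if (any(eff$degenerate)) abort("degenerate per-parcel t; cannot map to z")
    t_to_z(eff$t, eff$df)
  })
  tibble::tibble(parcel_id = parcel_set, z_music = zs[[1]],
                 z_nomusic = zs[[2]], dz = zs[[1]] - zs[[2]])
}

#' Parcels-as-observations condition contrast
#'
#' One-tailed paired t-test (music > no-music) on the per-parcel
#' subsequent-memory z scores, with degrees of freedom equal to the number
#' of parcels minus one. This assesses reliability across parcels; it
#' treats participants as a fixed effect and does not license
#' generalization to new participants (recorded in the output).
#'
#' @param zmap output of [condition_zmap()] (>= 3 parcels).
#' @return one-row tibble: `t`, `p`, `df`, `n_parcels`, `mean_dz`,
#'   `caveat`.
#' @export
parcelwise_condition_contrast <- function(zmap) {
  if (nrow(zmap) < 3) abort("need >= 3 parcels")
  res <- t_one_sample(zmap$dz, tail = "greater")
  tibble::tibble(t = res$t, p = res$p, df = res$df,
                 n_parcels = nrow(zmap), mean_dz = mean(zmap$dz),
                 caveat = "parcels as observations; participants fixed")
}

#' Participant-level reliability contrast
#'
#' For each participant, the reliability of the remembered-versus-forgotten
#' difference across the parcel set is summarized by a one-tailed paired
#' t-test over parcels (df = parcels - 1), converted to z with [t_to_z()];
#' the per-participant z values of the two conditions are then compared
#' with a one-tailed two-sample t-test (music > no-music, pooled variance,
#' df = n1 + n2 - 2). Unlike the parcelwise contrast this licenses
#' generalization to new participants.
#'
#' @param scores_music,scores_nomusic score tibbles for the two conditions.
#' @param recall recall table covering both groups.
#' @param parcel_set parcels over which reliability is computed.
#' @param value score column.
#' @return one-row tibble `t`, `p`, `df`, plus per-participant z values in
#'   attribute `"participant_z"`.
#' @export
participant_reliability_contrast <- function(scores_music, scores_nomusic,
                                             recall, parcel_set = NULL,
                                             value = "z") {
  per_participant_z <- function(sc) {
    keep <- if (is.null(parcel_set)) sc else
      sc[sc$parcel_id %in% parcel_set, ]
    bins <- bin_scores(keep, recall, value = value)
    bins <- bins[bins$complete, ]
    vapply(split(bins, bins$participant_id), function(b) {
      if (nrow(b) < 3) return(NA_real_)
      res <- t_one_sample(b$mean_r - b$mean_f, tail = "greater")
      if (res$degenerate) return(NA_real_)
      t_to_z(res$t, res$df)
    }, numeric(1))
  }
  zm <- per_participant_z(scores_music)
  zn <- per_participant_z(scores_nomusic)
  if (sum(is.finite(zm)) < 3 || sum(is.finite(zn)) < 3) {
    abort("need >= 3 participants with defined reliability per condition")
  }
  res <- t_two_sample(zm, zn, tail = "greater")
  out <- tibble::tibble(t = res$t, p = res$p, df = res$df,
                        n_music = sum(is.finite(zm)),
                        n_nomusic = sum(is.finite(zn)))
  attr(out, "participant_z") <- list(music = zm, nomusic = zn)
  out
}

#' Collapse 17-network-style labels to 9 networks
#'
#' Strips the trailing A/B/C subnetwork letter while keeping the central
#' and peripheral visual networks distinct, so the 17 subnetwork labels
#' collapse to exactly 9 bilateral networks.
#'
#' @param subnetwork character vector of 17-network-style labels.
#' @return character vector of collapsed network names.
#' @examples
#' collapse_network(c("DefaultA", "VisPeri", "ContC"))
#' @export
collapse_network <- function(subnetwork) {
  sub("(?<=.)[ABC]$", "", subnetwork, perl = TRUE)
}

#' Condition contrast within each cortical network
#'
#' Runs [parcelwise_condition_contrast()] within every collapsed network
#' and corrects the network p-values with Benjamini-Hochberg FDR. Networks
#' with fewer than 3 parcels are skipped with a warning.
#'
#' @param zmap output of [condition_zmap()] covering all parcels.
#' @param parcel_meta [parcel_metadata()]-style tibble (`parcel_id`,
#'   `network` or `subnetwork`).
#' @param q_threshold significance threshold (default 0.05).
#' @return tibble with one row per tested network: `network`, `t`, `p`,
#'   `q`, `df`, `n_parcels`, `significant`.
#' @export
network_contrast <- function(zmap, parcel_meta, q_threshold = 0.05) {
  if (!"network" %in% names(parcel_meta)) {
    parcel_meta$network <- collapse_network(parcel_meta$subnetwork)
  }
  meta <- parcel_meta[match(zmap$parcel_id, parcel_meta$parcel_id), ]
  if (any(is.na(meta$network))) abort("parcel without a network mapping")
  nets <- sort(unique(meta$network))
  rows <- lapply(nets, function(nw) {
    sub <- zmap[meta$network == nw, ]
    if (nrow(sub) < 3) {
      warn(sprintf("network %s has < 3 parcels; skipped", nw))
      return(NULL)
    }
    res <- parcelwise_condition_contrast(sub)
    tibble::tibble(network = nw, t = res$t, p = res$p, df = res$df,
                   n_parcels = res$n_parcels)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(network = character(0), t = numeric(0),
                          p = numeric(0), df = numeric(0),
                          n_parcels = integer(0), q = numeric(0),
                          significant = logical(0)))
  }
  out$q <- fdr_adjust(out$p)
  out$significant <- out$q <= q_threshold
  out
}
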