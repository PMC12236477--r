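#' Compact scene layout for simulated datasets
#'
#' Builds a small scene table with `n_songs` songs, each occurring in
#' `n_occurrences` blocks of `scenes_per_block` successive scenes.
#' Occurrence blocks are interleaved round-robin across songs (all first
#' occurrences, then all second occurrences, ...) with one silent filler
#' scene between blocks, so every later block has strictly-earlier same-song
#' scenes to be paired with.
#'
#' @param n_songs number of repeated songs.
#' @param n_occurrences occurrence blocks per song (>= 2 for cue pairs).
#' @param scenes_per_block scenes in each block (scalar, or vector of length
#'   `n_occurrences` applied to every song).
#' @param scene_dur_s duration of every scene in seconds.
#' @param filler_dur_s duration of the silent scene between blocks.
#' @return a [scene_table()].
#' @export
sim_scene_table <- function(n_songs = 2, n_occurrences = 2,
                            scenes_per_block = 3, scene_dur_s = 9,
                            filler_dur_s = 9) {
  if (n_songs < 1 || n_occurrences < 1) abort("need >= 1 song and occurrence")
  sizes <- rep_len(scenes_per_block, n_occurrences)
  songs <- character(0)
  for (occ in seq_len(n_occurrences)) {
    for (s in seq_len(n_songs)) {
      songs <- c(songs, rep(sprintf("song%02d", s), sizes[occ]),
                 NA_character_)
    }
  }
  n <- length(songs)
  dur <- ifelse(is.na(songs), filler_dur_s, scene_dur_s)
  ends <- cumsum(dur)
  scene_table(seq_len(n), c(0, ends[-n]), ends, songs)
}

#' Configuration of the synthetic two-group dataset
#'
#' Collects every knob of the generator in a validated list. The generative
#' model for participant p, parcel k, TR t inside scene s is
#' \deqn{x = e_{p,s} \, g \, u_{k,s} + \gamma\text{-term} + \epsilon,}
#' where `u_{k,s}` is a fixed unit-norm scene signature shared across
#' participants and groups, `e_{p,s} ~ lognormal(0, encoding_sd)` is the
#' participant's encoding strength for the scene, and
#' `epsilon ~ N(0, noise_sd^2)` i.i.d. During a scene belonging to a later
#' occurrence block of a song, affected parcels of music-group participants
#' additionally receive the mean reinstated signature of the cued
#' strictly-earlier same-song scenes,
#' \deqn{\frac{1}{|E_s|}\sum_{s' \in E_s} \gamma_{p,s'} u_{k,s'},}
#' with planted reactivation amplitude
#' `gamma_{p,s'} = react_gain * e_{p,s'}^react_encoding_coupling *
#' lognormal(0, react_sd)`. The no-music group is generated by the identical
#' code path with `gamma` forced to 0. Subsequent recall of a cued earlier
#' scene is Bernoulli with
#' `plogis(recall_intercept + recall_b_encoding * e + recall_c_react *
#' gamma)`; recall of other repeated-music scenes uses the encoding term
#' only.
#'
#' @param n_per_group participants per group (music / no-music).
#' @param n_parcels,voxels_per_parcel parcellation size.
#' @param TR_s repetition time in seconds.
#' @param scenes a [scene_table()]; default [sim_scene_table()].
#' @param signature_gain amplitude g of the shared scene signature.
#' @param encoding_sd log-scale spread of encoding strength e.
#' @param react_gain reactivation amplitude gamma (0 disables planting).
#' @param react_sd log-scale spread of the idiosyncratic reactivation
#'   multiplier (the recall channel independent of encoding).
#' @param react_encoding_coupling exponent tying reactivation amplitude to
#'   encoding strength (1 = proportional, 0 = independent).
#' @param affected_parcels integer ids of parcels receiving reinstatement;
#'   default all.
#' @param recall_intercept,recall_b_encoding,recall_c_react logistic recall
#'   model coefficients (a, b, c).
#' @param noise_sd i.i.d. Gaussian noise standard deviation per voxel/TR.
#' @param seed integer; fixes all randomness end-to-end.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 24, n_parcels = 50,
                       voxels_per_parcel = 12, TR_s = 1.5,
                       scenes = sim_scene_table(),
                       signature_gain = 1, encoding_sd = 0.3,
                       react_gain = 0, react_sd = 0.5,
                       react_encoding_coupling = 1,
                       affected_parcels = NULL,
                       recall_intercept = 0, recall_b_encoding = 1,
                       recall_c_react = 0, noise_sd = 1, seed = 1) {
  scenes <- validate_scene_table(scenes)
  for (nm in c("n_per_group", "n_parcels", "voxels_per_parcel")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 1) {
      abort(sprintf("`%s` must be a positive count", nm))
    }
  }
  assert_scalar_number(TR_s, "TR_s", positive = TRUE)
  for (nm in c("signature_gain", "encoding_sd", "react_gain", "react_sd",
               "react_encoding_coupling", "noise_sd")) {
    v <- assert_scalar_number(get(nm), nm)
    if (v < 0) abort(sprintf("`%s` must be >= 0", nm))
  }
  affected_parcels <- as.integer(affected_parcels %||% seq_len(n_parcels))
  if (length(affected_parcels) > 0 &&
      (min(affected_parcels) < 1 || max(affected_parcels) > n_parcels)) {
    abort("`affected_parcels` out of range")
  }
  if (nrow(repeated_music_scenes(scenes)) == 0) {
    abort("scene table has no repeated-music scenes")
  }
  structure(list(
    n_per_group = as.integer(n_per_group),
    n_parcels = as.integer(n_parcels),
    voxels_per_parcel = as.integer(voxels_per_parcel),
    TR_s = TR_s, scenes = scenes,
    signature_gain = signature_gain, encoding_sd = encoding_sd,
    react_gain = react_gain, react_sd = react_sd,
    react_encoding_coupling = react_encoding_coupling,
    affected_parcels = affected_parcels,
    recall_intercept = recall_intercept,
    recall_b_encoding = recall_b_encoding,
    recall_c_react = recall_c_react,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Parcel metadata in the 17-network style
#'
#' Assigns hemispheres and 17-network-style subnetwork labels round-robin
#' across parcels; collapsing the labels (strip the trailing A/B/C, keep the
#' central and peripheral visual networks distinct) yields 9 networks.
#'
#' @param n_parcels number of parcels.
#' @return tibble with `parcel_id`, `hemisphere`, `subnetwork`, `network`.
#' @export
parcel_metadata <- function(n_parcels) {
  labels17 <- c("VisCent", "VisPeri", "SomMotA", "SomMotB", "DorsAttnA",
                "DorsAttnB", "SalVentAttnA", "SalVentAttnB", "LimbicA",
                "LimbicB", "ContA", "ContB", "ContC", "DefaultA",
                "DefaultB", "DefaultC", "TempPar")
  sub <- rep_len(labels17, n_parcels)
  tibble::tibble(
    parcel_id = seq_len(n_parcels),
    hemisphere = rep_len(c("L", "R"), n_parcels),
    subnetwork = sub,
    network = collapse_network(sub)
  )
}

#' Generate a synthetic two-group parcellated dataset
#'
#' Draws scene signatures, encoding strengths, reactivation amplitudes,
#' voxel time series and recall outcomes according to the model documented
#' in [sim_config()]. The same seed always yields a bitwise-identical
#' dataset.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with elements `config`, `scenes`,
#'   `pool` (repeated-music scene rows), `megas`, `pairs`, `parcel_meta`,
#'   `recall` (tibble with `group`, `participant_id`, `scene_id`,
#'   `remembered`), `series` (per group, a named list of
#'   voxels x TR x parcels arrays), and `truth` (latent `encoding` and
#'   `react` matrices plus the cued-scene set).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  scenes <- config$scenes
  pool <- repeated_music_scenes(scenes)
  megas <- build_megascenes(scenes)
  pairs <- enumerate_pairs(scenes, megas)
  S <- nrow(pool)
  V <- config$voxels_per_parcel
  K <- config$n_parcels
  N <- config$n_per_group
  n_tr <- ceiling(max(scenes$end_s) / config$TR_s)
  if (S == 0 || V < 2) abort("degenerate config: need scenes and >= 2 voxels")

  pool_index <- stats::setNames(seq_len(S), pool$scene_id)
  cued <- sort(unique(pairs$earlier_scene))
  # cued earlier-scene set per later-block scene, as pool indices
  later_inject <- list()
  for (i in seq_len(nrow(megas))) {
    if (megas$occurrence[i] < 2) next
    e_set <- pairs$earlier_scene[pairs$mega_id == megas$mega_id[i]]
    if (length(e_set) == 0) next
    for (sid in megas$members[[i]]) {
      later_inject[[as.character(sid)]] <- pool_index[as.character(e_set)]
    }
  }

  ids <- list(music = sprintf("m%02d", seq_len(N)),
              nomusic = sprintf("n%02d", seq_len(N)))
  tr_of_scene <- scene_tr_index(n_tr, config$TR_s, pool, lag_s = 0)

  set.seed(config$seed)
  # 1. shared signatures: unit-norm columns, per parcel
  u <- array(rnorm(V * S * K), dim = c(V, S, K))
  for (k in seq_len(K)) {
    uk <- matrix(u[, , k], V, S)
    u[, , k] <- sweep(uk, 2, sqrt(colSums(uk^2)), "/")
  }
  # 2. encoding strengths e_{p,s} per group
  e <- list(
    music = matrix(rlnorm(N * S, 0, config$encoding_sd), N, S,
                   dimnames = list(ids$music, pool$scene_id)),
    nomusic = matrix(rlnorm(N * S, 0, config$encoding_sd), N, S,
                     dimnames = list(ids$nomusic, pool$scene_id))
  )
  # 3. idiosyncratic reactivation multipliers (music group carries gamma)
  xi <- matrix(rlnorm(N * S, 0, config$react_sd), N, S,
               dimnames = list(ids$music, pool$scene_id))
  gamma <- matrix(0, N, S, dimnames = list(ids$music, pool$scene_id))
  cued_idx <- pool_index[as.character(cued)]
  gamma[, cued_idx] <- config$react_gain *
    e$music[, cued_idx]^config$react_encoding_coupling * xi[, cued_idx]

  affected <- logical(K)
  affected[config$affected_parcels] <- TRUE

  series <- list(music = vector("list", N), nomusic = vector("list", N))
  for (grp in c("music", "nomusic")) {
    for (p in seq_len(N)) {
      mat <- array(rnorm(V * n_tr * K, sd = config$noise_sd),
                   dim = c(V, n_tr, K))
      for (s in seq_len(S)) {
        trs <- tr_of_scene[[s]]
        if (length(trs) == 0) next
        # V x K additive component active throughout the scene
        add <- e[[grp]][p, s] * config$signature_gain * matrix(u[, s, ], V, K)
        if (grp == "music") {
          e_set <- later_inject[[as.character(pool$scene_id[s])]]
          if (!is.null(e_set)) {
            gmk <- matrix(0, V, K)
            for (sp in e_set) {
              gmk <- gmk + gamma[p, sp] * matrix(u[, sp, ], V, K)
            }
            gmk <- gmk / length(e_set)
            gmk[, !affected] <- 0
            add <- add + gmk
          }
        }
        mat[, trs, ] <- mat[, trs, ] +
          aperm(array(add, dim = c(V, K, length(trs))), c(1, 3, 2))
      }
      dimnames(mat) <- list(NULL, NULL, seq_len(K))
      series[[grp]][[p]] <- mat
    }
    names(series[[grp]]) <- ids[[grp]]
  }

  # 4. recall outcomes for repeated-music scenes
  recall <- list()
  for (grp in c("music", "nomusic")) {
    g_mat <- if (grp == "music") gamma else matrix(0, N, S)
    eta <- config$recall_intercept +
      config$recall_b_encoding * e[[grp]] +
      config$recall_c_react * g_mat
    rem <- matrix(rbinom(N * S, 1, plogis(eta)) == 1, N, S)
    recall[[grp]] <- tibble::tibble(
      group = grp,
      participant_id = rep(ids[[grp]], times = S),
      scene_id = rep(pool$scene_id, each = N),
      remembered = as.vector(rem)
    )
  }

  structure(list(
    config = config, scenes = scenes, pool = pool, megas = megas,
    pairs = pairs, parcel_meta = parcel_metadata(K),
    recall = dplyr::bind_rows(recall),
    series = series,
    truth = list(encoding = e, react = gamma, cued_scenes = cued,
                 signatures = u)
  ), class = "sim_dataset")
}

#' TRs covered by each scene (internal)
#'
#' A TR belongs to a scene when its onset falls inside the half-open,
#' lag-shifted interval `[start_s + lag_s, end_s + lag_s)`.
#' @noRd
scene_tr_index <- function(n_tr, TR_s, scenes, lag_s = 0) {
  onsets <- (seq_len(n_tr) - 1) * TR_s
  lapply(seq_len(nrow(scenes)), function(i) {
    which(onsets >= scenes$start_s[i] + lag_s &
            onsets < scenes$end_s[i] + lag_s)
  })
}
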