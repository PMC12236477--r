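#' Deterministic per-(participant, parcel) permutation substream seed
#'
#' One master seed governs the whole analysis; each (participant, parcel)
#' cell derives its own substream seed from it so that serial, parallel and
#' re-ordered runs produce identical permutation draws. The derivation is
#' `((master mod 97561) * 21977 + parcel * 7919 + participant) mod
#' 2147483629 + 1`.
#'
#' @param master master seed (integer).
#' @param participant_idx participant index within its group (1-based).
#' @param parcel_idx parcel index (1-based).
#' @return integer seed suitable for [set.seed()].
#' @export
substream_seed <- function(master, participant_idx, parcel_idx) {
  as.integer(((as.numeric(master) %% 97561) * 21977 +
                parcel_idx * 7919 + participant_idx) %% 2147483629 + 1)
}

#' Permutation index matrix
#'
#' Draws `n_perm` independent uniform permutations of `1:n_items` under a
#' fixed seed; row j is the j-th shuffle of earlier-scene identities.
#'
#' @param n_items pool size being permuted.
#' @param n_perm number of permutations.
#' @param seed integer seed for this substream.
#' @return integer matrix `n_perm` x `n_items`.
#' @export
perm_indices <- function(n_items, n_perm, seed) {
  set.seed(seed)
  out <- matrix(0L, n_perm, n_items)
  for (i in seq_len(n_perm)) out[i, ] <- sample.int(n_items)
  out
}

# Shared geometry of the pairing structure on the scene pool.
pair_geometry <- function(pp) {
  pool_ids <- pp$pool$scene_id
  S <- length(pool_ids)
  pool_index <- stats::setNames(seq_len(S), pool_ids)
  cue <- pp$megas[pp$megas$mega_id %in% pp$pairs$mega_id, ]
  M <- nrow(cue)
  W <- matrix(0, S, M)
  for (m in seq_len(M)) {
    rows <- pool_index[as.character(cue$members[[m]])]
    W[rows, m] <- 1 / length(rows)
  }
  cued <- sort(unique(pp$pairs$earlier_scene))
  f <- match(pp$pairs$earlier_scene, cued)
  # scene x pair averaging matrix for pair -> scene aggregation
  A <- matrix(0, length(cued), length(f))
  A[cbind(f, seq_along(f))] <- 1
  A <- A / rowSums(A)
  list(S = S, M = M, W = W,
       m_idx = match(pp$pairs$mega_id, cue$mega_id),
       s_idx = unname(pool_index[as.character(pp$pairs$earlier_scene)]),
       earlier_scene = pp$pairs$earlier_scene,
       cued = cued, agg = A,
       n_pairs_per_scene = as.integer(table(f)))
}

# z-scores of the true contrast against the permutation null for one
# (participant, parcel) cell. D is the megas x pool contrast matrix.
permutation_z_cell <- function(D, geom, perms) {
  true_val <- D[cbind(geom$m_idx, geom$s_idx)]
  idx <- (perms[, geom$s_idx, drop = FALSE] - 1L) * nrow(D)
  idx <- idx + rep(geom$m_idx, each = nrow(perms))
  vals <- matrix(D[as.vector(idx)], nrow(perms), length(geom$m_idx))
  mu <- colMeans(vals)
  sdv <- col_sds(vals)
  if (any(sdv == 0)) {
    abort("degenerate permutation null (sd = 0); increase pool variability")
  }
  (true_val - mu) / sdv
}

#' Permutation-z reactivation scores
#'
#' Computes the pipeline's central quantity. For every music-group
#' participant, parcel and cue pair, the *raw* score is the Pearson
#' correlation (across voxels) between the participant's later mega-scene
#' pattern and the no-music group's average pattern for a strictly-earlier
#' same-song scene. A leave-one-out *baseline* computed entirely within the
#' no-music group (each held-out no-music participant's mega-scene pattern
#' against the remaining participants' average earlier-scene pattern,
#' averaged over held-out participants) is subtracted, yielding the
#' *contrast*. The contrast is z-scored against a null distribution formed
#' by shuffling earlier-scene identities among all repeated-music scenes
#' (`n_perm` shuffles, applied identically inside the raw and baseline
#' terms since both live on the same scene pool). Pair-level z values are
#' finally averaged per cued earlier scene.
#'
#' With `mode = "nomusic_control"` the identical machinery runs entirely
#' within the no-music group: each held-out no-music participant takes the
#' subject role (their raw score uses the average of the *other* no-music
#' participants), and that participant is also excluded from the baseline
#' computation.
#'
#' @param pp a [pool_patterns()] object (or a `sim_dataset`, which is
#'   converted on the fly).
#' @param n_perm number of shuffles (>= 100; the reference analysis uses
#'   1000).
#' @param seed master seed; per-(participant, parcel) substreams are
#'   derived via [substream_seed()].
#' @param mode `"cross_group"` (music vs no-music) or `"nomusic_control"`.
#' @param parcels parcel ids to score (default all).
#' @return tibble with one row per (participant, parcel, cued earlier
#'   scene): `participant_id`, `parcel_id`, `scene_id`, `z`, `raw`,
#'   `contrast`, `n_pairs`.
#' @export
reactivation_scores <- function(pp, n_perm = 1000, seed = 1,
                                mode = c("cross_group", "nomusic_control"),
                                parcels = NULL) {
  mode <- match.arg(mode)
  if (inherits(pp, "sim_dataset")) pp <- pool_patterns(pp)
  stopifnot(inherits(pp, "pool_patterns"))
  if (n_perm < 100) abort("`n_perm` must be >= 100")
  geom <- pair_geometry(pp)
  if (length(geom$m_idx) == 0) abort("no cue pairs: nothing to score")
  pm <- pp$groups$music
  pn <- pp$groups$nomusic
  Nn <- dim(pn)[3]
  V <- dim(pn)[1]
  parcels <- parcels %||% pp$parcel_ids
  if (mode == "cross_group" && Nn < 3) {
    abort("need >= 3 no-music participants for the leave-one-out baseline")
  }
  if (mode == "nomusic_control" && Nn < 4) {
    abort("no-music control needs >= 4 no-music participants")
  }

  pair_cells <- cbind(geom$m_idx, geom$s_idx)
  out <- vector("list", length(parcels))
  for (ki in seq_along(parcels)) {
    k <- parcels[ki]
    pn_k <- array(pn[, , , k], dim = dim(pn)[1:3])
    tot <- rowSums(pn_k, dims = 2)                       # V x S
    smega_n <- lapply(seq_len(Nn), function(j) {
      standardize_cols(matrix(pn_k[, , j], V, geom$S) %*% geom$W,
                       "mega-scene pattern")
    })
    if (mode == "cross_group") {
      subj_n <- dim(pm)[3]
      subj_ids <- dimnames(pm)[[3]]
      sa <- standardize_cols(tot / Nn, "group-average pattern")
      bl <- matrix(0, geom$M, geom$S)
      for (j in seq_len(Nn)) {
        loo <- (tot - matrix(pn_k[, , j], V, geom$S)) / (Nn - 1)
        bl <- bl + crossprod(smega_n[[j]],
                             standardize_cols(loo, "group-average pattern"))
      }
      bl <- bl / Nn
      D_of <- function(p) {
        smega_p <- standardize_cols(
          matrix(pm[, , p, k], V, geom$S) %*% geom$W, "mega-scene pattern")
        C_p <- crossprod(smega_p, sa)
        list(C = C_p, D = C_p - bl)
      }
    } else {
      subj_n <- Nn
      subj_ids <- dimnames(pn)[[3]]
      D_of <- function(p) {
        own <- matrix(pn_k[, , p], V, geom$S)
        avg_excl <- standardize_cols((tot - own) / (Nn - 1),
                                     "group-average pattern")
        C_p <- crossprod(smega_n[[p]], avg_excl)
        bl <- matrix(0, geom$M, geom$S)
        for (j in setdiff(seq_len(Nn), p)) {
          loo <- (tot - own - matrix(pn_k[, , j], V, geom$S)) / (Nn - 2)
          bl <- bl + crossprod(smega_n[[j]],
                               standardize_cols(loo,
                                                "group-average pattern"))
        }
        list(C = C_p, D = C_p - bl / (Nn - 1))
      }
    }
    n_sc <- length(geom$cued)
    zs <- raws <- cons <- matrix(NA_real_, n_sc, subj_n)
    for (p in seq_len(subj_n)) {
      cd <- D_of(p)
      perms <- perm_indices(geom$S, n_perm, substream_seed(seed, p, k))
      z_pair <- permutation_z_cell(cd$D, geom, perms)
      zs[, p] <- geom$agg %*% z_pair
      raws[, p] <- geom$agg %*% cd$C[pair_cells]
      cons[, p] <- geom$agg %*% cd$D[pair_cells]
    }
    out[[ki]] <- tibble::tibble(
      participant_id = rep(subj_ids, each = n_sc),
      parcel_id = k,
      scene_id = rep(geom$cued, subj_n),
      z = as.vector(zs), raw = as.vector(raws),
      contrast = as.vector(cons),
      n_pairs = rep(geom$n_pairs_per_scene, subj_n)
    )
  }
  dplyr::bind_rows(out)
}
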