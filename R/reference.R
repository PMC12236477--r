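#' Straight-line reference implementation of reactivation scoring
#'
#' A deliberately naive re-implementation of the reactivation pipeline used
#' to validate the optimized engine: every pattern, correlation, baseline
#' and shuffled contrast is materialized explicitly with plain loops and
#' [stats::cor()]. It shares only the permutation substream helpers
#' ([substream_seed()], [perm_indices()]) with the pipeline, so that both
#' see the same shuffle sequence; everything else is computed
#' independently. On identical inputs the pipeline must reproduce these
#' scores to within floating-point noise.
#'
#' @inheritParams reactivation_scores
#' @param dataset a `sim_dataset`.
#' @return tibble in the same layout as [reactivation_scores()].
#' @export
reference_reactivation_scores <- function(dataset, n_perm = 1000, seed = 1,
                                          mode = c("cross_group",
                                                   "nomusic_control")) {
  mode <- match.arg(mode)
  scenes <- dataset$scenes
  pool <- repeated_music_scenes(scenes)
  megas <- build_megascenes(scenes)
  pairs <- enumerate_pairs(scenes, megas)
  TR_s <- dataset$config$TR_s
  S <- nrow(pool)

  pat_of <- function(mat, scene_row) {
    onsets <- (seq_len(ncol(mat)) - 1) * TR_s
    sel <- onsets >= scene_row$start_s & onsets < scene_row$end_s
    rowMeans(mat[, sel, drop = FALSE])
  }
  mega_pat <- function(mat, members) {
    ps <- sapply(members, function(sid) {
      pat_of(mat, pool[pool$scene_id == sid, ])
    })
    rowMeans(as.matrix(ps))
  }

  cue_megas <- megas[megas$mega_id %in% pairs$mega_id, ]
  subj_grp <- if (mode == "cross_group") "music" else "nomusic"
  subj_list <- dataset$series[[subj_grp]]
  comp_list <- dataset$series$nomusic
  Nn <- length(comp_list)
  K <- dim(subj_list[[1]])[3]

  rows <- list()
  for (k in seq_len(K)) {
    comp_scene <- lapply(comp_list, function(a) {
      sapply(seq_len(S), function(s) pat_of(a[, , k], pool[s, ]))
    })
    comp_mega <- lapply(comp_list, function(a) {
      lapply(seq_len(nrow(cue_megas)), function(m) {
        mega_pat(a[, , k], cue_megas$members[[m]])
      })
    })
    for (p in seq_along(subj_list)) {
      # contrast matrix over (cueing mega, candidate earlier scene)
      D <- C <- matrix(NA_real_, nrow(cue_megas), S)
      for (m in seq_len(nrow(cue_megas))) {
        if (mode == "cross_group") {
          mp <- mega_pat(subj_list[[p]][, , k], cue_megas$members[[m]])
        } else {
          mp <- comp_mega[[p]][[m]]
        }
        for (s in seq_len(S)) {
          if (mode == "cross_group") {
            target <- rowMeans(sapply(seq_len(Nn), function(j) {
              comp_scene[[j]][, s]
            }))
            C[m, s] <- cor(mp, target)
            bl <- mean(sapply(seq_len(Nn), function(j) {
              loo <- rowMeans(sapply(setdiff(seq_len(Nn), j), function(jj) {
                comp_scene[[jj]][, s]
              }))
              cor(comp_mega[[j]][[m]], loo)
            }))
          } else {
            others <- setdiff(seq_len(Nn), p)
            target <- rowMeans(sapply(others, function(j) {
              comp_scene[[j]][, s]
            }))
            C[m, s] <- cor(mp, target)
            bl <- mean(sapply(others, function(j) {
              loo <- rowMeans(sapply(setdiff(others, j), function(jj) {
                comp_scene[[jj]][, s]
              }))
              cor(comp_mega[[j]][[m]], loo)
            }))
          }
          D[m, s] <- C[m, s] - bl
        }
      }
      perms <- perm_indices(S, n_perm, substream_seed(seed, p, k))
      m_idx <- match(pairs$mega_id, cue_megas$mega_id)
      s_idx <- match(pairs$earlier_scene, pool$scene_id)
      z_pair <- numeric(nrow(pairs))
      for (i in seq_len(nrow(pairs))) {
        true_val <- D[m_idx[i], s_idx[i]]
        null_vals <- sapply(seq_len(n_perm), function(j) {
          D[m_idx[i], perms[j, s_idx[i]]]
        })
        z_pair[i] <- (true_val - mean(null_vals)) / sd(null_vals)
      }
      for (sc in sort(unique(pairs$earlier_scene))) {
        sel <- pairs$earlier_scene == sc
        rows[[length(rows) + 1]] <- tibble::tibble(
          participant_id = names(subj_list)[p], parcel_id = k,
          scene_id = sc, z = mean(z_pair[sel]),
          raw = mean(C[cbind(m_idx[sel], s_idx[sel])]),
          contrast = mean(D[cbind(m_idx[sel], s_idx[sel])]),
          n_pairs = sum(sel)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
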