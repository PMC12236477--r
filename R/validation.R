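# Validation studies: fixed simulation experiments that measure the
# pipeline's statistical operating characteristics (exactness, calibration,
# specificity, power) under the named scenarios. These are the quantities
# reported by scripts/acceptance.R and asserted by the test suite.

#' Pipeline validation studies
#'
#' Each function runs a self-contained simulation experiment and returns
#' the measured quantities:
#'
#' * `validate_oracle()`: maximal absolute deviation between the optimized
#'   pipeline and the straight-line reference implementation on the tiny
#'   noise-free [scenario_oracle()] instance (both reactivation modes).
#' * `validate_null_calibration()`: on [scenario_null()] data, the
#'   one-tailed remembered-versus-forgotten rejection rate at alpha = 0.05
#'   across parcels, and the mean and variance of the pooled permutation-z
#'   scores.
#' * `validate_baseline()`: on [scenario_null()] data (both groups
#'   generated identically), the grand mean of the baseline-corrected
#'   contrast and its standard error clustered by participant.
#' * `validate_recovery()`: over replicates of [scenario_planted()], the
#'   fraction of replicates in which the five affected parcels attain
#'   exactly the top five remembered-versus-forgotten t values, the mean
#'   raw-correlation uplift in affected parcels, and the no-music control's
#'   rejection rate (with its between-replicate standard error).
#' * `validate_isc_control()`: over replicates of
#'   [scenario_encoding_only()] (recall driven only by encoding) and
#'   [scenario_encoding_plus_react()] (plus an independent
#'   reactivation-to-recall channel), the false-positive rate and the
#'   power, respectively, of the affected-parcel tests after sequential
#'   ISC residualization, plus the pre-regression effect rate under the
#'   encoding-only generator.
#'
#' @param seed master seed; replicate and analysis seeds are derived from
#'   it.
#' @param n_perm permutation count per scoring run.
#' @return a named list of measured quantities (see details above).
#' @export
validate_oracle <- function(seed = 1, n_perm = 150) {
  ds <- simulate_dataset(scenario_oracle(seed))
  pp <- pool_patterns(ds)
  devs <- vapply(c("cross_group", "nomusic_control"), function(mode) {
    if (mode == "nomusic_control" && ds$config$n_per_group < 4) {
      return(NA_real_)
    }
    a <- reactivation_scores(pp, n_perm = n_perm, seed = seed + 1,
                             mode = mode)
    b <- reference_reactivation_scores(ds, n_perm = n_perm,
                                       seed = seed + 1, mode = mode)
    key <- c("participant_id", "parcel_id", "scene_id")
    m <- dplyr::inner_join(a, b, by = key)
    max(abs(m$z.x - m$z.y), abs(m$raw.x - m$raw.y),
        abs(m$contrast.x - m$contrast.y))
  }, numeric(1))
  list(max_abs_dev = max(devs, na.rm = TRUE), n_scores = 6L)
}

#' @rdname validate_oracle
#' @param n_parcels parcels in the null study.
#' @param alpha test level whose rejection rate is measured.
#' @export
validate_null_calibration <- function(seed = 1, n_parcels = 500,
                                      n_perm = 200, alpha = 0.05) {
  ds <- simulate_dataset(scenario_null(seed, n_parcels = n_parcels))
  pp <- pool_patterns(ds)
  r <- reactivation_scores(pp, n_perm = n_perm, seed = seed + 1)
  eff <- searchlight_memory(r, ds$recall)
  list(rejection_rate = mean(eff$p < alpha),
       z_mean = mean(r$z), z_var = stats::var(r$z),
       n_parcels = n_parcels, n_scores = nrow(r))
}

#' @rdname validate_oracle
#' @export
validate_baseline <- function(seed = 1, n_parcels = 50, n_perm = 200) {
  ds <- simulate_dataset(scenario_null(seed, n_parcels = n_parcels))
  pp <- pool_patterns(ds)
  r <- reactivation_scores(pp, n_perm = n_perm, seed = seed + 1)
  by_part <- vapply(split(r$contrast, r$participant_id), mean, numeric(1))
  list(grand_mean = mean(r$contrast),
       cluster_se = sd(by_part) / sqrt(length(by_part)),
       n_participants = length(by_part))
}

#' @rdname validate_oracle
#' @param n_reps number of independent replicates.
#' @export
validate_recovery <- function(seed = 1, n_reps = 50, n_perm = 200) {
  top5 <- logical(n_reps)
  uplift <- control_rate <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    ds <- simulate_dataset(scenario_planted(seed + 1000 * i))
    pp <- pool_patterns(ds)
    r <- reactivation_scores(pp, n_perm = n_perm, seed = seed + i)
    aff <- ds$config$affected_parcels
    uplift[i] <- mean(r$raw[r$parcel_id %in% aff]) -
      mean(r$raw[!r$parcel_id %in% aff])
    eff <- searchlight_memory(r, ds$recall)
    top <- eff$parcel_id[order(-eff$t)][seq_along(aff)]
    top5[i] <- setequal(top, aff)
    ctrl <- reactivation_scores(pp, n_perm = n_perm, seed = seed + i,
                                mode = "nomusic_control")
    ceff <- searchlight_memory(ctrl, ds$recall)
    control_rate[i] <- mean(ceff$p < 0.05)
  }
  list(top5_rate = mean(top5), mean_uplift = mean(uplift),
       control_rate = mean(control_rate),
       control_rate_se = sd(control_rate) / sqrt(n_reps),
       n_reps = n_reps)
}

#' @rdname validate_oracle
#' @export
validate_isc_control <- function(seed = 1, n_reps = 20, n_perm = 200) {
  run_arm <- function(with_channel, i) {
    cfg <- scenario_encoding_only(seed + 2000 * i + with_channel,
                                  with_react_channel = with_channel == 1)
    ds <- simulate_dataset(cfg)
    pp <- pool_patterns(ds)
    r <- reactivation_scores(pp, n_perm = n_perm, seed = seed + i)
    isc <- spatial_isc(pp, "music")
    scr <- isc_memory_screen(isc, ds$recall)
    res <- suppressWarnings(residual_memory(r, ds$recall, isc, scr))
    aff <- ds$config$affected_parcels
    list(pre = res$pre_effects$p[match(aff, res$pre_effects$parcel_id)],
         post = res$effects$p[match(aff, res$effects$parcel_id)])
  }
  pre0 <- post0 <- post1 <- NULL
  for (i in seq_len(n_reps)) {
    a0 <- run_arm(0L, i)
    pre0 <- c(pre0, a0$pre); post0 <- c(post0, a0$post)
    post1 <- c(post1, run_arm(1L, i)$post)
  }
  list(pre_effect_rate = mean(pre0 < 0.05),
       fp_rate = mean(post0 < 0.05),
       power = mean(post1 < 0.05),
       n_tests = length(post0), n_reps = n_reps)
}
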