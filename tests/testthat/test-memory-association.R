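recall_for <- function(participants, scenes, remembered_ids) {
  g <- tidyr::expand_grid(participant_id = participants, scene_id = scenes)
  g$remembered <- g$scene_id %in% remembered_ids
  g
}

test_that("binning averages scores within recall bins", {
  sc <- tibble::tibble(participant_id = "p1", parcel_id = 1L,
                       scene_id = 1:3, z = c(1, 2, 0))
  rec <- recall_for("p1", 1:3, c(1, 2))
  b <- bin_scores(sc, rec)
  expect_equal(b$mean_r, 1.5)
  expect_equal(b$mean_f, 0)
  expect_equal(b$n_r + b$n_f, 3L)
  expect_true(b$complete)
  # all-remembered participant is flagged incomplete
  b2 <- bin_scores(sc, recall_for("p1", 1:3, 1:3))
  expect_false(b2$complete)
  expect_true(is.nan(b2$mean_f))
  # identical values in both bins give equal means
  sc$z <- 5
  b3 <- bin_scores(sc, rec)
  expect_equal(b3$mean_r, b3$mean_f)
  # missing recall rows error
  expect_error(bin_scores(sc, rec[rec$scene_id != 2, ]), "missing recall")
})

test_that("the paired test matches the closed-form t and flags degeneracy", {
  mk <- function(d) tibble::tibble(participant_id = paste0("p", seq_along(d)),
                                   mean_r = d, mean_f = 0,
                                   n_r = 1L, n_f = 1L, complete = TRUE)
  d <- c(0.5, 0.1, 0.4, 0.2, 0.3)
  out <- remembered_vs_forgotten(mk(d))
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(out$t, t_hand)
  expect_equal(out$p, pt(t_hand, 4, lower.tail = FALSE))
  expect_equal(out$df, 4)
  # all-zero differences: t = 0, one-tailed p = 0.5
  out0 <- remembered_vs_forgotten(mk(rep(0, 4)))
  expect_equal(out0$t, 0)
  expect_equal(out0$p, 0.5)
  # constant non-zero differences are flagged degenerate
  out1 <- remembered_vs_forgotten(mk(rep(1, 4)))
  expect_true(out1$degenerate)
  # fewer than 3 complete pairs errors
  expect_error(remembered_vs_forgotten(mk(c(1, 2))), "fewer than 3")
  # incomplete participants are dropped listwise
  bins <- mk(d)
  bins$complete[1] <- FALSE
  out2 <- remembered_vs_forgotten(bins)
  expect_equal(out2$n, 4L)
  expect_equal(out2$n_dropped, 1L)
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(fdr_adjust(0.04), 0.04)          # m = 1 leaves p unchanged
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone in sorted-p order
  set.seed(1)
  p <- runif(20)
  q <- fdr_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("searchlight corrects only within the stated correction set", {
  set.seed(2)
  n_p <- 8
  sc <- tidyr::expand_grid(participant_id = paste0("p", 1:n_p),
                           parcel_id = 1:4, scene_id = 1:6)
  sc$z <- rnorm(nrow(sc))
  rec <- recall_for(paste0("p", 1:n_p), 1:6, c(1, 3, 5))
  out <- searchlight_memory(sc, rec, correction_set = 1:2)
  expect_true(all(is.na(out$q[out$parcel_id %in% 3:4])))
  expect_false(any(is.na(out$q[out$parcel_id %in% 1:2])))
  # correction set of one parcel: q equals p there
  out1 <- searchlight_memory(sc, rec, correction_set = 2)
  expect_equal(out1$q[out1$parcel_id == 2], out1$p[out1$parcel_id == 2])
  # requesting a parcel with no scores errors
  expect_error(searchlight_memory(sc, rec, parcel_set = 1:9), "parcel")
})

test_that("ROI effects aggregate member parcels before binning", {
  set.seed(3)
  n_p <- 10
  sc <- tidyr::expand_grid(participant_id = paste0("p", 1:n_p),
                           parcel_id = 1:3, scene_id = 1:8)
  sc$z <- rnorm(nrow(sc))
  rec <- recall_for(paste0("p", 1:n_p), 1:8, c(1, 2, 5, 7))
  # single-parcel ROI reproduces the searchlight result
  roi1 <- roi_memory(sc, rec, tibble::tibble(parcel_id = 2L, roi_id = "r"))
  sl <- searchlight_memory(sc, rec, parcel_set = 2)
  expect_equal(roi1$t, sl$t)
  expect_equal(roi1$p, sl$p)
  # two parcels with identical scores give the same t as either alone
  dup <- sc[sc$parcel_id %in% 1:2, ]
  dup$z[dup$parcel_id == 2] <- dup$z[dup$parcel_id == 1]
  roi2 <- roi_memory(dup, rec,
                     tibble::tibble(parcel_id = 1:2, roi_id = "r"))
  sl1 <- searchlight_memory(dup, rec, parcel_set = 1)
  expect_equal(roi2$t, sl1$t)
  # two-parcel ROI equals direct computation on parcel-mean scores
  roi3 <- roi_memory(sc, rec, tibble::tibble(parcel_id = c(1L, 3L),
                                             roi_id = "r"))
  avg <- dplyr::summarise(
    dplyr::group_by(sc[sc$parcel_id %in% c(1, 3), ],
                    participant_id, scene_id),
    z = mean(z), .groups = "drop"
  )
  direct <- remembered_vs_forgotten(bin_scores(avg, rec))
  expect_equal(roi3$t, direct$t)
})

test_that("type-I error of the paired test is nominal on null data", {
  # many independent null parcels; rejection rate should be ~alpha
  set.seed(4)
  n_p <- 12; n_parcel <- 400
  sc <- tidyr::expand_grid(participant_id = paste0("p", 1:n_p),
                           parcel_id = seq_len(n_parcel), scene_id = 1:10)
  sc$z <- rnorm(nrow(sc))
  rec <- recall_for(paste0("p", 1:n_p), 1:10, c(1, 2, 3, 7, 9))
  out <- searchlight_memory(sc, rec)
  rate <- mean(out$p < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n_parcel)
  expect_gt(rate, ci[1])
  expect_lt(rate, ci[2])
})
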