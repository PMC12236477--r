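test_that("spatial ISC is a leave-one-out correlation", {
  ds <- quick_dataset(seed = 31, n_per_group = 4)
  pp <- pool_patterns(ds)
  isc <- spatial_isc(pp, condition = "music")
  # direct recomputation for one cell
  arr <- pp$groups$music
  own <- arr[, 3, 2, 1]
  loo <- rowMeans(arr[, 3, -2, 1])
  cell <- isc$r[isc$participant_id == "m02" &
                  isc$scene_id == pp$pool$scene_id[3] &
                  isc$parcel_id == 1]
  expect_equal(cell, cor(own, loo))
  expect_true(all(abs(isc$r) <= 1))
  # a participant equal to the mean of the others has r = 1
  arr2 <- arr
  arr2[, , 1, 1] <- rowMeans(arr2[, , -1, 1], dims = 2)
  pp2 <- pp; pp2$groups$music <- arr2
  isc2 <- spatial_isc(pp2, condition = "music", parcels = 1)
  expect_equal(isc2$r[isc2$participant_id == "m01"],
               rep(1, nrow(pp$pool)), tolerance = 1e-10)
  # orthogonalized participant has r ~ 0
  v <- arr[, 1, 1, 1]
  m <- rowMeans(arr[, 1, -1, 1])
  arr3 <- arr
  arr3[, 1, 1, 1] <- v - m * sum(v * (m - mean(m))) /
    sum(m * (m - mean(m)))
  pp3 <- pp; pp3$groups$music <- arr3
  isc3 <- spatial_isc(pp3, condition = "music", parcels = 1)
  expect_lt(abs(isc3$r[isc3$participant_id == "m01" &
                         isc3$scene_id == pp$pool$scene_id[1]]), 1e-8)
})

test_that("ISC requires at least 3 participants per condition", {
  ds <- quick_dataset(n_per_group = 2)
  expect_error(spatial_isc(pool_patterns(ds)), ">= 3 participants")
})

test_that("the ISC screen selects parcels below the threshold", {
  ds <- quick_dataset(seed = 32, n_per_group = 12, n_parcels = 3)
  pp <- pool_patterns(ds)
  isc <- spatial_isc(pp, "music")
  scr <- isc_memory_screen(isc, ds$recall, p_threshold = 1)
  expect_equal(scr$regions, 1:3)  # threshold 1 selects everything
  scr0 <- isc_memory_screen(isc, ds$recall, p_threshold = 1e-12)
  expect_length(scr0$regions, 0)
  expect_equal(nrow(scr$effects), 3)
  expect_false(is.unsorted(scr$regions))
})

test_that("sequential residualization follows OLS algebra", {
  scores <- tibble::tibble(participant_id = "p1", parcel_id = 1L,
                           scene_id = 1:6,
                           z = c(2, 4, 6, 8, 10, 12))
  mk_isc <- function(vals, parcel) {
    tibble::tibble(condition = "music", participant_id = "p1",
                   scene_id = 1:6, parcel_id = parcel, r = vals)
  }
  # no regions: unchanged
  expect_equal(sequential_residualize(scores, mk_isc(rnorm(6), 5L),
                                      integer(0)), scores)
  # predictor proportional to scores: residuals all but vanish
  out <- sequential_residualize(scores, mk_isc(scores$z / 2, 5L), 5L)
  expect_equal(out$z, rep(0, 6), tolerance = 1e-12)
  # orthogonal centred predictors remove only the intercept
  x1 <- c(1, -1, 1, -1, 1, -1)
  x2 <- c(1, 1, -1, -1, 1, -1) * 0  # constant: skipped with warning
  z0 <- c(3, 3, -3, -3, 3, -3)
  sc2 <- scores; sc2$z <- z0
  pred <- dplyr::bind_rows(mk_isc(x1, 5L), mk_isc(x2, 6L))
  expect_warning(out2 <- sequential_residualize(sc2, pred, c(5L, 6L)),
                 "constant")
  fit <- lm(z0 ~ x1)
  expect_equal(out2$z, unname(residuals(fit)), tolerance = 1e-12)
  # residuals are orthogonal to every (non-constant) predictor used
  expect_lt(abs(cor(out2$z, x1)), 1e-10)
})

test_that("sequential steps with orthogonal centred predictors equal joint OLS", {
  set.seed(7)
  n <- 12
  x1 <- scale(rnorm(n))[, 1]
  x2 <- unname(scale(residuals(lm(rnorm(n) ~ x1)))[, 1])  # orthogonal to x1
  y <- 1 + 2 * x1 - x2 + rnorm(n)
  scores <- tibble::tibble(participant_id = "p1", parcel_id = 1L,
                           scene_id = 1:n, z = y)
  isc <- dplyr::bind_rows(
    tibble::tibble(condition = "music", participant_id = "p1",
                   scene_id = 1:n, parcel_id = 5L, r = x1),
    tibble::tibble(condition = "music", participant_id = "p1",
                   scene_id = 1:n, parcel_id = 6L, r = x2)
  )
  seq_out <- sequential_residualize(scores, isc, c(5L, 6L))
  joint <- residuals(lm(y ~ x1 + x2))
  expect_equal(seq_out$z, unname(joint), tolerance = 1e-10)
  # final residuals are orthogonal to the last predictor
  expect_lt(abs(cor(seq_out$z, x2)), 1e-8)
})

test_that("residual re-analysis leaves scores untouched with no regions", {
  ds <- quick_dataset(seed = 33, n_per_group = 8, n_parcels = 2)
  pp <- pool_patterns(ds)
  r <- reactivation_scores(pp, n_perm = 100, seed = 2)
  isc <- spatial_isc(pp, "music")
  out <- residual_memory(r, ds$recall, isc, integer(0))
  expect_equal(out$effects$t, out$pre_effects$t)
  expect_equal(out$comparison$t_pre, out$comparison$t_post)
})
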