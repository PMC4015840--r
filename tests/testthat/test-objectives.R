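test_that("difference-of-means coefficients match hand arithmetic", {
  # A trials all (1,0), B trials all (0,1)
  slice <- cbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  labels <- c(1, 1, 2, 2)
  expect_equal(diff_of_means_objective(slice, labels, PAIR), c(1, -1))

  # equal class means -> exact zero vector
  slice2 <- cbind(c(1, 2), c(3, 4), c(3, 4), c(1, 2))
  expect_equal(diff_of_means_objective(slice2, labels, PAIR), c(0, 0))

  # A = {(2,0),(0,2)}, B = {(-2,0),(0,-2)}: means (1,1) and (-1,-1) -> (2,2)
  slice3 <- cbind(c(2, 0), c(0, 2), c(-2, 0), c(0, -2))
  expect_equal(diff_of_means_objective(slice3, labels, PAIR), c(2, 2))

  # antisymmetry in the pair
  expect_equal(diff_of_means_objective(slice3, labels, condition_pair(2, 1)),
               -c(2, 2))

  # empty class identifies which condition is missing
  expect_error(diff_of_means_objective(slice3, rep(1, 4), PAIR), "'b'")
})

test_that("the vectorized fold evaluator agrees with per-sample evaluation", {
  set.seed(5)
  data <- array(rnorm(6 * 9 * 12), c(6, 9, 12))
  labels <- rep(c(1L, 2L), 6)
  obj <- objective_diff_of_means(PAIR)
  D_fast <- obj$evaluate_fold(data, labels, NULL, (0:8) / 100, 1:12)
  D_slow <- vapply(1:9, function(j)
    diff_of_means_objective(data[, j, ], labels, PAIR), numeric(6))
  expect_equal(D_fast, D_slow, tolerance = 1e-12)
})

test_that("windowed difference reduces, averages, and dilutes as expected", {
  eff <- small_effect(m = 4, n = 50, npc = 6, amplitude = 1, seed = 8)
  ds <- eff$dataset
  # a one-sample window equals the per-timepoint objective at that sample
  j <- resolve_window(ds$times, c(0.2, 0.21))
  expect_length(j, 1L)
  expect_equal(windowed_diff_objective(ds, PAIR, c(0.2, 0.21)),
               diff_of_means_objective(ds$data[, j, ], ds$labels, PAIR))
  # noiseless planted effect: window twice the effect length halves the
  # coefficients (averaging dilution, computed analytically)
  topo <- c(1, -1)
  x <- array(0, c(2, 40, 4))
  on <- resolve_window((0:39) / 100, c(0.1, 0.2))
  x[, on, 1:2] <- x[, on, 1:2] + topo
  dsn <- epoched_dataset(x, (0:39) / 100, labels = c(1, 1, 2, 2))
  expect_equal(windowed_diff_objective(dsn, PAIR, c(0.1, 0.2)), topo)
  expect_equal(windowed_diff_objective(dsn, PAIR, c(0.1, 0.3)), topo / 2)
  expect_error(windowed_diff_objective(dsn, PAIR, c(0.5, 0.6)), "no sample")
})

test_that("temporal difference contrasts two disjoint windows", {
  times <- (0:59) / 100
  # linear ramp slope 1/s on channel 2 only; window centers 0.4 s apart
  x <- array(0, c(3, 60, 5))
  for (k in 1:5) x[2, , k] <- times
  ds <- epoched_dataset(x + 0, times, labels = c(1, 1, 1, 2, 2))
  wa <- c(0.40, 0.50); wb <- c(0.00, 0.10)   # window means 0.445 and 0.045
  got <- temporal_difference_objective(ds, wa, wb)
  expect_equal(got, c(0, 0.4, 0))
  # constant signal -> zero vector
  dsc <- epoched_dataset(array(3, c(3, 60, 5)), times, labels = c(1, 1, 1, 2, 2))
  expect_equal(temporal_difference_objective(dsc, wa, wb), rep(0, 3))
  expect_error(temporal_difference_objective(ds, c(0, 0.2), c(0.1, 0.3)),
               "disjoint")
})

test_that("temporal-difference coefficients localize to ramped channels", {
  set.seed(11)
  times <- (0:59) / 100
  x <- array(rnorm(4 * 60 * 40, sd = 0.01), c(4, 60, 40))
  for (k in 1:40) for (ch in c(1, 3)) x[ch, , k] <- x[ch, , k] + times
  ds <- epoched_dataset(x, times, labels = rep(c(1, 2), 20))
  got <- temporal_difference_objective(ds, c(0.4, 0.5), c(0.0, 0.1))
  expect_equal(got[c(1, 3)], c(0.4, 0.4), tolerance = 0.01)
  expect_lt(max(abs(got[c(2, 4)])), 0.01)
})

test_that("the RT predictor codes closed intervals with RT2 precedence", {
  times <- (0:99) / 100
  p <- make_rt_predictor(rt1 = 0.5, rt2 = NaN, times)
  expect_identical(which(p$values[1, ] == -1),
                   which(times >= 0.3 & times <= 0.55))
  expect_true(all(p$values[1, times < 0.3 | times > 0.55] == 0))
  # both RTs missing -> all-zero row
  p2 <- make_rt_predictor(NaN, NaN, times)
  expect_true(all(p2$values == 0))
  # overlapping windows: +1 wins on the overlap (enumerated under the rule)
  p3 <- make_rt_predictor(0.5, 0.6, times)
  overlap <- times >= 0.4 & times <= 0.55
  expect_true(all(p3$values[1, overlap] == 1))
  expect_true(all(p3$values[1, times >= 0.3 & times < 0.4] == -1))
  expect_error(make_rt_predictor(0.5, 0.6, times, pre_s = -0.1), "non-negative")
})

test_that("whole-epoch regression recovers planted slopes", {
  times <- (0:49) / 100
  pred <- make_rt_predictor(rt1 = rep(0.2, 8), rt2 = rep(0.4, 8), times)
  n <- 50; p <- 8
  x <- array(0, c(3, n, p))
  for (k in 1:p) {
    x[1, , k] <- pred$values[k, ]              # beta exactly 1
    x[2, , k] <- 2 * pred$values[k, ] + 3      # affine: beta 2
  }
  ds <- epoched_dataset(x, times, labels = rep(c(1, 2), 4))
  beta <- temporal_regression_objective(ds, pred)
  expect_equal(beta[1:2], c(1, 2))
  expect_equal(beta[3], 0)
  # uncorrelated noise: beta near zero within a few OLS standard errors
  set.seed(21)
  x[3, , ] <- rnorm(n * p)
  dsn <- epoched_dataset(x, times, labels = rep(c(1, 2), 4))
  se <- 1 / sqrt(sum((pred$values - mean(pred$values))^2))
  expect_lt(abs(temporal_regression_objective(dsn, pred)[3]), 4 * se)
  # seeded parameter recovery: data = alpha * predictor + noise
  set.seed(22)
  alpha <- c(0.5, -1.5, 3)
  xr <- array(rnorm(3 * n * p, sd = 0.1), c(3, n, p))
  for (k in 1:p) xr[, , k] <- xr[, , k] + outer(alpha, pred$values[k, ])
  dsr <- epoched_dataset(xr, times, labels = rep(c(1, 2), 4))
  expect_equal(temporal_regression_objective(dsr, pred), alpha,
               tolerance = 4 * 0.1 * se / min(abs(alpha)))
  # constant predictor errors
  flat <- structure(list(values = matrix(1, p, n), description = "flat"),
                    class = "temporal_predictor")
  expect_error(temporal_regression_objective(ds, flat), "constant")
})

test_that("objectives are equivariant to channel permutation", {
  set.seed(31)
  ds <- small_effect(m = 6, n = 30, npc = 5, seed = 31)$dataset
  perm <- sample(6)
  dsp <- ds
  dsp$data <- ds$data[perm, , ]
  dsp$channel_names <- ds$channel_names[perm]
  dsp$channel_groups <- ds$channel_groups[perm]
  expect_equal(diff_of_means_objective(dsp$data[, 25, ], dsp$labels, PAIR),
               diff_of_means_objective(ds$data[, 25, ], ds$labels, PAIR)[perm])
  expect_equal(windowed_diff_objective(dsp, PAIR, c(0.2, 0.3)),
               windowed_diff_objective(ds, PAIR, c(0.2, 0.3))[perm])
  expect_equal(temporal_difference_objective(dsp, c(0.2, 0.25), c(0, 0.05)),
               temporal_difference_objective(ds, c(0.2, 0.25), c(0, 0.05))[perm])
})
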