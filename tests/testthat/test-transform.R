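test_that("normalization returns unit vectors and flags exact nulls", {
  nf <- normalize_filter(c(3, 4))
  expect_equal(nf$w, c(0.6, 0.8))
  expect_false(nf$degenerate)
  expect_equal(normalize_filter(c(1, -1))$w, c(1, -1) / sqrt(2))
  z <- normalize_filter(c(0, 0))
  expect_true(z$degenerate)
  expect_equal(z$w, c(0, 0))
  expect_error(normalize_filter(c(1, NaN)), "finite")
})

test_that("projection is the plain dot product with length checking", {
  expect_equal(project_topography(c(1, 2), c(0.6, 0.8)), 2.2)
  expect_equal(project_topography(c(1, 1), c(1, -1) / sqrt(2)), 0)
  expect_equal(project_topography(c(5, 7, 9), c(1, 0, 0)), 5)
  expect_error(project_topography(c(1, 2), c(1, 2, 3)), "lengths")
})

test_that("fold assignment partitions trials under every scheme", {
  labels <- rep(c(1L, 2L), each = 6)
  for (scheme in list(cv_scheme("loo"), cv_scheme("loopc"),
                      cv_scheme("kfold", k = 4, seed = 2),
                      cv_scheme("loso", subject_ids = rep(1:3, 4)))) {
    folds <- cv_folds(scheme, labels)
    expect_identical(sort(unlist(folds)), 1:12)
  }
  # k-fold stratification: class counts per fold differ by at most 1
  folds <- cv_folds(cv_scheme("kfold", k = 4, seed = 2), labels)
  per_class <- sapply(folds, function(f) sum(labels[f] == 1))
  expect_lte(max(per_class) - min(per_class), 1L)
  # seeded reproducibility
  expect_identical(folds, cv_folds(cv_scheme("kfold", k = 4, seed = 2), labels))
  # loopc demands balance
  expect_error(cv_folds(cv_scheme("loopc"), c(1L, 1L, 1L, 2L)),
               "balance_trial_counts")
})

test_that("the 4-trial hand enumeration is reproduced fold by fold", {
  res <- ems_transform(hand_dataset(), objective_diff_of_means(PAIR))
  expect_equal(as.vector(res$surrogates$values), hand_surrogates)
  expect_equal(res$filters$filters[, 1, ], hand_filters)
  expect_false(any(res$surrogates$degenerate))
  ec <- effect_time_course(res$surrogates, PAIR)
  expect_equal(ec$difference, 4 / sqrt(10))
  # leave-one-out-per-condition on the same data keeps class-paired folds
  res2 <- ems_transform(hand_dataset(), objective_diff_of_means(PAIR),
                        cv_scheme("loopc"))
  expect_equal(dim(res2$filters$filters)[3], 2L)
  expect_norms_unit(res2$filters)
})

test_that("an exact null yields degenerate filters and zero surrogates, not errors", {
  x <- array(1, c(3, 2, 4))         # identical trials: every fold difference is 0
  ds <- epoched_dataset(x, c(0, 0.01), labels = c(1, 1, 2, 2))
  res <- ems_transform(ds, objective_diff_of_means(PAIR))
  expect_true(all(res$filters$degenerate))
  expect_true(all(res$surrogates$degenerate))
  expect_true(all(res$surrogates$values == 0))
})

test_that("surrogates scale with the data while filters do not", {
  eff <- small_effect(seed = 12)
  obj <- objective_diff_of_means(PAIR)
  r1 <- ems_transform(eff$dataset, obj)
  ds2 <- eff$dataset
  ds2$data <- ds2$data * 3.7
  r2 <- ems_transform(ds2, obj)
  expect_equal(r2$surrogates$values, 3.7 * r1$surrogates$values)
  expect_equal(r2$filters$filters, r1$filters$filters)
})

test_that("no trial ever influences the filter it is projected onto", {
  eff <- small_effect(m = 6, n = 20, npc = 5, seed = 13, window = c(0.05, 0.15))
  obj <- objective_diff_of_means(PAIR)
  base <- ems_transform(eff$dataset, obj)
  # corrupt the held-out trial of a fold; that fold's filter is bit-identical
  for (fold in c(1L, 4L, 10L)) {
    ds2 <- eff$dataset
    ds2$data[, , fold] <- 1e6 * matrix(rnorm(6 * 20), 6)
    r2 <- ems_transform(ds2, obj)
    expect_identical(r2$filters$filters[, , fold], base$filters$filters[, , fold])
  }
  # same audit for a k-fold scheme: corrupt every trial of one fold
  scheme <- cv_scheme("kfold", k = 5, seed = 3)
  folds <- cv_folds(scheme, eff$dataset$labels)
  basek <- ems_transform(eff$dataset, obj, scheme)
  ds3 <- eff$dataset
  ds3$data[, , folds[[2]]] <- 100
  r3 <- ems_transform(ds3, obj, scheme)
  expect_identical(r3$filters$filters[, , 2], basek$filters$filters[, , 2])
})

test_that("surrogates are invariant to channel permutation and zero-channel padding", {
  eff <- small_effect(m = 6, n = 15, npc = 4, seed = 14, window = c(0.05, 0.1))
  obj <- objective_diff_of_means(PAIR)
  base <- ems_transform(eff$dataset, obj)
  perm <- c(4, 1, 6, 2, 5, 3)
  dsp <- eff$dataset
  dsp$data <- dsp$data[perm, , ]
  dsp$channel_names <- dsp$channel_names[perm]
  dsp$channel_groups <- dsp$channel_groups[perm]
  expect_equal(ems_transform(dsp, obj)$surrogates$values,
               base$surrogates$values, tolerance = 1e-12)
  # append an all-zero channel
  dsz <- epoched_dataset(
    aperm(array(c(aperm(eff$dataset$data, c(3, 2, 1)), rep(0, 15 * 8)),
                c(8, 15, 7)), c(3, 2, 1)),
    eff$dataset$times, eff$dataset$labels)
  expect_equal(ems_transform(dsz, obj)$surrogates$values,
               base$surrogates$values, tolerance = 1e-12)
})

test_that("the normalized difference filter maximizes the class-separation objective", {
  set.seed(41)
  for (rep in 1:8) {
    m <- sample(2:10, 1); p <- 2 * sample(2:10, 1)
    slice <- matrix(rnorm(m * p), m)
    labels <- rep(c(1L, 2L), p / 2)
    d <- diff_of_means_objective(slice, labels, PAIR)
    w_hat <- normalize_filter(d)$w
    best <- separation_value(slice, labels, PAIR, w_hat)
    rand <- matrix(rnorm(m * 200), m)
    rand <- sweep(rand, 2, sqrt(colSums(rand^2)), "/")
    vals <- apply(rand, 2, function(w) separation_value(slice, labels, PAIR, w))
    expect_true(all(vals <= best + 1e-12))
  }
})

test_that("projecting the full-data mean difference onto its own filter gives its norm", {
  eff <- small_effect(m = 7, n = 25, npc = 6, seed = 15, window = c(0.05, 0.15))
  ds <- eff$dataset
  obj <- objective_diff_of_means(PAIR)
  D <- obj$evaluate_fold(ds$data, ds$labels, NULL, ds$times, seq_along(ds$labels))
  for (j in c(1, 10, 25)) {
    d <- D[, j]
    expect_equal(project_topography(d, normalize_filter(d)$w),
                 sqrt(sum(d^2)), tolerance = 1e-10)
  }
})

test_that("transforms refuse mixed-unit sensor groups until z-scored", {
  m <- 6
  topo <- rep(1, m) / sqrt(m)
  sc <- effect_scenario(m, 20, 5,
                        components = list(effect_component(topo, c(0.05, 0.15))),
                        channel_groups = rep(1:2, each = 3),
                        group_scales = c(1, 1000), seed = 16)
  ds <- gen_effect_dataset(sc)$dataset
  obj <- objective_diff_of_means(PAIR)
  expect_error(ems_transform(ds, obj), "z-score")
  z <- zscore_by_sensor_group(ds)
  expect_silent(res <- ems_transform(z, obj))
  expect_norms_unit(res$filters)
})

test_that("too few trials per class for leave-one-out is caught", {
  x <- array(rnorm(12), c(2, 3, 2))
  ds <- epoched_dataset(x, (0:2) / 100, labels = c(1L, 2L))
  expect_error(ems_transform(ds, objective_diff_of_means(PAIR)),
               ">= 2 trials")
})

test_that("stationary filtering equals the per-timepoint transform on one sample", {
  ds <- hand_dataset()
  st <- stationary_transform(ds, objective_windowed_diff(PAIR, c(-0.001, 0.001)))
  expect_equal(as.vector(st$surrogates$values), hand_surrogates)
  expect_true(st$filters$stationary)
  expect_error(stationary_transform(ds, objective_diff_of_means(PAIR)),
               "windowed")
  expect_error(ems_transform(ds, objective_windowed_diff(PAIR, c(0, 1))),
               "per-timepoint")
})

test_that("a stationary template peaks in its window and at topography re-appearances", {
  m <- 8
  topo <- normalize_filter(c(rep(1, 4), rep(-1, 4)))$w
  sc <- effect_scenario(m, 80, 12,
                        components = list(
                          effect_component(topo, c(0.20, 0.30), amplitude = 2),
                          effect_component(topo, c(0.55, 0.65), amplitude = 1)),
                        seed = 17)
  eff <- gen_effect_dataset(sc)
  st <- stationary_transform(eff$dataset,
                             objective_windowed_diff(PAIR, c(0.20, 0.30)))
  ec <- effect_time_course(st$surrogates, PAIR)
  in_w1 <- eff$dataset$times >= 0.2 & eff$dataset$times < 0.3
  in_w2 <- eff$dataset$times >= 0.55 & eff$dataset$times < 0.65
  out_w <- eff$dataset$times < 0.15
  # maximal inside the defining window; the re-appearance (half amplitude)
  # deflects at about half the height; baseline stays near zero
  expect_gt(min(ec$difference[in_w1]), max(ec$difference[out_w]))
  expect_gt(mean(ec$difference[in_w2]), 0.25 * mean(ec$difference[in_w1]))
  expect_lt(mean(abs(ec$difference[out_w])), 0.25 * mean(ec$difference[in_w1]))
})

test_that("whitening reweights by inverse noise covariance", {
  d <- c(1, 1)
  expect_equal(whiten_filter(d, diag(2)), d)
  # equal-diagonal covariance at full shrinkage leaves the direction alone
  S <- matrix(c(2, 0.5, 0.5, 2), 2)
  w <- whiten_filter(d, S, shrinkage = 1)
  expect_equal(w / sqrt(sum(w^2)), d / sqrt(sum(d^2)))
  # closed form: diag(4, 1) down-weights the noisy channel
  expect_equal(whiten_filter(c(1, 1), diag(c(4, 1))), c(0.25, 1))
  expect_error(whiten_filter(c(1, 1), matrix(c(1, 2, 3, 4), 2)), "symmetric")
  expect_error(whiten_filter(c(1, 1), matrix(0, 2, 2), shrinkage = 0),
               "shrinkage")
  expect_error(whiten_filter(c(1, 1), diag(2), shrinkage = 2), "\\[0, 1\\]")
})

test_that("filter similarity exposes identical, opposite, and block-structured filters", {
  fs <- structure(
    list(filters = array(rep(c(0.6, 0.8), 3), c(2, 3, 1)),
         scheme = list(kind = "loo"), normalized = TRUE,
         degenerate = matrix(FALSE, 3, 1), stationary = FALSE,
         objective = "test"),
    class = "spatial_filter_set")
  expect_equal(filter_similarity(fs), matrix(1, 3, 3))
  fs$filters[, 2, 1] <- -fs$filters[, 2, 1]
  sim <- filter_similarity(fs)
  expect_equal(sim[1, 2], -1)
  expect_equal(sim, t(sim))

  # two orthogonal planted topographies in disjoint windows -> 2-block structure
  q <- qr.Q(qr(matrix(rnorm(16), 8)))[, 1:2]
  sc <- effect_scenario(8, 40, 15,
                        components = list(
                          effect_component(q[, 1], c(0.00, 0.20), amplitude = 4),
                          effect_component(q[, 2], c(0.20, 0.40), amplitude = 4)),
                        seed = 18)
  eff <- gen_effect_dataset(sc)
  res <- ems_transform(eff$dataset, objective_diff_of_means(PAIR))
  sim <- filter_similarity(res$filters)
  b1 <- eff$dataset$times < 0.2
  within <- c(sim[b1, b1][upper.tri(sim[b1, b1])],
              sim[!b1, !b1][upper.tri(sim[!b1, !b1])])
  between <- as.vector(sim[b1, !b1])
  expect_gt(mean(within), mean(between))
})

test_that("leave-one-subject-out pre-computes per-subject class means", {
  # 2 subjects x 2 classes x 2 trials; constant per (subject, class) cell so
  # the expected filter is the across-subject mean difference, computable by hand
  x <- array(0, c(2, 1, 8))
  cell_means <- list("1.1" = c(1, 0), "1.2" = c(0, 1),
                     "2.1" = c(3, 0), "2.2" = c(0, 3))
  sid <- rep(1:2, each = 4)
  lab <- rep(c(1L, 1L, 2L, 2L), 2)
  for (k in 1:8) x[, 1, k] <- cell_means[[paste(sid[k], lab[k], sep = ".")]]
  ds <- epoched_dataset(x, 0, lab)
  res <- ems_transform(ds, objective_diff_of_means(PAIR),
                       cv_scheme("loso", subject_ids = sid))
  # fold holding out subject 1 uses only subject 2: d = (3,0)-(0,3) = (3,-3)
  expect_equal(res$filters$filters[, 1, 1], c(1, -1) / sqrt(2))
  expect_equal(res$filters$filters[, 1, 2], c(1, -1) / sqrt(2))
  # surrogates: subject-1 trials projected on subject-2's filter
  expect_equal(res$surrogates$values[1, 1], sum(c(1, 0) * c(1, -1) / sqrt(2)))
})
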