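# Quantitative assessment of filtered output: effect time courses, SNR in
# decibels, SNR-versus-trial-count curves, ROI baseline filters, nested
# Gaussian naive-Bayes decoding, and component latency/duration metrics.

#' Effect time course from surrogate values
#'
#' Per sample: the mean over condition-`a` surrogate values minus the mean
#' over condition-`b` values, with a confidence half-width from a t quantile
#' on the Welch standard error of the difference.
#'
#' Note the caution on within-subject statistics: surrogate time courses from
#' a leave-one-out transform are not independent of one another (their filters
#' share almost all trials), so closed-form tests on aggregates *within* one
#' recording are anti-conservative; use seeded label-permutation resampling
#' (e.g. [permute_labels()]) instead. The half-width here is descriptive.
#'
#' @param S A `surrogate_matrix` from [ems_transform()] or
#'   [stationary_transform()].
#' @param pair A [condition_pair()].
#' @param conf_level Confidence level for the half-width (default 0.99).
#' @return Data frame with columns `time`, `difference`, `half_width`.
#' @export
effect_time_course <- function(S, pair, conf_level = 0.99) {
  stopifnot(inherits(S, "surrogate_matrix"))
  check_pair_present(S$labels, pair)
  A <- S$values[S$labels == pair$a, , drop = FALSE]
  B <- S$values[S$labels == pair$b, , drop = FALSE]
  na <- nrow(A); nb <- nrow(B)
  diff <- colMeans(A) - colMeans(B)
  va <- apply(A, 2L, stats::var) / na
  vb <- apply(B, 2L, stats::var) / nb
  se <- sqrt(va + vb)
  df <- ifelse(se > 0, (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1)),
               na + nb - 2)
  hw <- stats::qt(1 - (1 - conf_level) / 2, pmax(df, 1)) * se
  data.frame(time = S$times, difference = diff, half_width = hw)
}

#' Seeded label permutation
#'
#' Utility for building empirical null distributions of effect courses or
#' decoding accuracy: returns the condition labels in seeded random order.
#'
#' @param labels Per-trial condition ids.
#' @param seed Integer seed.
#' @return Permuted label vector of the same length.
#' @export
permute_labels <- function(labels, seed = 1L) {
  with_seed(seed, sample(labels))
}

#' Signal-to-noise ratio of a difference course in decibels
#'
#' `SNR = 10 log10((RMS_S / STD_N)^2)` where `RMS_S` is the root-mean-square
#' of the difference course over the signal window and `STD_N` its sample
#' standard deviation (n-1 denominator) over a disjoint baseline (noise)
#' window.
#'
#' @param diff_course Per-sample difference values (e.g. the `difference`
#'   column of [effect_time_course()]).
#' @param times Sample times in seconds, same length.
#' @param signal_window,noise_window Half-open windows `c(start_s, end_s)`;
#'   must be disjoint; the noise window needs >= 2 samples.
#' @return Object of class `snr_report`: `snr_db`, `rms_signal`, `sd_noise`,
#'   plus the windows.
#' @export
estimate_snr <- function(diff_course, times, signal_window, noise_window) {
  stopifnot(length(diff_course) == length(times))
  is_ <- resolve_window(times, signal_window, "signal_window")
  in_ <- resolve_window(times, noise_window, "noise_window")
  if (length(intersect(is_, in_)))
    stop("signal_window and noise_window must be disjoint", call. = FALSE)
  if (length(in_) < 2L)
    stop("noise_window needs at least 2 samples", call. = FALSE)
  rms_signal <- sqrt(mean(diff_course[is_]^2))
  sd_noise <- stats::sd(diff_course[in_])
  if (sd_noise == 0)
    stop("difference course is constant in the noise window; SNR undefined",
         call. = FALSE)
  structure(list(snr_db = 10 * log10((rms_signal / sd_noise)^2),
                 rms_signal = rms_signal, sd_noise = sd_noise,
                 signal_window = signal_window, noise_window = noise_window),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("<snr_report> %.3f dB (RMS_S = %.4g, STD_N = %.4g)\n",
              x$snr_db, x$rms_signal, x$sd_noise))
  invisible(x)
}

#' Region-of-interest spatial filter
#'
#' The ROI baseline is a special-case spatial filter: member sensors share one
#' uniform weight, all others are zero. `mode = "mean"` gives weight `1/n`
#' (exactly the ROI average); `mode = "unit"` gives `1/sqrt(n)` (the unit-norm
#' variant used when substituting the ROI for an estimated filter).
#'
#' @param member_mask Logical per-channel membership vector (>= 1 member).
#' @param mode `"mean"` or `"unit"`.
#' @return Numeric per-channel weight vector.
#' @export
roi_filter <- function(member_mask, mode = c("mean", "unit")) {
  mode <- match.arg(mode)
  member_mask <- as.logical(member_mask)
  n <- sum(member_mask)
  if (n < 1L) stop("ROI must contain at least one channel", call. = FALSE)
  w <- numeric(length(member_mask))
  w[member_mask] <- if (mode == "mean") 1 / n else 1 / sqrt(n)
  w
}

# project every trial of a dataset onto one fixed filter -> trial x sample
project_fixed_filter <- function(ds, w) {
  m <- dim(ds$data)[1L]; n <- dim(ds$data)[2L]; p <- dim(ds$data)[3L]
  t(matrix(crossprod(matrix(ds$data, m), w), n, p))
}

#' Mean SNR as a function of the number of trials averaged
#'
#' For each trial count `n`, draws `reps` seeded subsamples of `n` trials per
#' condition, computes the effect time course with either the cross-validated
#' EMS transform or a fixed unit-norm ROI filter substituted for the estimated
#' filter, measures the SNR, and averages over repetitions.
#'
#' @param ds An `epoched_dataset`.
#' @param pair A [condition_pair()].
#' @param objective Per-timepoint objective for the EMS mode; default
#'   [objective_diff_of_means()] on `pair`.
#' @param filter_mode `"ems"` or `"roi"`.
#' @param ns Integer vector of per-condition trial counts (each `>= 2` for
#'   EMS, and at most the smaller class size).
#' @param reps Repetitions per count (default 100).
#' @param seed Integer seed; subsample draws are deterministic given it.
#' @param signal_window,noise_window Passed to [estimate_snr()].
#' @param roi_mask Logical channel mask (required when `filter_mode = "roi"`).
#' @return Data frame with columns `n` and `mean_snr_db`.
#' @export
snr_vs_trial_count <- function(ds, pair, objective = NULL,
                               filter_mode = c("ems", "roi"),
                               ns, reps = 100L, seed = 1L,
                               signal_window, noise_window, roi_mask = NULL) {
  filter_mode <- match.arg(filter_mode)
  if (is.null(objective)) objective <- objective_diff_of_means(pair)
  ia <- which(ds$labels == pair$a)
  ib <- which(ds$labels == pair$b)
  check_pair_present(ds$labels, pair)
  if (max(ns) > min(length(ia), length(ib)))
    stop(sprintf("max(ns) = %d exceeds the smaller class size (%d)",
                 max(ns), min(length(ia), length(ib))), call. = FALSE)
  if (filter_mode == "roi") {
    if (is.null(roi_mask)) stop("filter_mode = 'roi' requires roi_mask", call. = FALSE)
    w_roi <- roi_filter(roi_mask, "unit")
  }
  draws <- with_seed(seed, {
    lapply(ns, function(n)
      lapply(seq_len(reps), function(r) c(sample(ia, n), sample(ib, n))))
  })
  mean_snr <- vapply(seq_along(ns), function(i) {
    snrs <- vapply(seq_len(reps), function(r) {
      sub <- subset_trials(ds, draws[[i]][[r]])
      if (filter_mode == "ems") {
        S <- ems_transform(sub, objective, cv_scheme("loo"), check = FALSE)$surrogates
        vals <- S$values
      } else {
        vals <- project_fixed_filter(sub, w_roi)
      }
      d <- colMeans(vals[sub$labels == pair$a, , drop = FALSE]) -
           colMeans(vals[sub$labels == pair$b, , drop = FALSE])
      estimate_snr(d, ds$times, signal_window, noise_window)$snr_db
    }, numeric(1))
    mean(snrs)
  }, numeric(1))
  data.frame(n = ns, mean_snr_db = mean_snr)
}

#' Nested EMS + Gaussian naive-Bayes decoding
#'
#' Classifies each time point of each trial as condition `a` or `b` using only
#' the one-dimensional filtered output, with the filter estimation nested
#' inside the classifier cross-validation so training and test sets stay
#' disjoint. Trials are first balanced across conditions; each outer iteration
#' sets aside one seeded pair of trials (one per condition), runs the EMS
#' transform (leave-one-out) on the remaining trials to obtain the per-class
#' mean and variance of the surrogate values at each sample, projects the two
#' held-out trials onto the filter estimated from all remaining trials, and
#' assigns each held-out sample to the class with the higher Gaussian
#' posterior (ties go to condition `a`). Accuracy per sample is the proportion
#' of correct decisions over the outer loop, then smoothed with a centered
#' boxcar window (edge-truncated).
#'
#' @param ds An `epoched_dataset` (>= 3 trials per condition after balancing).
#' @param pair A [condition_pair()].
#' @param objective Per-timepoint objective; default difference of class means.
#' @param smooth_s Smoothing window in seconds (default 0.050; 0 disables).
#' @param seed Integer seed (balancing and outer-loop pairing).
#' @param var_floor Variance floor for the Gaussian likelihoods; default
#'   `1e-12 * var(data)`. Floor activations are counted in the result.
#' @param filter_mode `"ems"` (default) or `"roi"`: with `"roi"` the estimated
#'   spatial filter is replaced everywhere by the fixed unit-norm ROI filter
#'   built from `roi_mask` (the ROI-GNB baseline).
#' @param roi_mask Logical channel mask (required when `filter_mode = "roi"`).
#' @return Object of class `decoding_result`: `times`, `accuracy`,
#'   `smoothed_accuracy`, `smooth_s`, `n_outer_iterations`, `n_floored`.
#' @export
nested_gnb_decode <- function(ds, pair, objective = NULL, smooth_s = 0.050,
                              seed = 1L, var_floor = NULL,
                              filter_mode = c("ems", "roi"), roi_mask = NULL) {
  filter_mode <- match.arg(filter_mode)
  if (filter_mode == "roi") {
    if (is.null(roi_mask)) stop("filter_mode = 'roi' requires roi_mask", call. = FALSE)
    w_roi <- roi_filter(roi_mask, "unit")
  }
  if (is.null(objective)) objective <- objective_diff_of_means(pair)
  keep <- balance_trial_counts(ds$labels, pair, seed = seed)
  dsb <- subset_trials(ds, keep)
  ia <- which(dsb$labels == pair$a)
  ib <- which(dsb$labels == pair$b)
  n_pc <- length(ia)
  if (n_pc < 3L)
    stop("nested decoding needs >= 3 trials per condition after balancing",
         call. = FALSE)
  if (is.null(var_floor)) var_floor <- 1e-12 * stats::var(as.vector(dsb$data))
  pairs <- with_seed(seed + 1L, cbind(sample(ia), sample(ib)))
  n <- dim(dsb$data)[2L]; p <- dim(dsb$data)[3L]
  correct <- matrix(NA, 2L * n_pc, n)
  n_floored <- 0L
  for (i in seq_len(n_pc)) {
    held <- pairs[i, ]
    train_idx <- setdiff(seq_len(p), held)
    tr <- subset_trials(dsb, train_idx)
    tr_values <- if (filter_mode == "ems")
      ems_transform(tr, objective, cv_scheme("loo"), check = FALSE)$surrogates$values
    else
      project_fixed_filter(tr, w_roi)
    va <- tr_values[tr$labels == pair$a, , drop = FALSE]
    vb <- tr_values[tr$labels == pair$b, , drop = FALSE]
    mu_a <- colMeans(va); mu_b <- colMeans(vb)
    s2_a <- apply(va, 2L, stats::var); s2_b <- apply(vb, 2L, stats::var)
    fl <- (s2_a < var_floor) | (s2_b < var_floor)
    n_floored <- n_floored + sum(fl)
    s2_a <- pmax(s2_a, var_floor); s2_b <- pmax(s2_b, var_floor)
    # filter from the full training set; held-out trials never influenced it
    if (filter_mode == "ems") {
      D <- eval_fold_matrix(objective, tr$data, tr$labels, tr$covariates,
                            tr$times, train_idx)
      nrm <- sqrt(colSums(D^2))
      deg <- nrm < 1e-12 * pmax(1, sqrt(apply(tr$data^2, 2L, sum)))
      Dhat <- sweep(D, 2L, ifelse(deg, 1, nrm), "/"); Dhat[, deg] <- 0
    } else {
      Dhat <- matrix(w_roi, dim(dsb$data)[1L], n)
    }
    for (j in 1:2) {
      s <- .colSums(dsb$data[, , held[j]] * Dhat, dim(dsb$data)[1L], n)
      ll_a <- -0.5 * log(s2_a) - (s - mu_a)^2 / (2 * s2_a)
      ll_b <- -0.5 * log(s2_b) - (s - mu_b)^2 / (2 * s2_b)
      decided_a <- ll_a >= ll_b           # tie -> condition a
      truth_a <- dsb$labels[held[j]] == pair$a
      correct[2L * (i - 1L) + j, ] <- decided_a == truth_a
    }
  }
  acc <- colMeans(correct)
  structure(list(times = dsb$times, accuracy = acc,
                 smoothed_accuracy = smooth_boxcar(acc, dsb$times, smooth_s),
                 smooth_s = smooth_s, n_outer_iterations = n_pc,
                 n_decisions_per_sample = 2L * n_pc, n_floored = n_floored),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %d samples, %d outer iterations, peak accuracy %.3f\n",
              length(x$accuracy), x$n_outer_iterations, max(x$smoothed_accuracy)))
  invisible(x)
}

#' Centered boxcar smoothing, truncated at epoch edges
#'
#' @param x Per-sample values.
#' @param times Sample times in seconds.
#' @param width_s Window width in seconds; `<=` one sample step disables.
#' @return Smoothed vector of the same length.
#' @export
smooth_boxcar <- function(x, times, width_s) {
  n <- length(x)
  if (n < 2L || width_s <= 0) return(x)
  dt <- mean(diff(times))
  h <- floor(width_s / 2 / dt + 1e-9)
  if (h < 1L) return(x)
  vapply(seq_len(n), function(j)
    mean(x[max(1L, j - h):min(n, j + h)]), numeric(1))
}

#' Peak latency and duration of a component in a time course
#'
#' The peak latency is the time of the maximum absolute value inside the
#' search window; the duration is the time span of the contiguous run of
#' samples, containing the peak, whose absolute value stays at or above
#' `threshold_frac` times the peak.
#'
#' @param course Per-sample values.
#' @param times Sample times in seconds, same length.
#' @param search_window Half-open window `c(start_s, end_s)`.
#' @param threshold_frac Fraction of the peak defining the duration (default
#'   0.5, i.e. full width at half maximum).
#' @return List with `latency_s`, `duration_s` and `defined` (`FALSE`, with
#'   `NA` metrics, when the course is identically zero in the window).
#' @export
component_metrics <- function(course, times, search_window, threshold_frac = 0.5) {
  stopifnot(length(course) == length(times),
            threshold_frac > 0, threshold_frac < 1)
  idx <- resolve_window(times, search_window, "search_window")
  v <- abs(course[idx])
  if (all(v == 0))
    return(list(latency_s = NA_real_, duration_s = NA_real_, defined = FALSE))
  pk <- which.max(v)
  thr <- threshold_frac * v[pk]
  lo <- pk
  while (lo > 1L && v[lo - 1L] >= thr) lo <- lo - 1L
  hi <- pk
  while (hi < length(v) && v[hi + 1L] >= thr) hi <- hi + 1L
  tw <- times[idx]
  list(latency_s = tw[pk], duration_s = tw[hi] - tw[lo], defined = TRUE)
}
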