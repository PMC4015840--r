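# Seeded generators producing epoched datasets with known ground truth, so
# every transform and evaluation operation is testable without a real
# recording. Defaults emulate the regime the matched filter is optimal for:
# i.i.d. Gaussian sensor noise with planted condition-specific topographies.

#' Describe one planted spatio-temporal component
#'
#' @param topography Numeric per-channel pattern.
#' @param window Numeric `c(start_s, end_s)`: when the component is active.
#' @param amplitude Scalar multiplier (data units).
#' @param class_specific If `TRUE` (default) the component is added to
#'   condition-1 trials only; otherwise to every trial.
#' @param latency_jitter_sd Per-trial Gaussian onset jitter in seconds,
#'   truncated at the epoch boundary (default 0).
#' @param shape `"boxcar"` (constant inside the window) or `"hann"` (raised
#'   cosine peaking at the window center).
#' @return Object of class `effect_component`.
#' @export
effect_component <- function(topography, window, amplitude = 1,
                             class_specific = TRUE, latency_jitter_sd = 0,
                             shape = c("boxcar", "hann")) {
  shape <- match.arg(shape)
  stopifnot(all(is.finite(topography)), length(window) == 2L,
            window[2] > window[1], latency_jitter_sd >= 0)
  structure(list(topography = as.numeric(topography), window = as.numeric(window),
                 amplitude = amplitude, class_specific = class_specific,
                 latency_jitter_sd = latency_jitter_sd, shape = shape),
            class = "effect_component")
}

#' Describe a synthetic evoked-effect scenario
#'
#' @param n_channels,n_samples,n_trials_per_class Positive dimensions.
#' @param sample_rate Sampling rate in Hz (default 100).
#' @param noise_sd Sensor noise standard deviation, scalar or one value per
#'   sensor group (must be > 0).
#' @param components List of [effect_component()]s.
#' @param seed Integer seed; generation is a pure function of seed + scenario.
#' @param channel_groups Optional per-channel group ids (default: one group).
#' @param group_scales Optional per-group unit scale multipliers applied to
#'   whole channel blocks (noise and signal), emulating sensor types recording
#'   in different units; groups with different scales get distinct unit
#'   strings so the transforms demand z-scoring.
#' @param noise_cor Optional channel x channel noise correlation matrix
#'   (default identity, i.e. i.i.d. noise) for exercising covariance
#'   whitening.
#' @param t0 Epoch start time in seconds (default 0).
#' @return Object of class `effect_scenario`.
#' @export
effect_scenario <- function(n_channels, n_samples, n_trials_per_class,
                            sample_rate = 100, noise_sd = 1,
                            components = list(), seed = 1L,
                            channel_groups = NULL, group_scales = NULL,
                            noise_cor = NULL, t0 = 0) {
  stopifnot(n_channels > 0, n_samples > 0, n_trials_per_class > 0,
            all(noise_sd > 0))
  times <- t0 + (seq_len(n_samples) - 1L) / sample_rate
  for (cmp in components) {
    stopifnot(inherits(cmp, "effect_component"),
              length(cmp$topography) == n_channels)
    if (cmp$window[1] < times[1] - 1e-9 ||
        cmp$window[2] > times[n_samples] + 1 / sample_rate + 1e-9)
      stop("component window exceeds the epoch", call. = FALSE)
  }
  if (is.null(channel_groups)) channel_groups <- rep(1L, n_channels)
  structure(list(n_channels = n_channels, n_samples = n_samples,
                 n_trials_per_class = n_trials_per_class,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 components = components, seed = as.integer(seed),
                 channel_groups = as.integer(channel_groups),
                 group_scales = group_scales, noise_cor = noise_cor, t0 = t0),
            class = "effect_scenario")
}

#' Generate a structureless Gaussian null dataset
#'
#' I.i.d. standard Gaussian data with labels assigned randomly half/half —
#' the reference input for checking that leave-one-out filtering is unbiased
#' under the null (no planted effect anywhere).
#'
#' @param n_channels,n_samples,n_trials Positive dimensions.
#' @param seed Integer seed (bit-reproducible).
#' @param sample_rate Sampling rate in Hz (default 100).
#' @param t0 Epoch start time (default 0).
#' @return An `epoched_dataset` with labels 1/2 (counts differing by at most 1).
#' @export
gen_null_dataset <- function(n_channels, n_samples, n_trials, seed = 1L,
                             sample_rate = 100, t0 = 0) {
  stopifnot(n_channels > 0, n_samples > 0, n_trials > 0)
  with_seed(seed, {
    data <- array(stats::rnorm(n_channels * n_samples * n_trials),
                  c(n_channels, n_samples, n_trials))
    labels <- sample(rep_len(c(1L, 2L), n_trials))
    epoched_dataset(data, t0 + (seq_len(n_samples) - 1L) / sample_rate, labels)
  })
}

hann_profile <- function(times, onset, len) {
  u <- (times - onset) / len
  ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
}

#' Generate a dataset with planted condition-specific topographies
#'
#' Gaussian noise plus, for each component, `amplitude * topography` added
#' during its (possibly jittered, epoch-clipped) window — on condition-1
#' trials only when `class_specific`. Labels are condition 1 for the first
#' `n_trials_per_class` trials and condition 2 for the rest.
#'
#' @param scenario An [effect_scenario()].
#' @return List with `dataset` (an `epoched_dataset`) and `truth`: per-trial
#'   component onsets (`onsets`: component x trial, `NA` where not planted),
#'   windows actually used, topographies, labels, and the count of
#'   jitter-clipped windows (`n_clipped`).
#' @export
gen_effect_dataset <- function(scenario) {
  sc <- scenario
  m <- sc$n_channels; n <- sc$n_samples; p <- 2L * sc$n_trials_per_class
  times <- sc$t0 + (seq_len(n) - 1L) / sc$sample_rate
  labels <- rep(c(1L, 2L), each = sc$n_trials_per_class)
  groups <- sc$channel_groups
  sds <- rep_len(sc$noise_sd, length(unique(groups)))
  with_seed(sc$seed, {
    if (is.null(sc$noise_cor)) {
      data <- array(stats::rnorm(m * n * p), c(m, n, p))
    } else {
      L <- chol(sc$noise_cor)
      data <- array(crossprod(L, matrix(stats::rnorm(m * n * p), m)), c(m, n, p))
    }
    for (gi in seq_along(sort(unique(groups)))) {
      g <- sort(unique(groups))[gi]
      data[groups == g, , ] <- data[groups == g, , , drop = FALSE] * sds[gi]
    }
    nc <- length(sc$components)
    onsets <- matrix(NA_real_, max(nc, 1L), p)
    n_clipped <- 0L
    for (ci in seq_len(nc)) {
      cmp <- sc$components[[ci]]
      len <- cmp$window[2] - cmp$window[1]
      trials <- if (cmp$class_specific) which(labels == 1L) else seq_len(p)
      jit <- if (cmp$latency_jitter_sd > 0)
        stats::rnorm(length(trials), 0, cmp$latency_jitter_sd) else numeric(length(trials))
      for (ti in seq_along(trials)) {
        k <- trials[ti]
        onset <- cmp$window[1] + jit[ti]
        lo <- times[1]; hi <- times[n] + 1 / sc$sample_rate - len
        if (onset < lo || onset > hi) {
          onset <- min(max(onset, lo), hi)
          n_clipped <- n_clipped + 1L
        }
        prof <- if (cmp$shape == "hann") hann_profile(times, onset, len)
                else as.numeric(times >= onset - 1e-9 & times < onset + len - 1e-9)
        active <- which(prof != 0)
        if (length(active))
          data[, active, k] <- data[, active, k] +
            cmp$amplitude * outer(cmp$topography, prof[active])
        onsets[ci, k] <- onset
      }
    }
    if (!is.null(sc$group_scales)) {
      gs <- rep_len(sc$group_scales, length(unique(groups)))
      for (gi in seq_along(sort(unique(groups)))) {
        g <- sort(unique(groups))[gi]
        data[groups == g, , ] <- data[groups == g, , , drop = FALSE] * gs[gi]
      }
      units <- stats::setNames(sprintf("unit_scale_%g", gs),
                               as.character(sort(unique(groups))))
    } else {
      units <- NULL
    }
    ds <- epoched_dataset(data, times, labels, channel_groups = groups,
                          units = units)
    list(dataset = ds,
         truth = list(onsets = onsets,
                      topographies = lapply(sc$components, `[[`, "topography"),
                      windows = lapply(sc$components, `[[`, "window"),
                      labels = labels, n_clipped = n_clipped))
  })
}

#' Generate a dual-task dataset with reaction-time-coupled components
#'
#' Emulates the structure of a psychological-refractory-period recording:
#' per target trial it draws two reaction times (RT2 > RT1, log-normal), then
#' plants (a) an *early* component with fixed onset whose duration grows with
#' RT1, (b) a *late* raised-cosine component of fixed duration whose peak
#' latency grows with RT1, and (c) response-locked activity with a lateralized
#' topography of opposite sign around RT1 and RT2 (the two responses being
#' made with opposite hands). Control trials contain only noise and have
#' missing (`NaN`) reaction times.
#'
#' @param n_channels,n_samples Positive dimensions (default 20 x 200).
#' @param sample_rate Hz (default 100; default epoch 0 to 2 s).
#' @param n_trials_per_class Target and control trial count (default 20).
#' @param noise_sd Gaussian noise SD (> 0).
#' @param seed Integer seed.
#' @param rt1_meanlog,rt1_sdlog Log-normal parameters of RT1 in seconds.
#' @param gap_meanlog,gap_sdlog Log-normal parameters of RT2 - RT1.
#' @param early_onset,early_dur_base,early_dur_slope Early component: onset
#'   (s), duration = `early_dur_base + early_dur_slope * RT1`.
#' @param late_latency_base,late_latency_slope,late_dur Late component: peak
#'   latency = `late_latency_base + late_latency_slope * RT1`, fixed duration.
#' @param resp_pre,resp_post Response-locked window extent around each RT.
#' @param amplitude Component amplitude in noise-SD units.
#' @param max_redraws Bounded retries when a draw would exceed the epoch.
#' @return List with `dataset` (covariates `rt1`, `rt2`) and `truth`
#'   (per-trial `rt1`, `rt2`, `early_duration`, `late_latency`; topographies
#'   `top_early`, `top_late`, `top_resp`; `n_redrawn`).
#' @export
gen_rt_dataset <- function(n_channels = 20L, n_samples = 200L, sample_rate = 100,
                           n_trials_per_class = 20L, noise_sd = 1, seed = 1L,
                           rt1_meanlog = log(0.45), rt1_sdlog = 0.20,
                           gap_meanlog = log(0.55), gap_sdlog = 0.15,
                           early_onset = 0.10, early_dur_base = 0.05,
                           early_dur_slope = 0.5,
                           late_latency_base = 0.20, late_latency_slope = 1.0,
                           late_dur = 0.15,
                           resp_pre = 0.200, resp_post = 0.050,
                           amplitude = 1, max_redraws = 100L) {
  stopifnot(noise_sd > 0)
  m <- n_channels; n <- n_samples; p <- 2L * n_trials_per_class
  times <- (seq_len(n) - 1L) / sample_rate
  t_end <- times[n]
  labels <- rep(c(1L, 2L), each = n_trials_per_class)
  with_seed(seed, {
    top_resp <- rep(c(1, -1), length.out = m) / sqrt(m)   # lateralized: half +, half -
    # early/late topographies orthogonal to the response pattern and each
    # other, so each matched projection isolates its own component
    q <- qr.Q(qr(cbind(top_resp, matrix(stats::rnorm(m * 2L), m))))
    top_early <- q[, 2]
    top_late <- q[, 3]
    data <- array(stats::rnorm(m * n * p, sd = noise_sd), c(m, n, p))
    rt1 <- rep(NaN, p); rt2 <- rep(NaN, p)
    early_duration <- rep(NA_real_, p); late_latency <- rep(NA_real_, p)
    n_redrawn <- 0L
    for (k in which(labels == 1L)) {
      for (try in seq_len(max_redraws)) {
        r1 <- stats::rlnorm(1, rt1_meanlog, rt1_sdlog)
        r2 <- r1 + stats::rlnorm(1, gap_meanlog, gap_sdlog)
        ok <- (r2 + resp_post < t_end) &&
          (late_latency_base + late_latency_slope * r1 + late_dur / 2 < t_end) &&
          (early_onset + early_dur_base + early_dur_slope * r1 < t_end)
        if (ok) break
        n_redrawn <- n_redrawn + 1L
      }
      rt1[k] <- r1; rt2[k] <- r2
      # (a) early: fixed onset, duration tracks RT1 (boxcar)
      dur <- early_dur_base + early_dur_slope * r1
      early_duration[k] <- dur
      act <- times >= early_onset - 1e-9 & times < early_onset + dur - 1e-9
      data[, act, k] <- data[, act, k] + amplitude * top_early
      # (b) late: peak latency tracks RT1, fixed duration (raised cosine)
      lat <- late_latency_base + late_latency_slope * r1
      late_latency[k] <- lat
      prof <- hann_profile(times, lat - late_dur / 2, late_dur)
      act <- which(prof != 0)
      data[, act, k] <- data[, act, k] +
        amplitude * outer(top_late, prof[act])
      # (c) response-locked, opposite signs for the two hands
      act1 <- times >= r1 - resp_pre & times <= r1 + resp_post
      act2 <- times >= r2 - resp_pre & times <= r2 + resp_post
      data[, act1, k] <- data[, act1, k] - amplitude * top_resp
      data[, act2, k] <- data[, act2, k] + amplitude * top_resp
    }
    ds <- epoched_dataset(data, times, labels,
                          covariates = list(rt1 = rt1, rt2 = rt2))
    list(dataset = ds,
         truth = list(rt1 = rt1, rt2 = rt2, early_duration = early_duration,
                      late_latency = late_latency, top_early = top_early,
                      top_late = top_late, top_resp = top_resp,
                      labels = labels, n_redrawn = n_redrawn))
  })
}
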