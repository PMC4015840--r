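# Objective functions: maps from a data slice (+ labels / covariates) to one
# coefficient per channel. The per-channel coefficient vector is later
# normalized and used as a spatial filter, so an objective encodes the data
# analysis question ("what topography expresses this effect?").

#' Construct an objective specification
#'
#' An objective is the pluggable heart of effect-matched spatial filtering: any
#' map producing one finite coefficient per channel is a valid objective. Three
#' kinds exist:
#' \describe{
#'   \item{`per-timepoint`}{`evaluate(slice, labels, covariates)` is called
#'     independently at each sample with the channel x trial slice of the
#'     retained trials and must return `n_channels` coefficients.}
#'   \item{`windowed`}{`evaluate_fold(data, labels, covariates, times,
#'     trial_idx)` is called once per cross-validation fold with the full
#'     retained channel x sample x trial block and returns a single filter.}
#'   \item{`whole-epoch-regression`}{like `windowed` but fits across the whole
#'     epoch (e.g. a temporal-predictor regression).}
#' }
#' Per-timepoint objectives may additionally supply `evaluate_fold` returning a
#' channel x sample coefficient matrix as a vectorized fast path.
#'
#' @param name Identifier string.
#' @param kind One of `"per-timepoint"`, `"windowed"`, `"whole-epoch-regression"`.
#' @param evaluate The coefficient-producing function (contract above).
#' @param params Named list of parameters (kept for provenance).
#' @param evaluate_fold Optional fold-level evaluator (contract above).
#' @return Object of class `ems_objective`.
#' @export
ems_objective <- function(name, kind, evaluate, params = list(),
                          evaluate_fold = NULL) {
  kind <- match.arg(kind, c("per-timepoint", "windowed", "whole-epoch-regression"))
  stopifnot(is.function(evaluate) || is.function(evaluate_fold))
  structure(list(name = name, kind = kind, params = params,
                 evaluate = evaluate, evaluate_fold = evaluate_fold),
            class = "ems_objective")
}

#' @export
print.ems_objective <- function(x, ...) {
  cat(sprintf("<ems_objective> %s (%s)\n", x$name, x$kind))
  invisible(x)
}

check_coef <- function(d, m, name) {
  if (length(d) != m || !is.numeric(d))
    stop(sprintf("objective '%s' returned %d coefficients; expected %d",
                 name, length(d), m), call. = FALSE)
  if (!all(is.finite(d)))
    stop(sprintf("objective '%s' returned non-finite coefficients", name),
         call. = FALSE)
  as.numeric(d)
}

# ---- difference of class means ----------------------------------------------

#' Difference-of-class-means coefficients at one time point
#'
#' For each channel: mean over condition-`a` trials minus mean over
#' condition-`b` trials. This un-normalized difference topography is the
#' matched filter for the binary contrast; normalization is a separate step.
#'
#' @param slice Numeric channel x trial matrix (one time point).
#' @param labels Per-trial condition ids, length `ncol(slice)`.
#' @param pair A [condition_pair()].
#' @return Numeric vector, one coefficient per channel.
#' @export
diff_of_means_objective <- function(slice, labels, pair) {
  ia <- which(labels == pair$a)
  ib <- which(labels == pair$b)
  if (!length(ia)) stop(sprintf("condition %d ('a') has no trials in slice", pair$a),
                        call. = FALSE)
  if (!length(ib)) stop(sprintf("condition %d ('b') has no trials in slice", pair$b),
                        call. = FALSE)
  slice <- as.matrix(slice)
  rowMeans(slice[, ia, drop = FALSE]) - rowMeans(slice[, ib, drop = FALSE])
}

#' Per-timepoint difference-of-means objective
#'
#' Wraps [diff_of_means_objective()] as an [ems_objective()] for
#' [ems_transform()], with a vectorized fold evaluator that computes the
#' class-mean difference at every sample in one matrix product.
#'
#' @param pair A [condition_pair()].
#' @return An `ems_objective` of kind `"per-timepoint"`.
#' @export
objective_diff_of_means <- function(pair) {
  ems_objective(
    name = "diff_of_means", kind = "per-timepoint",
    params = list(pair = pair),
    evaluate = function(slice, labels, covariates)
      diff_of_means_objective(slice, labels, pair),
    evaluate_fold = function(data, labels, covariates, times, trial_idx) {
      ia <- which(labels == pair$a)
      ib <- which(labels == pair$b)
      if (!length(ia) || !length(ib))
        stop(sprintf("condition %d has no trials in fold",
                     if (!length(ia)) pair$a else pair$b), call. = FALSE)
      m <- dim(data)[1L]; n <- dim(data)[2L]
      xm <- matrix(data, m * n)
      ma <- xm[, ia, drop = FALSE] %*% rep(1 / length(ia), length(ia))
      mb <- xm[, ib, drop = FALSE] %*% rep(1 / length(ib), length(ib))
      matrix(ma - mb, m, n)
    })
}

# ---- windowed difference (stationary template) ------------------------------

#' Windowed difference-of-means coefficients
#'
#' Per channel: average the data over a half-open time window, then take the
#' condition-`a` minus condition-`b` class-mean difference. Yields one
#' stationary filter summarizing the contrast inside the window.
#'
#' @param ds An `epoched_dataset` (already excluding any held-out trials).
#' @param pair A [condition_pair()].
#' @param window Numeric `c(start_s, end_s)`, half-open, resolved against
#'   `ds$times`.
#' @return Numeric vector, one coefficient per channel.
#' @export
windowed_diff_objective <- function(ds, pair, window) {
  idx <- resolve_window(ds$times, window, "window")
  win_mean <- apply(ds$data[, idx, , drop = FALSE], c(1L, 3L), mean)
  diff_of_means_objective(win_mean, ds$labels, pair)
}

#' Stationary windowed-difference objective
#'
#' Wraps [windowed_diff_objective()] for [stationary_transform()].
#'
#' @inheritParams windowed_diff_objective
#' @return An `ems_objective` of kind `"windowed"`.
#' @export
objective_windowed_diff <- function(pair, window) {
  ems_objective(
    name = "windowed_diff", kind = "windowed",
    params = list(pair = pair, window = window),
    evaluate = NULL,
    evaluate_fold = function(data, labels, covariates, times, trial_idx) {
      idx <- resolve_window(times, window, "window")
      win_mean <- apply(data[, idx, , drop = FALSE], c(1L, 3L), mean)
      diff_of_means_objective(win_mean, labels, pair)
    })
}

# ---- temporal difference (readiness-potential style) ------------------------

#' Temporal-difference coefficients between two windows
#'
#' Per channel: the mean over all trials and samples of `window_a` minus the
#' mean over all trials and samples of `window_b`. Sensors whose amplitude
#' changes between the two intervals (e.g. late vs early pre-movement windows
#' for a readiness potential) receive large weights.
#'
#' @param ds An `epoched_dataset` (already excluding any held-out trials).
#' @param window_a,window_b Half-open windows in seconds; must be disjoint and
#'   nonempty.
#' @return Numeric vector, one coefficient per channel.
#' @export
temporal_difference_objective <- function(ds, window_a, window_b) {
  ia <- resolve_window(ds$times, window_a, "window_a")
  ib <- resolve_window(ds$times, window_b, "window_b")
  if (length(intersect(ia, ib)))
    stop("window_a and window_b must be disjoint", call. = FALSE)
  apply(ds$data[, ia, , drop = FALSE], 1L, mean) -
    apply(ds$data[, ib, , drop = FALSE], 1L, mean)
}

#' Stationary temporal-difference objective
#'
#' Wraps [temporal_difference_objective()] for [stationary_transform()].
#'
#' @inheritParams temporal_difference_objective
#' @return An `ems_objective` of kind `"windowed"`.
#' @export
objective_temporal_difference <- function(window_a, window_b) {
  ems_objective(
    name = "temporal_difference", kind = "windowed",
    params = list(window_a = window_a, window_b = window_b),
    evaluate = NULL,
    evaluate_fold = function(data, labels, covariates, times, trial_idx) {
      ds <- list(data = data, times = times, labels = labels)
      temporal_difference_objective(ds, window_a, window_b)
    })
}

# ---- temporal predictor + whole-epoch regression ----------------------------

#' Build a reaction-time-locked temporal predictor
#'
#' Codes each (trial, sample) entry with -1 inside the closed interval from
#' `pre_s` before to `post_s` after the first response (RT1), +1 inside the
#' corresponding interval around the second response (RT2), and 0 elsewhere.
#' When the two intervals overlap, the RT2 (+1) coding takes precedence (the
#' second response is the later event). A missing (`NaN`) reaction time leaves
#' that event's coding all-zero for the trial. Regressing sensor data on this
#' predictor isolates response-locked activity whose sign differs between the
#' two responses (e.g. opposite-hand motor fields).
#'
#' @param rt1,rt2 Per-trial reaction times in seconds (`NaN` allowed).
#' @param times Sample times in seconds.
#' @param pre_s Seconds before each response to include (default 0.200).
#' @param post_s Seconds after each response to include (default 0.050).
#' @return Object of class `temporal_predictor` with fields `values`
#'   (trial x sample matrix of -1/0/+1) and `description`.
#' @export
make_rt_predictor <- function(rt1, rt2, times, pre_s = 0.200, post_s = 0.050) {
  if (pre_s < 0 || post_s < 0)
    stop("pre_s and post_s must be non-negative", call. = FALSE)
  stopifnot(length(rt1) == length(rt2))
  p <- length(rt1); n <- length(times)
  values <- matrix(0, p, n)
  for (k in seq_len(p)) {
    if (is.finite(rt1[k]))
      values[k, times >= rt1[k] - pre_s & times <= rt1[k] + post_s] <- -1
    if (is.finite(rt2[k]))
      values[k, times >= rt2[k] - pre_s & times <= rt2[k] + post_s] <- 1
  }
  structure(list(values = values,
                 description = sprintf(
                   "-1 in [RT1-%g, RT1+%g], +1 in [RT2-%g, RT2+%g], else 0",
                   pre_s, post_s, pre_s, post_s)),
            class = "temporal_predictor")
}

#' Whole-epoch regression coefficients against a temporal predictor
#'
#' For each channel, fits an ordinary least-squares regression (single
#' predictor plus intercept) of the channel's flattened trial x sample values
#' on the flattened predictor and returns the slope. One beta per channel,
#' forming a single stationary filter.
#'
#' @param ds An `epoched_dataset` (already excluding any held-out trials).
#' @param predictor A [make_rt_predictor()] result (or any
#'   `temporal_predictor`) whose rows match the trials of `ds`.
#' @return Numeric vector of per-channel regression slopes.
#' @export
temporal_regression_objective <- function(ds, predictor) {
  m <- dim(ds$data)[1L]; n <- dim(ds$data)[2L]; p <- dim(ds$data)[3L]
  pv <- predictor$values
  if (nrow(pv) != p || ncol(pv) != n)
    stop(sprintf("predictor is %d x %d but dataset has %d trials x %d samples",
                 nrow(pv), ncol(pv), p, n), call. = FALSE)
  # flatten sample-fastest to match the channel rows of the data array
  x <- as.vector(t(pv))
  xc <- x - mean(x)
  ssx <- sum(xc^2)
  if (ssx == 0) stop("temporal predictor is constant; regression undefined",
                     call. = FALSE)
  xm <- matrix(aperm(ds$data, c(2L, 3L, 1L)), n * p, m)  # (sample*trial) x channel
  as.numeric(crossprod(xm, xc)) / ssx
}

#' Whole-epoch regression objective
#'
#' Wraps [temporal_regression_objective()] for [stationary_transform()]; the
#' predictor rows are subset to each fold's retained trials.
#'
#' @param predictor A `temporal_predictor` aligned with the full dataset.
#' @return An `ems_objective` of kind `"whole-epoch-regression"`.
#' @export
objective_temporal_regression <- function(predictor) {
  ems_objective(
    name = "temporal_regression", kind = "whole-epoch-regression",
    params = list(predictor = predictor$description),
    evaluate = NULL,
    evaluate_fold = function(data, labels, covariates, times, trial_idx) {
      sub <- list(values = predictor$values[trial_idx, , drop = FALSE])
      temporal_regression_objective(
        list(data = data, times = times, labels = labels),
        structure(sub, class = "temporal_predictor"))
    })
}
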