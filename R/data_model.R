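#' emsfilter: effect-matched spatial filtering for epoched multi-sensor data
#'
#' Reduces epoched multichannel recordings (channel x sample x trial) to a
#' single surrogate time course per trial by projecting every time sample onto
#' a unit-norm spatial filter matched to an experimental effect estimated from
#' held-out trials. See `vignette("ems-filtering")` for the method and its
#' assumptions.
#'
#' @keywords internal
"_PACKAGE"

# ---- seeded RNG scoping ------------------------------------------------------

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded package functions never disturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# ---- EpochedDataset ----------------------------------------------------------

#' Construct an epoched multi-sensor dataset
#'
#' The core container: a 3-D real array of dimension channel x sample x trial
#' together with its per-channel, per-sample and per-trial metadata. The
#' dimension order is fixed and enforced throughout the package.
#'
#' @param data 3-D numeric array, channel x sample x trial.
#' @param times Numeric vector of sample times in seconds (strictly increasing,
#'   uniform step), length `dim(data)[2]`.
#' @param labels Integer per-trial condition ids, length `dim(data)[3]`.
#' @param channel_names Optional character vector of channel names.
#' @param channel_groups Optional integer sensor-group ids per channel (e.g.
#'   magnetometers vs gradiometers). Default: one group.
#' @param covariates Optional named list of per-trial numeric vectors (e.g.
#'   reaction times); `NaN`/`NA` encodes a missing response.
#' @param units Optional named character vector mapping group id to unit string
#'   (e.g. `c("1" = "fT")`). Default `"au"` for every group.
#' @param validate If `TRUE` (default) stop when [validate_dataset()] reports
#'   violations.
#' @return An object of class `epoched_dataset`.
#' @seealso [validate_dataset()], [zscore_by_sensor_group()]
#' @export
epoched_dataset <- function(data, times, labels,
                            channel_names = NULL, channel_groups = NULL,
                            covariates = NULL, units = NULL,
                            validate = TRUE) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  m <- dim(data)[1L]
  if (is.null(channel_names)) channel_names <- sprintf("ch%03d", seq_len(m))
  if (is.null(channel_groups)) channel_groups <- rep(1L, m)
  channel_groups <- as.integer(channel_groups)
  if (is.null(units)) {
    g <- sort(unique(channel_groups))
    units <- stats::setNames(rep("au", length(g)), as.character(g))
  }
  ds <- structure(
    list(data = data, times = as.numeric(times), labels = as.integer(labels),
         channel_names = as.character(channel_names),
         channel_groups = channel_groups,
         covariates = covariates, units = units),
    class = "epoched_dataset")
  if (validate) {
    bad <- validate_dataset(ds)
    if (length(bad)) stop("invalid epoched_dataset:\n  - ",
                          paste(bad, collapse = "\n  - "), call. = FALSE)
  }
  ds
}

#' @export
print.epoched_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_dataset> %d channels x %d samples x %d trials\n",
              d[1], d[2], d[3]))
  cat(sprintf("  times: [%.4g, %.4g] s, fs = %.6g Hz\n",
              x$times[1], x$times[length(x$times)], sampling_rate(x)))
  cat("  labels:", paste(sprintf("%d (n=%d)", sort(unique(x$labels)),
                                 tabulate(factor(x$labels))), collapse = ", "), "\n")
  cat("  groups:", paste(sprintf("%s [%s]", names(x$units), x$units),
                         collapse = ", "), "\n")
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Sampling rate of a dataset in Hz
#' @param ds An `epoched_dataset`.
#' @return Scalar sampling rate, `1 / mean(diff(times))`.
#' @export
sampling_rate <- function(ds) 1 / mean(diff(ds$times))

#' Validate an epoched dataset
#'
#' Checks every container invariant and reports violations instead of raising,
#' so malformed on-disk data produce a complete diagnosis in one pass.
#'
#' @param ds An `epoched_dataset` (or a bare list with the same fields).
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_dataset <- function(ds) {
  v <- character()
  d <- dim(ds$data)
  if (is.null(d) || length(d) != 3L)
    return("data must be a 3-D array (channel x sample x trial)")
  if (any(d <= 0L)) v <- c(v, "data dimensions must all be strictly positive")
  if (!all(is.finite(ds$data))) v <- c(v, "data finite: array contains NA/NaN/Inf")
  n <- length(ds$times)
  if (n != d[2L]) v <- c(v, sprintf("times length (%d) != sample dimension (%d)", n, d[2L]))
  if (n >= 2L) {
    dt <- diff(ds$times)
    if (any(dt <= 0)) v <- c(v, "times must be strictly increasing")
    else if (max(dt) - min(dt) > 1e-9 * max(abs(dt)))
      v <- c(v, "times must have a constant sampling step")
  }
  if (!all(is.finite(ds$times))) v <- c(v, "times must be finite")
  if (length(ds$channel_names) != d[1L])
    v <- c(v, sprintf("channel_names length (%d) != channel dimension (%d)",
                      length(ds$channel_names), d[1L]))
  if (length(ds$channel_groups) != d[1L])
    v <- c(v, sprintf("channel_groups length (%d) != channel dimension (%d)",
                      length(ds$channel_groups), d[1L]))
  if (length(ds$labels) != d[3L])
    v <- c(v, sprintf("labels length (%d) != trial dimension (%d)",
                      length(ds$labels), d[3L]))
  if (anyNA(ds$labels)) v <- c(v, "labels must not contain NA")
  else if (length(unique(ds$labels)) < 1L) v <- c(v, "labels need >= 1 distinct value")
  if (!is.null(ds$covariates)) {
    if (is.null(names(ds$covariates)) || any(names(ds$covariates) == ""))
      v <- c(v, "covariates must be a named list")
    for (nm in names(ds$covariates))
      if (length(ds$covariates[[nm]]) != d[3L])
        v <- c(v, sprintf("covariate '%s' length (%d) != trial dimension (%d)",
                          nm, length(ds$covariates[[nm]]), d[3L]))
  }
  groups <- as.character(sort(unique(ds$channel_groups)))
  if (!all(groups %in% names(ds$units)))
    v <- c(v, "units must name every channel group")
  v
}

# ---- ConditionPair -----------------------------------------------------------

#' Define a pair of experimental conditions
#'
#' A binary contrast: condition `a` (the effect condition) against condition
#' `b` (the control), by label id.
#'
#' @param a,b Distinct integer condition labels.
#' @return Object of class `condition_pair` with fields `a` and `b`.
#' @export
condition_pair <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  stopifnot(length(a) == 1L, length(b) == 1L, is.finite(a), is.finite(b))
  if (a == b) stop("condition_pair: the two labels must differ", call. = FALSE)
  structure(list(a = a, b = b), class = "condition_pair")
}

check_pair_present <- function(labels, pair) {
  for (side in c("a", "b"))
    if (!any(labels == pair[[side]]))
      stop(sprintf("condition %d ('%s') has no trials", pair[[side]], side),
           call. = FALSE)
  invisible(TRUE)
}

# ---- window resolution -------------------------------------------------------

#' Resolve a half-open time window to sample indices
#'
#' Selects the samples with `window[1] <= t < window[2]` by direct comparison
#' against `times` (no rounding to indices); half-open so adjacent windows
#' never double-count a sample.
#'
#' @param times Sample times in seconds.
#' @param window Numeric length-2, `c(start_s, end_s)`.
#' @param what Label used in error messages.
#' @return Integer sample indices (possibly empty unless `require_nonempty`).
#' @param require_nonempty Stop when no sample falls in the window.
#' @export
resolve_window <- function(times, window, what = "window", require_nonempty = TRUE) {
  stopifnot(is.numeric(window), length(window) == 2L)
  if (window[2] <= window[1])
    stop(sprintf("%s: end (%g) must exceed start (%g)", what, window[2], window[1]),
         call. = FALSE)
  idx <- which(times >= window[1] & times < window[2])
  if (require_nonempty && !length(idx))
    stop(sprintf("%s [%g, %g) contains no sample", what, window[1], window[2]),
         call. = FALSE)
  idx
}

# ---- z-scoring by sensor group ----------------------------------------------

#' Z-score each sensor group over its entire data block
#'
#' Mixed sensor arrays (e.g. magnetometers and gradiometers) record in
#' different units whose ranges differ by orders of magnitude; any filter
#' spanning both would be dominated by the larger-unit group. Each group's
#' full channel-in-group x sample x trial block is therefore converted to
#' z-scores using the block mean and population standard deviation, after
#' which every group has mean 0 and standard deviation 1 and the groups are
#' commensurable.
#'
#' @param ds An `epoched_dataset`.
#' @return A new `epoched_dataset` with z-scored data and every group's unit
#'   set to `"z-score"`. Idempotent up to numerical tolerance.
#' @export
zscore_by_sensor_group <- function(ds) {
  out <- ds
  for (g in sort(unique(ds$channel_groups))) {
    ch <- which(ds$channel_groups == g)
    block <- ds$data[ch, , , drop = FALSE]
    mu <- mean(block)
    sd_pop <- sqrt(mean((block - mu)^2))
    if (sd_pop == 0)
      stop(sprintf("sensor group %s has zero variance; cannot z-score", g),
           call. = FALSE)
    out$data[ch, , ] <- (block - mu) / sd_pop
  }
  out$units[] <- "z-score"
  out
}

# ---- trial balancing ---------------------------------------------------------

#' Equalize trial counts across two conditions
#'
#' Retains every trial of the smaller class plus a seeded uniform subsample
#' (without replacement) of the larger class of equal size, as required before
#' leave-one-out-per-condition filtering or decoding.
#'
#' @param labels Per-trial condition ids.
#' @param pair A [condition_pair()].
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return Sorted integer vector of retained trial indices (original trial
#'   order preserved); equal counts per class.
#' @export
balance_trial_counts <- function(labels, pair, seed = 1L) {
  check_pair_present(labels, pair)
  ia <- which(labels == pair$a)
  ib <- which(labels == pair$b)
  n <- min(length(ia), length(ib))
  keep <- with_seed(seed, {
    if (length(ia) > n) ia <- sample(ia, n)
    if (length(ib) > n) ib <- sample(ib, n)
    c(ia, ib)
  })
  sort(keep)
}

#' Extract a subset of trials from a dataset
#'
#' @param ds An `epoched_dataset`.
#' @param idx Integer trial indices to keep (order respected).
#' @return An `epoched_dataset` restricted to those trials.
#' @export
subset_trials <- function(ds, idx) {
  out <- ds
  out$data <- ds$data[, , idx, drop = FALSE]
  out$labels <- ds$labels[idx]
  if (!is.null(ds$covariates))
    out$covariates <- lapply(ds$covariates, `[`, idx)
  out
}
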