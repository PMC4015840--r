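# The EMS transform proper: cross-validated per-timepoint filter estimation,
# unit normalization, projection, the stationary-template variant, optional
# noise-covariance whitening, and filter-set diagnostics.

# ---- cross-validation schemes ------------------------------------------------

#' Define a cross-validation scheme for filter estimation
#'
#' Every trial belongs to exactly one fold; the filter for a fold is estimated
#' from all trials outside the fold, so no trial is ever projected onto a
#' filter its own data influenced.
#'
#' @param kind `"loo"` (leave-one-out, the default), `"loopc"`
#'   (leave-one-out-per-condition; requires equal class counts, folds pair the
#'   i-th trial of each condition in original order), `"kfold"` (seeded,
#'   label-stratified), or `"loso"` (leave-one-subject-out; per-subject class
#'   means are pre-computed before differencing across retained subjects).
#' @param k Number of folds (`kfold` only).
#' @param subject_ids Per-trial subject ids (`loso` only).
#' @param seed Integer seed for fold assignment (`kfold` only).
#' @return Object of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("loo", "loopc", "kfold", "loso"),
                      k = 5L, subject_ids = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "kfold" && (!is.numeric(k) || k < 2L))
    stop("kfold requires k >= 2", call. = FALSE)
  if (kind == "loso" && is.null(subject_ids))
    stop("loso requires subject_ids", call. = FALSE)
  structure(list(kind = kind, k = as.integer(k), subject_ids = subject_ids,
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Assign trials to cross-validation folds
#'
#' @param scheme A [cv_scheme()].
#' @param labels Per-trial condition ids.
#' @return List of integer vectors: the held-out trial indices of each fold.
#'   Folds partition the trials.
#' @export
cv_folds <- function(scheme, labels) {
  p <- length(labels)
  switch(scheme$kind,
    loo = as.list(seq_len(p)),
    loopc = {
      cls <- sort(unique(labels))
      if (length(cls) != 2L)
        stop("loopc requires exactly 2 condition labels", call. = FALSE)
      ia <- which(labels == cls[1]); ib <- which(labels == cls[2])
      if (length(ia) != length(ib))
        stop("loopc requires equal class counts; use balance_trial_counts() first",
             call. = FALSE)
      Map(c, ia, ib)
    },
    kfold = {
      k <- scheme$k
      if (k > p) stop("k exceeds the number of trials", call. = FALSE)
      fold_of <- integer(p)
      with_seed(scheme$seed, {
        for (cl in unique(labels)) {
          idx <- which(labels == cl)
          idx <- if (length(idx) > 1L) sample(idx) else idx
          fold_of[idx] <- rep_len(seq_len(k), length(idx))
        }
      })
      unname(split(seq_len(p), fold_of))
    },
    loso = {
      if (length(scheme$subject_ids) != p)
        stop("subject_ids length must equal the number of trials", call. = FALSE)
      unname(split(seq_len(p), scheme$subject_ids))
    })
}

# ---- filter normalization and projection ------------------------------------

#' Normalize a coefficient vector to unit length
#'
#' Dividing the difference topography by its Euclidean norm makes the filter
#' unit-length, so projections preserve the measurement units of the data. A
#' vector whose norm is below `tol_rel * max(1, ref_norm)` is classified as
#' degenerate (a legitimate outcome under an exact null) and returned as
#' all-zeros with a flag rather than raising.
#'
#' @param d Numeric coefficient vector (finite).
#' @param ref_norm Scale reference for the degeneracy tolerance (e.g. the norm
#'   of the data slice the coefficients came from). Default 1.
#' @param tol_rel Relative zero-norm tolerance (default 1e-12).
#' @return List with `w` (unit vector, or zeros when degenerate) and
#'   `degenerate` (logical flag).
#' @export
normalize_filter <- function(d, ref_norm = 1, tol_rel = 1e-12) {
  if (!all(is.finite(d))) stop("filter coefficients must be finite", call. = FALSE)
  nrm <- sqrt(sum(d^2))
  if (nrm < tol_rel * max(1, ref_norm))
    list(w = rep(0, length(d)), degenerate = TRUE)
  else
    list(w = d / nrm, degenerate = FALSE)
}

#' Project a topography onto a spatial filter
#'
#' The dot product of an observed sensor topography and a unit-norm filter:
#' one scalar in the units of the data.
#'
#' @param x Numeric channel vector (observed topography).
#' @param w_hat Numeric filter of the same length (unit norm by convention).
#' @return Scalar projection `sum(x * w_hat)`.
#' @export
project_topography <- function(x, w_hat) {
  if (length(x) != length(w_hat))
    stop(sprintf("topography (%d) and filter (%d) lengths differ",
                 length(x), length(w_hat)), call. = FALSE)
  sum(x * w_hat)
}

# ---- containers --------------------------------------------------------------

new_filter_set <- function(filters, scheme, degenerate, stationary = FALSE,
                           objective_name = "") {
  structure(list(filters = filters, scheme = scheme, normalized = TRUE,
                 degenerate = degenerate, stationary = stationary,
                 objective = objective_name),
            class = "spatial_filter_set")
}

new_surrogate_matrix <- function(values, labels, times, degenerate) {
  structure(list(values = values, labels = labels, times = times,
                 degenerate = degenerate),
            class = "surrogate_matrix")
}

#' @export
print.spatial_filter_set <- function(x, ...) {
  d <- dim(x$filters)
  cat(sprintf("<spatial_filter_set> %d channels x %d samples x %d folds (%s%s)\n",
              d[1], d[2], d[3], x$scheme$kind,
              if (x$stationary) ", stationary" else ""))
  cat(sprintf("  objective: %s; degenerate filters: %d\n",
              x$objective, sum(x$degenerate)))
  invisible(x)
}

#' @export
print.surrogate_matrix <- function(x, ...) {
  cat(sprintf("<surrogate_matrix> %d trials x %d samples; %d degenerate entries\n",
              nrow(x$values), ncol(x$values), sum(x$degenerate)))
  invisible(x)
}

check_units_single <- function(ds) {
  present <- as.character(sort(unique(ds$channel_groups)))
  u <- unique(unname(ds$units[present]))
  if (length(u) > 1L)
    stop("dataset mixes sensor groups with different units (",
         paste(u, collapse = ", "),
         "); z-score with zscore_by_sensor_group() or filter the groups separately",
         call. = FALSE)
  invisible(TRUE)
}

# fold-level filter matrix for a per-timepoint objective (channel x sample)
eval_fold_matrix <- function(objective, data, labels, covariates, times, trial_idx) {
  m <- dim(data)[1L]; n <- dim(data)[2L]
  if (!is.null(objective$evaluate_fold)) {
    D <- objective$evaluate_fold(data, labels, covariates, times, trial_idx)
    if (!is.matrix(D) || nrow(D) != m || ncol(D) != n)
      stop(sprintf("objective '%s' fold evaluator must return a %d x %d matrix",
                   objective$name, m, n), call. = FALSE)
    if (!all(is.finite(D)))
      stop(sprintf("objective '%s' returned non-finite coefficients",
                   objective$name), call. = FALSE)
    D
  } else {
    vapply(seq_len(n), function(j)
      check_coef(objective$evaluate(data[, j, , drop = TRUE], labels, covariates),
                 m, objective$name),
      numeric(m))
  }
}

subset_covariates <- function(covariates, idx) {
  if (is.null(covariates)) NULL else lapply(covariates, `[`, idx)
}

# ---- the EMS transform -------------------------------------------------------

#' Effect-matched spatial filtering
#'
#' At every time sample and for every cross-validation fold, evaluates the
#' objective on the trials *outside* the fold, normalizes the resulting
#' coefficient vector to unit length, and projects each held-out trial's
#' topography at that sample onto it. The result is one surrogate time course
#' per trial, in the units of the data, together with the full set of
#' estimated filters.
#'
#' Degenerate (zero-norm) filters yield surrogate value 0 and are flagged in
#' the degeneracy masks rather than raising: they arise legitimately under an
#' exact null. Datasets mixing sensor groups with different units are refused
#' (z-score first, see [zscore_by_sensor_group()]).
#'
#' @param ds An `epoched_dataset`.
#' @param objective An [ems_objective()] of kind `"per-timepoint"` (e.g.
#'   [objective_diff_of_means()]).
#' @param scheme A [cv_scheme()]; default leave-one-out.
#' @param check Validate the dataset first (default `TRUE`).
#' @return List with `surrogates` (a `surrogate_matrix`: trial x sample values,
#'   labels, degeneracy mask) and `filters` (a `spatial_filter_set`: channel x
#'   sample x fold array, sample x fold degeneracy mask).
#' @seealso [stationary_transform()], [effect_time_course()]
#' @export
ems_transform <- function(ds, objective, scheme = cv_scheme("loo"), check = TRUE) {
  if (check) {
    bad <- validate_dataset(ds)
    if (length(bad)) stop("invalid dataset:\n  - ", paste(bad, collapse = "\n  - "),
                          call. = FALSE)
  }
  if (!inherits(objective, "ems_objective") || objective$kind != "per-timepoint")
    stop("ems_transform requires a per-timepoint objective; see stationary_transform()",
         call. = FALSE)
  check_units_single(ds)
  m <- dim(ds$data)[1L]; n <- dim(ds$data)[2L]; p <- dim(ds$data)[3L]
  if (scheme$kind == "loo" && identical(objective$name, "diff_of_means")) {
    pair <- objective$params$pair
    if (min(sum(ds$labels == pair$a), sum(ds$labels == pair$b)) < 2L)
      stop("leave-one-out with a difference-of-means objective needs >= 2 trials per class",
           call. = FALSE)
  }
  folds <- cv_folds(scheme, ds$labels)

  # leave-one-subject-out: the objective sees per-subject class means
  loso <- scheme$kind == "loso"
  if (loso) {
    sid <- scheme$subject_ids
    cells <- split(seq_len(p), list(factor(sid), factor(ds$labels)), drop = TRUE)
    pseudo <- vapply(cells, function(ix)
      apply(ds$data[, , ix, drop = FALSE], c(1L, 2L), mean),
      matrix(0, m, n))                      # m x n x cell
    pseudo_lab <- vapply(cells, function(ix) ds$labels[ix[1]], integer(1))
    pseudo_sid <- vapply(cells, function(ix) as.character(sid[ix[1]]), character(1))
    fold_subjects <- names(split(seq_len(p), sid))
  }

  S <- matrix(NA_real_, p, n)
  mask_s <- matrix(FALSE, p, n)
  filters <- array(NA_real_, c(m, n, length(folds)))
  mask_f <- matrix(FALSE, n, length(folds))

  for (f in seq_along(folds)) {
    out_idx <- folds[[f]]
    if (loso) {
      keep <- pseudo_sid != fold_subjects[f]
      dat_in <- pseudo[, , keep, drop = FALSE]
      lab_in <- pseudo_lab[keep]
      cov_in <- NULL
      in_idx <- which(keep)
    } else {
      in_idx <- setdiff(seq_len(p), out_idx)
      dat_in <- ds$data[, , in_idx, drop = FALSE]
      lab_in <- ds$labels[in_idx]
      cov_in <- subset_covariates(ds$covariates, in_idx)
    }
    D <- eval_fold_matrix(objective, dat_in, lab_in, cov_in, ds$times, in_idx)
    norms <- sqrt(.colSums(D * D, m, n))
    slice_norms <- sqrt(apply(dat_in * dat_in, 2L, sum))
    deg <- norms < 1e-12 * pmax(1, slice_norms)
    Dhat <- sweep(D, 2L, ifelse(deg, 1, norms), "/")
    Dhat[, deg] <- 0
    filters[, , f] <- Dhat
    mask_f[, f] <- deg
    for (k in out_idx) {
      S[k, ] <- .colSums(ds$data[, , k] * Dhat, m, n)
      S[k, deg] <- 0
      mask_s[k, deg] <- TRUE
    }
  }
  list(surrogates = new_surrogate_matrix(S, ds$labels, ds$times, mask_s),
       filters = new_filter_set(filters, scheme, mask_f,
                                objective_name = objective$name))
}

# ---- stationary-template transform ------------------------------------------

#' Stationary-template spatial filtering
#'
#' Estimates a single filter per cross-validation fold (e.g. the windowed
#' class-mean difference around a component peak, or a whole-epoch regression
#' beta topography) and projects every sample of each held-out trial onto that
#' one filter. The surrogate course then tracks when the fixed topography
#' waxes and wanes over the epoch — including re-appearances outside the
#' window that defined it.
#'
#' @param ds An `epoched_dataset`.
#' @param objective An [ems_objective()] of kind `"windowed"` or
#'   `"whole-epoch-regression"` (e.g. [objective_windowed_diff()]).
#' @param scheme A [cv_scheme()]; default leave-one-out.
#' @param check Validate the dataset first (default `TRUE`).
#' @return As [ems_transform()], but the filter set holds one channel x 1
#'   filter per fold (`stationary = TRUE`).
#' @export
stationary_transform <- function(ds, objective, scheme = cv_scheme("loo"),
                                 check = TRUE) {
  if (check) {
    bad <- validate_dataset(ds)
    if (length(bad)) stop("invalid dataset:\n  - ", paste(bad, collapse = "\n  - "),
                          call. = FALSE)
  }
  if (!inherits(objective, "ems_objective") ||
      !objective$kind %in% c("windowed", "whole-epoch-regression"))
    stop("stationary_transform requires a windowed or whole-epoch-regression objective",
         call. = FALSE)
  check_units_single(ds)
  m <- dim(ds$data)[1L]; n <- dim(ds$data)[2L]; p <- dim(ds$data)[3L]
  folds <- cv_folds(scheme, ds$labels)
  S <- matrix(NA_real_, p, n)
  mask_s <- matrix(FALSE, p, n)
  filters <- array(NA_real_, c(m, 1L, length(folds)))
  mask_f <- matrix(FALSE, 1L, length(folds))
  for (f in seq_along(folds)) {
    out_idx <- folds[[f]]
    in_idx <- setdiff(seq_len(p), out_idx)
    d <- objective$evaluate_fold(ds$data[, , in_idx, drop = FALSE],
                                 ds$labels[in_idx],
                                 subset_covariates(ds$covariates, in_idx),
                                 ds$times, in_idx)
    d <- check_coef(d, m, objective$name)
    nf <- normalize_filter(d, ref_norm = sqrt(sum(ds$data[, , in_idx]^2)))
    filters[, 1L, f] <- nf$w
    mask_f[1L, f] <- nf$degenerate
    for (k in out_idx) {
      if (nf$degenerate) {
        S[k, ] <- 0
        mask_s[k, ] <- TRUE
      } else {
        S[k, ] <- as.numeric(crossprod(ds$data[, , k], nf$w))
      }
    }
  }
  list(surrogates = new_surrogate_matrix(S, ds$labels, ds$times, mask_s),
       filters = new_filter_set(filters, scheme, mask_f, stationary = TRUE,
                                objective_name = objective$name))
}

# ---- noise-covariance whitening ---------------------------------------------

#' Whiten a coefficient vector by a (shrunk) noise covariance
#'
#' Multiplies the difference topography by the inverse of a shrinkage-
#' regularized noise covariance, as in Fisher's linear discriminant: channels
#' with high noise variance are down-weighted. The caller normalizes the
#' result; the default pipeline leaves whitening off because the plain matched
#' filter keeps the topography directly interpretable.
#'
#' @param d Numeric channel coefficient vector.
#' @param noise_cov Symmetric positive semi-definite channel x channel matrix.
#' @param shrinkage Shrinkage weight in `[0, 1]` toward an isotropic target
#'   (`diag` of the mean variance); 0 = raw covariance, 1 = isotropic.
#' @return Whitened coefficient vector (un-normalized).
#' @export
whiten_filter <- function(d, noise_cov, shrinkage = 0) {
  m <- length(d)
  if (!is.matrix(noise_cov) || any(dim(noise_cov) != m))
    stop("noise_cov must be a square matrix matching the filter length",
         call. = FALSE)
  if (!all(is.finite(noise_cov)) ||
      max(abs(noise_cov - t(noise_cov))) > 1e-8 * max(1, max(abs(noise_cov))))
    stop("noise_cov must be finite and symmetric", call. = FALSE)
  if (shrinkage < 0 || shrinkage > 1)
    stop("shrinkage must lie in [0, 1]", call. = FALSE)
  target <- diag(mean(diag(noise_cov)), m)
  reg <- (1 - shrinkage) * noise_cov + shrinkage * target
  out <- tryCatch(solve(reg, d), error = function(e) e)
  if (inherits(out, "error"))
    stop("regularized covariance is singular; increase shrinkage", call. = FALSE)
  as.numeric(out)
}

# ---- filter-set diagnostics --------------------------------------------------

#' Temporal similarity structure of a filter set
#'
#' Averages the filters over folds and returns the sample x sample matrix of
#' Pearson correlations between the fold-averaged filters — a compact view of
#' when the effect topography is stable and when it transitions. Samples whose
#' filters are fully degenerate give `NaN` rows/columns.
#'
#' @param fs A `spatial_filter_set` from [ems_transform()].
#' @return Symmetric sample x sample correlation matrix, diagonal 1 where
#'   non-degenerate.
#' @export
filter_similarity <- function(fs) {
  stopifnot(inherits(fs, "spatial_filter_set"))
  if (!isTRUE(fs$normalized)) stop("filter set must be normalized", call. = FALSE)
  avg <- apply(fs$filters, c(1L, 2L), mean)      # channel x sample
  n <- ncol(avg)
  ok <- apply(avg, 2L, stats::sd) > 0
  out <- matrix(NaN, n, n)
  if (any(ok))
    out[ok, ok] <- suppressWarnings(stats::cor(avg[, ok, drop = FALSE]))
  diag(out)[ok] <- 1
  out
}
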