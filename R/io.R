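# On-disk formats: the HDF5 epochs container, result serialization with
# provenance, JSON reports, and CSV label/covariate import.

EPOCHS_SCHEMA_VERSION <- "1.0"

#' Write an epoched dataset to an HDF5 epochs container
#'
#' Layout: group `/epochs` with 64-bit float datasets `data`
#' (channel x sample x trial), `times`, integer `labels` and
#' `channel_groups`, string `channel_names`; optional group `/covariates`
#' with one named per-trial vector each (`NaN` = missing); group attributes
#' `sample_rate_hz`, `schema_version`, `unit_group_ids`, `units`.
#' Round trips are bit-exact for 64-bit floats.
#'
#' @param ds An `epoched_dataset`.
#' @param path Output file path.
#' @param overwrite Overwrite an existing file (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(ds, path, overwrite = FALSE) {
  if (file.exists(path)) {
    if (!overwrite) stop("file exists: ", path, " (use overwrite = TRUE)",
                         call. = FALSE)
    unlink(path)
  }
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "epochs")
  rhdf5::h5write(ds$data, path, "epochs/data")
  rhdf5::h5write(ds$times, path, "epochs/times")
  rhdf5::h5write(as.integer(ds$labels), path, "epochs/labels")
  rhdf5::h5write(ds$channel_names, path, "epochs/channel_names")
  rhdf5::h5write(as.integer(ds$channel_groups), path, "epochs/channel_groups")
  if (!is.null(ds$covariates)) {
    rhdf5::h5createGroup(path, "covariates")
    for (nm in names(ds$covariates))
      rhdf5::h5write(as.numeric(ds$covariates[[nm]]), path,
                     paste0("covariates/", nm))
  }
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "epochs")
  rhdf5::h5writeAttribute(sampling_rate(ds), gid, "sample_rate_hz")
  rhdf5::h5writeAttribute(EPOCHS_SCHEMA_VERSION, gid, "schema_version")
  rhdf5::h5writeAttribute(names(ds$units), gid, "unit_group_ids")
  rhdf5::h5writeAttribute(unname(ds$units), gid, "units")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

h5_has <- function(listing, name) name %in% listing$name |
  name %in% sub("^/", "", paste(listing$group, listing$name, sep = "/"))

#' Read an epoched dataset from an HDF5 epochs container
#'
#' Errors name every missing dataset or attribute; the reconstructed dataset
#' is validated and all violations are reported at once.
#'
#' @param path Path to a file written by [write_epochs()].
#' @return An `epoched_dataset`.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll())
  listing <- rhdf5::h5ls(path)
  full <- sub("^//", "/", paste(listing$group, listing$name, sep = "/"))
  need <- c("/epochs/data", "/epochs/times", "/epochs/labels",
            "/epochs/channel_names", "/epochs/channel_groups")
  missing <- setdiff(need, full)
  if (length(missing))
    stop("epochs container is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  at <- rhdf5::h5readAttributes(path, "epochs")
  if (is.null(at$schema_version))
    stop("epochs container is missing attribute 'schema_version'", call. = FALSE)
  if (!identical(as.character(at$schema_version), EPOCHS_SCHEMA_VERSION))
    stop("unsupported schema_version: ", at$schema_version, call. = FALSE)
  units <- NULL
  if (!is.null(at$unit_group_ids))
    units <- stats::setNames(as.character(at$units), as.character(at$unit_group_ids))
  covariates <- NULL
  if ("/covariates" %in% full || any(listing$group == "/covariates")) {
    nms <- listing$name[listing$group == "/covariates"]
    if (length(nms))
      covariates <- stats::setNames(
        lapply(nms, function(nm) as.numeric(
          rhdf5::h5read(path, paste0("covariates/", nm)))), nms)
  }
  ds <- structure(
    list(data = rhdf5::h5read(path, "epochs/data"),
         times = as.numeric(rhdf5::h5read(path, "epochs/times")),
         labels = as.integer(rhdf5::h5read(path, "epochs/labels")),
         channel_names = as.character(rhdf5::h5read(path, "epochs/channel_names")),
         channel_groups = as.integer(rhdf5::h5read(path, "epochs/channel_groups")),
         covariates = covariates, units = units),
    class = "epoched_dataset")
  if (is.null(units)) {
    g <- sort(unique(ds$channel_groups))
    ds$units <- stats::setNames(rep("au", length(g)), as.character(g))
  }
  # NA covariates (HDF5 NaN) back to NaN for the documented missing encoding
  if (!is.null(ds$covariates))
    ds$covariates <- lapply(ds$covariates, function(x) { x[is.na(x)] <- NaN; x })
  bad <- validate_dataset(ds)
  if (length(bad))
    stop("invalid epochs container:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  ds
}

#' Append filtering results to an HDF5 container
#'
#' Writes the surrogate matrix and/or filter set under `/results` with
#' provenance attributes (objective name, cross-validation scheme, seed,
#' package version).
#'
#' @param path Output HDF5 file (created if absent; `/results` must not
#'   already exist unless `overwrite`).
#' @param surrogates Optional `surrogate_matrix`.
#' @param filters Optional `spatial_filter_set`.
#' @param seed Seed used for the run (stored as provenance).
#' @param overwrite Replace an existing `/results` group.
#' @return `path`, invisibly.
#' @export
write_results <- function(path, surrogates = NULL, filters = NULL,
                          seed = NA_integer_, overwrite = FALSE) {
  on.exit(rhdf5::h5closeAll())
  if (!file.exists(path)) rhdf5::h5createFile(path)
  listing <- rhdf5::h5ls(path)
  if (any(listing$group == "/" & listing$name == "results")) {
    if (!overwrite) stop("/results already exists in ", path,
                         " (use overwrite = TRUE)", call. = FALSE)
    rhdf5::h5delete(path, "results")
  }
  rhdf5::h5createGroup(path, "results")
  if (!is.null(surrogates)) {
    rhdf5::h5createGroup(path, "results/surrogates")
    rhdf5::h5write(surrogates$values, path, "results/surrogates/values")
    rhdf5::h5write(as.integer(surrogates$labels), path, "results/surrogates/labels")
    rhdf5::h5write(surrogates$times, path, "results/surrogates/times")
    rhdf5::h5write(surrogates$degenerate + 0L, path, "results/surrogates/degenerate")
  }
  if (!is.null(filters)) {
    rhdf5::h5createGroup(path, "results/filters")
    rhdf5::h5write(filters$filters, path, "results/filters/values")
    rhdf5::h5write(filters$degenerate + 0L, path, "results/filters/degenerate")
  }
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "results")
  src <- if (!is.null(filters)) filters else surrogates
  rhdf5::h5writeAttribute(
    if (!is.null(filters)) filters$objective else "", gid, "objective")
  rhdf5::h5writeAttribute(
    if (!is.null(filters)) filters$scheme$kind else "", gid, "cv_scheme")
  rhdf5::h5writeAttribute(as.integer(seed), gid, "seed")
  rhdf5::h5writeAttribute(
    as.character(utils::packageVersion("emsfilter")), gid, "package_version")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read back a surrogate matrix written by [write_results()]
#' @param path HDF5 file containing `/results/surrogates`.
#' @return A `surrogate_matrix`.
#' @export
read_surrogates <- function(path) {
  on.exit(rhdf5::h5closeAll())
  new_surrogate_matrix(
    rhdf5::h5read(path, "results/surrogates/values"),
    as.integer(rhdf5::h5read(path, "results/surrogates/labels")),
    as.numeric(rhdf5::h5read(path, "results/surrogates/times")),
    rhdf5::h5read(path, "results/surrogates/degenerate") != 0L)
}

#' Read back a filter set written by [write_results()]
#' @param path HDF5 file containing `/results/filters`.
#' @return A `spatial_filter_set` (scheme descriptor reduced to its kind).
#' @export
read_filters <- function(path) {
  on.exit(rhdf5::h5closeAll())
  at <- rhdf5::h5readAttributes(path, "results")
  f <- rhdf5::h5read(path, "results/filters/values")
  new_filter_set(f, list(kind = as.character(at$cv_scheme)),
                 rhdf5::h5read(path, "results/filters/degenerate") != 0L,
                 stationary = dim(f)[2L] == 1L,
                 objective_name = as.character(at$objective))
}

#' Serialize an evaluation report to JSON
#'
#' SNR reports and decoding results are flat lists of scalars and vectors;
#' they are written as a single JSON object with a `type` tag.
#'
#' @param report An `snr_report` or `decoding_result`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  type <- class(report)[1]
  obj <- c(list(type = type,
                package_version = as.character(utils::packageVersion("emsfilter"))),
           unclass(report))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Import per-trial labels and covariates from CSV
#'
#' One row per trial, header required; a `label` column gives the condition
#' id, every other numeric column becomes a covariate (empty cells or `NA`
#' become `NaN`, the missing-response encoding).
#'
#' @param path CSV file path.
#' @return List with `labels` and `covariates` (possibly `NULL`).
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, header = TRUE)
  if (!"label" %in% names(tab))
    stop("trial table needs a 'label' column", call. = FALSE)
  cov_names <- setdiff(names(tab), "label")
  covariates <- if (length(cov_names)) {
    out <- lapply(tab[cov_names], function(x) {
      x <- as.numeric(x); x[is.na(x)] <- NaN; x
    })
    out
  }
  list(labels = as.integer(tab$label), covariates = covariates)
}
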