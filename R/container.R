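# Directory-based named-array container: a JSON manifest plus one file
# per dataset (numeric arrays as full-precision text, tables as CSV).
# Chosen for language neutrality and inspectability; arrays round-trip
# bit for bit.

CONTAINER_SCHEMA <- "oscdecode-container-1"

#' Write a named-array container
#'
#' @param datasets named list of numeric vectors/arrays/matrices and
#'   data.frames.
#' @param path container directory (created if needed).
#' @param attrs named list of scalar metadata stored in the manifest
#'   (e.g. `fs`, `seed`, a serialized config).
#' @return `path`, invisibly.
#' @export
write_container <- function(datasets, path, attrs = list()) {
  stop_if(is.null(names(datasets)) || any(names(datasets) == ""),
          "all datasets must be named")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(schema = CONTAINER_SCHEMA, attrs = attrs, datasets = list())
  for (nm in names(datasets)) {
    x <- datasets[[nm]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
    if (is.data.frame(x)) {
      file <- paste0(safe, ".csv")
      utils::write.csv(x, file.path(path, file), row.names = FALSE)
      manifest$datasets[[nm]] <- list(type = "table", file = file)
    } else {
      stop_if(!is.numeric(x) && !is.integer(x) && !is.logical(x),
              "dataset ", nm, " must be numeric/logical or a data.frame")
      file <- paste0(safe, ".txt")
      dm <- dim(x) %||% length(x)
      writeLines(sprintf("%.17g", as.numeric(x)), file.path(path, file))
      manifest$datasets[[nm]] <- list(type = "array", dim = as.integer(dm),
                                      file = file)
    }
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a named-array container
#'
#' Arrays are restored with their original dimensions; the manifest
#' `attrs` are attached as an attribute.  Unknown schema versions and
#' missing required datasets are explicit errors.
#'
#' @param path container directory.
#' @param required character vector of dataset names that must be present.
#' @return named list of datasets, with attribute `attrs`.
#' @export
read_container <- function(path, required = NULL) {
  mf <- file.path(path, "manifest.json")
  stop_if(!file.exists(mf), "no container manifest at ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  stop_if(!identical(manifest$schema, CONTAINER_SCHEMA),
          "unsupported container schema '", manifest$schema,
          "'; supported: ", CONTAINER_SCHEMA)
  missing <- setdiff(required, names(manifest$datasets))
  stop_if(length(missing) > 0,
          "container missing required dataset(s): ",
          paste(missing, collapse = ", "))
  out <- list()
  for (nm in names(manifest$datasets)) {
    info <- manifest$datasets[[nm]]
    fp <- file.path(path, info$file)
    stop_if(!file.exists(fp), "dataset file missing: ", info$file)
    if (identical(info$type, "table")) {
      out[[nm]] <- utils::read.csv(fp)
    } else {
      v <- as.numeric(readLines(fp))
      stop_if(any(!is.finite(v)),
              "dataset ", nm, " contains non-finite values")
      dm <- unlist(info$dim)
      out[[nm]] <- if (length(dm) > 1) array(v, dm) else v
    }
  }
  attr(out, "attrs") <- manifest$attrs
  out
}

#' Write an epoch set (with optional ground truth) to a container
#'
#' @param epochs an [epoch_set()].
#' @param path container directory.
#' @param truth optional `ground_truth` from [generate_trials()].
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path, truth = NULL) {
  ds <- list(data = epochs$data, labels = as.numeric(epochs$labels),
             attributes = epochs$attributes)
  if (!is.null(truth)) {
    ds$groundtruth_trend <- truth$trend
    ds$groundtruth_oscillation <- truth$oscillation
    ds$groundtruth_noise <- truth$noise
    ds$groundtruth_latency_shift <- truth$latency_shift
    ds$groundtruth_phase_offsets <- truth$phase_offsets
  }
  write_container(ds, path, attrs = list(fs = epochs$fs,
                                         kind = "epoch_set"))
}

#' Read an epoch set from a container
#'
#' @param path container directory.
#' @return an [epoch_set()]; invariants are validated on load.
#' @export
read_epochs <- function(path) {
  ds <- read_container(path, required = c("data", "labels"))
  at <- attr(ds, "attrs")
  epoch_set(ds$data, at$fs, as.integer(ds$labels),
            attributes = ds$attributes)
}
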