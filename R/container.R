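## Cohort container: a single hierarchical file per cohort (RDS-serialised
## list) holding per-patient groups (signal, validity mask, R-peaks, labels)
## plus array geometry and acquisition/provenance attributes. Writing and
## re-reading is bit-exact.

CONTAINER_FORMAT <- "mcg-cohort"
CONTAINER_VERSION <- "1.0"

required_container_fields <- c("format", "version", "fs", "units",
                               "component", "geometry", "standoff", "attrs",
                               "provenance", "patients")

default_acquisition_attrs <- function() {
  list(
    sensor_type = "simulated SQUID-like magnetometer array",
    n_channels = 64L,
    positioning = "array centred over the anterior thorax, supine (simulated)",
    shielding = "noise-free environment plus modelled interference (simulated)",
    noise = "additive white Gaussian + slow baseline drift + 50 Hz line",
    protocol = "continuous resting sinus-rhythm recording (simulated)",
    synchronization = "R-peak ground truth stored by the simulator",
    preprocessing = "none (raw simulator output)",
    signal_format = "raw continuous multichannel time series",
    labels_def = "synthetic class-conditional task labels",
    validation = "patient-stratified k-fold cross-validation"
  )
}

#' Write a cohort container
#'
#' @param recordings List of `mcg_recording`.
#' @param path Output file path.
#' @param attrs Acquisition metadata attributes (defaults describe the
#'   simulator; override for other sources).
#' @param provenance Optional list (seed, config hash, ...); software version
#'   is added automatically.
#' @return `path`, invisibly.
#' @export
write_container <- function(recordings, path,
                            attrs = default_acquisition_attrs(),
                            provenance = list()) {
  stopifnot(length(recordings) >= 1,
            all(vapply(recordings, inherits, logical(1), "mcg_recording")))
  arr <- recordings[[1]]$sensor_array
  provenance$software_version <-
    as.character(utils::packageVersion("magcardia"))
  obj <- list(
    format = CONTAINER_FORMAT, version = CONTAINER_VERSION,
    fs = recordings[[1]]$fs, units = "pT",
    component = attr(arr, "component"),
    geometry = tibble::tibble(channel = arr$channel, x = arr$x, y = arr$y,
                              z = arr$z),
    standoff = attr(arr, "standoff"),
    attrs = attrs, provenance = provenance,
    patients = lapply(recordings, function(r) {
      list(patient_id = r$patient_id, signal = r$signal,
           valid_channels = r$valid_channels, r_peaks = r$r_peaks,
           labels = r$labels, class_label = r$class_label,
           meta = r$meta)
    })
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Read a cohort container
#'
#' @param path Container file path.
#' @param as_recordings Rebuild `mcg_recording` objects (default) instead of
#'   returning the raw container list.
#' @return List of `mcg_recording`, or the container list with class
#'   `mcg_container`.
#' @export
read_container <- function(path, as_recordings = TRUE) {
  obj <- readRDS(path)
  miss <- setdiff(required_container_fields, names(obj))
  if (length(miss) > 0) {
    stop("schema error: missing required field(s): ",
         paste(miss, collapse = ", "))
  }
  if (!identical(obj$format, CONTAINER_FORMAT)) {
    stop("schema error: format is not '", CONTAINER_FORMAT, "'")
  }
  for (p in obj$patients) {
    pm <- setdiff(c("patient_id", "signal", "valid_channels", "labels"),
                  names(p))
    if (length(pm) > 0) {
      stop("schema error: patient group missing field(s): ",
           paste(pm, collapse = ", "))
    }
  }
  if (!as_recordings) {
    class(obj) <- "mcg_container"
    return(obj)
  }
  arr <- default_sensor_array(standoff = obj$standoff)
  arr$x <- obj$geometry$x
  arr$y <- obj$geometry$y
  arr$z <- obj$geometry$z
  lapply(obj$patients, function(p) {
    structure(list(signal = p$signal, fs = obj$fs, sensor_array = arr,
                   patient_id = p$patient_id, labels = p$labels,
                   valid_channels = p$valid_channels, r_peaks = p$r_peaks,
                   class_label = p$class_label %||% NA_character_,
                   effect_size = NA_real_, meta = p$meta %||% list()),
              class = "mcg_recording")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Segment-list container (between preprocess/qc/pretrain CLI stages).
write_segments <- function(segments, path, provenance = list()) {
  provenance$software_version <-
    as.character(utils::packageVersion("magcardia"))
  saveRDS(list(format = "mcg-segments", version = CONTAINER_VERSION,
               provenance = provenance, segments = segments), path)
  invisible(path)
}

read_segments <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mcg-segments")) {
    stop("schema error: not an mcg-segments file")
  }
  obj$segments
}
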