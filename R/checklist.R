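#' Minimum-reporting checklist validation for MCG containers
#'
#' Maps each item of a minimum reporting checklist for magnetocardiography
#' studies (sensor system, field components, array layout, standoff,
#' positioning, shielding, noise conditions, recording protocol,
#' synchronization, preprocessing, signal format, clinical labels,
#' validation design) to a presence/validity test on the container's
#' metadata. Missing items are failures, not errors.
#'
#' @param container Path to a cohort container, or the object returned by
#'   [read_container()] with `as_recordings = FALSE`.
#' @param json_path Optional path to also serialise the report as JSON.
#' @return Tibble of class `mcg_checklist_report`: `domain`, `item`, `pass`,
#'   `detail`.
#' @export
validate_reporting_checklist <- function(container, json_path = NULL) {
  obj <- if (is.character(container)) {
    read_container(container, as_recordings = FALSE)
  } else {
    container
  }
  a <- obj$attrs %||% list()
  nonempty <- function(x) {
    !is.null(x) && length(x) > 0 && !all(is.na(x)) &&
      (!is.character(x) || any(nzchar(x)))
  }
  n_ch <- if (!is.null(obj$geometry)) nrow(obj$geometry) else 0L
  sig_ok <- length(obj$patients) > 0 &&
    all(vapply(obj$patients, function(p) {
      is.matrix(p$signal) && nrow(p$signal) == n_ch
    }, logical(1)))
  items <- list(
    list("Instrumentation", "Sensor system",
         nonempty(a$sensor_type) && nonempty(a$n_channels),
         "sensor type and channel count"),
    list("Instrumentation", "Field components",
         nonempty(obj$component) &&
           all(obj$component %in% c("Bz", "Bx", "By", "Bxyz", "Bx/By/Bz")),
         "measured field component tag"),
    list("Measurement geometry", "Array layout",
         n_ch > 0 && !is.null(a$n_channels) && n_ch == a$n_channels &&
           anyDuplicated(round(obj$geometry[, c("x", "y")], 12)) == 0,
         "per-channel sensor coordinates"),
    list("Measurement geometry", "Standoff distance",
         nonempty(obj$standoff) && all(obj$standoff > 0),
         "chest-to-sensor distance"),
    list("Measurement geometry", "Positioning", nonempty(a$positioning),
         "patient positioning and alignment"),
    list("Acquisition environment", "Shielding", nonempty(a$shielding),
         "shielding conditions"),
    list("Acquisition environment", "Noise conditions",
         nonempty(obj$fs) && nonempty(a$noise),
         "sampling rate and noise characteristics"),
    list("Physiological context", "Recording protocol", nonempty(a$protocol),
         "duration, posture, physiological state"),
    list("Physiological context", "Synchronization",
         nonempty(a$synchronization), "beat alignment / gating strategy"),
    list("Preprocessing", "Signal processing", nonempty(a$preprocessing),
         "filtering, artefact handling, segmentation"),
    list("Data representation", "Signal format",
         nonempty(a$signal_format) && sig_ok,
         "signal representation and consistent shapes"),
    list("Clinical reference", "Labels",
         length(obj$patients) > 0 &&
           all(vapply(obj$patients, function(p) nonempty(p$labels),
                      logical(1))),
         "endpoints / reference standards per patient"),
    list("Evaluation", "Validation design", nonempty(a$validation),
         "cohort construction and patient-level separation")
  )
  rep <- purrr::map_dfr(items, function(it) {
    tibble::tibble(domain = it[[1]], item = it[[2]],
                   pass = isTRUE(it[[3]]), detail = it[[4]])
  })
  class(rep) <- c("mcg_checklist_report", class(rep))
  if (!is.null(json_path)) {
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA)
  }
  rep
}
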