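#' Read a device geometry from a YAML configuration file
#'
#' The file holds a `name` and a `sections` list with one entry per channel
#' section; units are encoded in the key suffixes (`length_um`, `width_um`,
#' `height_um`, `diameter_um`). See the packaged presets under
#' `system.file("extdata", "devices", package = "mixinject")` for the dialect.
#'
#' @param path Path to a YAML device file.
#' @return A [device_geometry()].
#' @export
read_device_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name) || is.null(cfg$sections)) {
    abort("Device config needs `name` and `sections` keys.")
  }
  sections <- purrr::map_dfr(cfg$sections, function(s) {
    tibble::tibble(
      label = s$label,
      length_um = as.numeric(s$length_um),
      shape = s$shape,
      width_um = as.numeric(s$width_um %||% NA),
      height_um = as.numeric(s$height_um %||% NA),
      diameter_um = as.numeric(s$diameter_um %||% NA),
      flow_scope = s$flow_scope
    )
  })
  device_geometry(cfg$name, sections)
}

#' Read a flow configuration from a YAML file
#'
#' Expects top-level keys `Q_X_uL_min`, `Q_S_uL_min`, `Q_O_uL_min`, and
#' optionally `Q_B_uL_min`.
#'
#' @param path Path to a YAML flow file.
#' @return A [flow_config()].
#' @export
read_flow_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  flow_config(
    Q_X = as.numeric(cfg$Q_X_uL_min %||% 0),
    Q_S = as.numeric(cfg$Q_S_uL_min %||% 0),
    Q_O = as.numeric(cfg$Q_O_uL_min %||% 0),
    Q_B = if (!is.null(cfg$Q_B_uL_min)) as.numeric(cfg$Q_B_uL_min)
  )
}

#' Detector-trace and hit-series files
#'
#' Detector traces travel as plain two-column CSV (`time_s`, `voltage_V`);
#' the sample rate is recovered from the time column. Hit series are CSV with
#' columns `window_index`, `hits_per_train`.
#'
#' @param trace,path,hits File path or object to write/read.
#' @return `read_trace_csv()` a [detector_trace][synth_trace()];
#'   `read_hits_csv()` an integer vector of per-window hit counts.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "detector_trace"))
  readr::write_csv(tibble::tibble(
    time_s = trace$time, voltage_V = trace$voltage
  ), path)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("time_s", "voltage_V") %in% names(df)))
  dt <- median(diff(df$time_s))
  new_detector_trace(df$time_s, df$voltage_V,
    sample_rate = 1 / dt, t0 = df$time_s[[1]]
  )
}

#' @rdname trace_io
#' @export
write_hits_csv <- function(hits, path) {
  readr::write_csv(tibble::tibble(
    window_index = seq_along(hits) - 1L, hits_per_train = hits
  ), path)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_hits_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("window_index", "hits_per_train") %in% names(df)))
  as.integer(df$hits_per_train[order(df$window_index)])
}
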