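#' Channel cross-sections
#'
#' A cross-section is either rectangular (`width` x `height`, in um) or
#' circular (`diameter`, in um). Mixer channels in the droplet-generator
#' devices are rectangular; the fused-silica capillary joining the device to
#' the nozzle is circular.
#'
#' @param shape `"rectangular"` or `"circular"`.
#' @param width,height Rectangular dimensions (um).
#' @param diameter Circular bore diameter (um).
#'
#' @return A `cross_section` object.
#' @examples
#' cross_section("rectangular", width = 150, height = 150)
#' cross_section("circular", diameter = 100)
#' @export
cross_section <- function(shape = c("rectangular", "circular"),
                          width = NULL, height = NULL, diameter = NULL) {
  shape <- match.arg(shape)
  if (shape == "rectangular") {
    if (is.null(width) || is.null(height)) {
      abort("A rectangular cross-section needs `width` and `height`.")
    }
    check_positive(width, "width")
    check_positive(height, "height")
    out <- list(shape = shape, width = width, height = height)
  } else {
    if (is.null(diameter)) abort("A circular cross-section needs `diameter`.")
    check_positive(diameter, "diameter")
    out <- list(shape = shape, diameter = diameter)
  }
  structure(out, class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  if (x$shape == "rectangular") {
    cat(sprintf("<cross_section> rectangular %g x %g um\n", x$width, x$height))
  } else {
    cat(sprintf("<cross_section> circular, diameter %g um\n", x$diameter))
  }
  invisible(x)
}

#' Cross-sectional area
#'
#' @param cs A [cross_section()].
#' @return Area in um^2.
#' @examples
#' cross_section_area(cross_section("circular", diameter = 100))
#' @export
cross_section_area <- function(cs) {
  stopifnot(inherits(cs, "cross_section"))
  if (cs$shape == "rectangular") cs$width * cs$height else pi * (cs$diameter / 2)^2
}

#' Volumetric flow configuration
#'
#' Bundles the three pump flows of a mixer/droplet-generator run: the crystal
#' stream `Q_X`, the substrate stream `Q_S`, and the segmenting oil stream
#' `Q_O`. For synchronization-only runs a single aqueous buffer stream `Q_B`
#' may replace the two mixed streams. Derived totals: `Q_aq = Q_X + Q_S` (or
#' `Q_B` when given) and `Q_T = Q_aq + Q_O`.
#'
#' @param Q_X,Q_S,Q_O Crystal, substrate, and oil flow rates (uL/min).
#' @param Q_B Optional single aqueous buffer flow (uL/min) replacing
#'   `Q_X + Q_S`.
#' @return A `flow_config` object with elements `Q_X`, `Q_S`, `Q_O`, `Q_B`,
#'   `Q_aq`, `Q_T` (all uL/min).
#' @examples
#' flow_config(Q_X = 0.5, Q_S = 0.4, Q_O = 18.3)
#' @export
flow_config <- function(Q_X = 0, Q_S = 0, Q_O = 0, Q_B = NULL) {
  check_positive(Q_X, "Q_X", strict = FALSE)
  check_positive(Q_S, "Q_S", strict = FALSE)
  check_positive(Q_O, "Q_O", strict = FALSE)
  if (!is.null(Q_B)) check_positive(Q_B, "Q_B", strict = FALSE)
  Q_aq <- if (!is.null(Q_B)) Q_B else Q_X + Q_S
  Q_T <- Q_aq + Q_O
  if (Q_T <= 0) abort("Total flow Q_T must be > 0.")
  structure(
    list(Q_X = Q_X, Q_S = Q_S, Q_O = Q_O, Q_B = Q_B, Q_aq = Q_aq, Q_T = Q_T),
    class = "flow_config"
  )
}

#' @export
print.flow_config <- function(x, ...) {
  cat(sprintf(
    "<flow_config> Q_X %g, Q_S %g, Q_O %g%s -> Q_aq %g, Q_T %g uL/min\n",
    x$Q_X, x$Q_S, x$Q_O,
    if (!is.null(x$Q_B)) sprintf(", Q_B %g", x$Q_B) else "", x$Q_aq, x$Q_T
  ))
  invisible(x)
}

section_flow <- function(flows, flow_scope) {
  switch(flow_scope,
    aqueous_only = flows$Q_aq,
    total = flows$Q_T,
    abort(sprintf("Unknown flow_scope '%s'.", flow_scope))
  )
}

#' Mixer device geometry
#'
#' A device is an ordered set of exactly three channel sections. Section A is
#' the mixing channel where the substrate and crystal streams first meet
#' (aqueous flow only); section B is where the droplet is formed and
#' accelerated by the oil phase (total flow); section C is the remaining
#' device, capillary, and nozzle path to the gas-focusing orifice (total
#' flow).
#'
#' `device_geometry()` builds a device from per-section lengths and
#' cross-sections; [preset_device()] loads the two published designs from
#' packaged configuration files.
#'
#' @param name Device identifier.
#' @param sections A data frame with one row per section and columns `label`
#'   (`"A"`, `"B"`, `"C"`), `length_um`, `shape`, `width_um`, `height_um`,
#'   `diameter_um`, `flow_scope` (`"aqueous_only"` for A, `"total"` for B, C).
#'
#' @return A `device_geometry`: a tibble of sections with a `name` attribute.
#' @seealso [preset_device()], [residence_breakdown()]
#' @export
device_geometry <- function(name, sections) {
  sections <- tibble::as_tibble(sections)
  needed <- c("label", "length_um", "shape", "flow_scope")
  if (!all(needed %in% names(sections))) {
    abort(paste0("`sections` needs columns: ", paste(needed, collapse = ", ")))
  }
  if (!identical(sort(sections$label), c("A", "B", "C"))) {
    abort("A device needs exactly one section per label A, B, C.")
  }
  sections <- dplyr::arrange(sections, .data$label)
  expected_scope <- c(A = "aqueous_only", B = "total", C = "total")
  if (!identical(sections$flow_scope, unname(expected_scope[sections$label]))) {
    abort("flow_scope must be 'aqueous_only' for section A and 'total' for B and C.")
  }
  check_positive(sections$length_um, "length_um")
  for (col in c("width_um", "height_um", "diameter_um")) {
    if (!col %in% names(sections)) sections[[col]] <- NA_real_
  }
  sections$area_um2 <- purrr::pmap_dbl(
    sections[c("shape", "width_um", "height_um", "diameter_um")],
    function(shape, width_um, height_um, diameter_um) {
      cs <- if (shape == "rectangular") {
        cross_section("rectangular", width = width_um, height = height_um)
      } else {
        cross_section("circular", diameter = diameter_um)
      }
      cross_section_area(cs)
    }
  )
  structure(sections, name = name, class = c("device_geometry", class(sections)))
}

#' @export
print.device_geometry <- function(x, ...) {
  cat(sprintf("<device_geometry> %s\n", attr(x, "name")))
  NextMethod()
}

#' Published droplet-generator mixer designs
#'
#' Loads one of the two capillary-coupled Y-mixer droplet generators from the
#' configuration files shipped with the package:
#'
#' * `"DG250-Y"`: 100 x 100 um aqueous mixing channel (section A) joining a
#'   150 x 150 um droplet-formation channel (section B).
#' * `"DG300-Y"`: 150 x 150 um channels throughout sections A and B.
#'
#' Both share section lengths A = 528 um, B = 285 um, and C = 15.4 mm of
#' 100 um inner-diameter circular capillary to the nozzle orifice.
#'
#' @param name `"DG250-Y"` or `"DG300-Y"`.
#' @return A [device_geometry()].
#' @examples
#' preset_device("DG300-Y")
#' @export
preset_device <- function(name) {
  key <- tolower(gsub("-", "", name))
  file <- switch(key,
    dg250y = "dg250-y.yaml",
    dg300y = "dg300-y.yaml",
    abort(sprintf("Unknown device preset '%s' (available: DG250-Y, DG300-Y).", name))
  )
  read_device_config(system.file("extdata", "devices", file,
    package = "mixinject", mustWork = TRUE
  ))
}

#' Mean channel velocity from a volumetric flow
#'
#' @param Q Volumetric flow rate (uL/min).
#' @param cs A [cross_section()].
#' @return Mean velocity (um/s).
#' @examples
#' mean_velocity(0.9, cross_section("rectangular", width = 150, height = 150))
#' @export
mean_velocity <- function(Q, cs) {
  check_positive(Q, "Q")
  area <- cross_section_area(cs)
  uL_min_to_um3_s(Q) / area
}

#' Residence time in one channel section
#'
#' The section's `flow_scope` selects the flow: the aqueous flow `Q_aq` for
#' section A (before the oil joins), the total flow `Q_T` for sections B and C.
#'
#' @param section One row of a [device_geometry()] (a data frame with
#'   `length_um`, `area_um2`, `flow_scope`).
#' @param flows A [flow_config()].
#' @return Residence time (s).
#' @export
section_residence_time <- function(section, flows) {
  stopifnot(inherits(flows, "flow_config"))
  q <- section_flow(flows, section$flow_scope[[1]])
  check_positive(q, sprintf("flow for section %s", section$label[[1]]))
  v <- uL_min_to_um3_s(q) / section$area_um2[[1]]
  section$length_um[[1]] / v
}

#' Reaction time point from per-section residence times
#'
#' Decomposes the reaction time point t_R of a mix-and-inject run into the
#' residence times of the three device sections, t_R = t_A + t_B + t_C, using
#' the mean velocity Q / area in each section. Acceleration inside the
#' gas-focusing nozzle is excluded: section C ends where the focusing gas
#' takes over.
#'
#' @inheritParams section_residence_time
#' @param device A [device_geometry()].
#' @return A `residence_breakdown` tibble with one row per section (`label`,
#'   `length_um`, `area_um2`, `flow_uL_min`, `velocity_um_s`, `time_s`) and a
#'   `t_R` attribute. Use [glance()] for the one-row t_A/t_B/t_C/t_R summary.
#' @examples
#' dev <- preset_device("DG300-Y")
#' rb <- residence_breakdown(dev, flow_config(Q_X = 0.5, Q_S = 0.4, Q_O = 18.3))
#' glance(rb)
#' @export
residence_breakdown <- function(device, flows) {
  stopifnot(inherits(device, "device_geometry"), inherits(flows, "flow_config"))
  out <- tibble::as_tibble(device)
  out$flow_uL_min <- purrr::map_dbl(out$flow_scope, ~ section_flow(flows, .x))
  check_positive(out$flow_uL_min, "section flows")
  out$velocity_um_s <- uL_min_to_um3_s(out$flow_uL_min) / out$area_um2
  out$time_s <- out$length_um / out$velocity_um_s
  out <- out[c(
    "label", "length_um", "area_um2", "flow_uL_min", "velocity_um_s", "time_s"
  )]
  structure(out,
    t_R = sum(out$time_s), device = attr(device, "name"),
    class = c("residence_breakdown", class(out))
  )
}

#' @export
print.residence_breakdown <- function(x, ...) {
  cat(sprintf(
    "<residence_breakdown> %s, t_R = %.3f s\n",
    attr(x, "device") %||% "device", attr(x, "t_R")
  ))
  NextMethod()
}

#' @rdname residence_breakdown
#' @param x A `residence_breakdown`.
#' @param ... Unused.
#' @method tidy residence_breakdown
#' @export
tidy.residence_breakdown <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname residence_breakdown
#' @method glance residence_breakdown
#' @export
glance.residence_breakdown <- function(x, ...) {
  t <- x$time_s
  names(t) <- paste0("t_", x$label)
  tibble::tibble(
    device = attr(x, "device") %||% NA_character_,
    t_A = t[["t_A"]], t_B = t[["t_B"]], t_C = t[["t_C"]],
    t_R = attr(x, "t_R")
  )
}
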