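#' Viscosity-corrected diffusion coefficient
#'
#' Scales a reference diffusivity to a working liquor of different viscosity
#' by the Einstein relation, D * eta = D_ref * eta_ref. Substrate diffusion
#' coefficients are tabulated in water; crystal slurries are suspended in a
#' viscous mother liquor (e.g. 18% PEG 3350), so the working diffusivity is
#' substantially smaller.
#'
#' @param D_ref Reference diffusivity (cm^2/s).
#' @param eta_ref Reference solvent viscosity (mPa.s); water at room
#'   temperature is 1.00.
#' @param eta Working-liquor viscosity (mPa.s).
#' @return Corrected diffusivity (cm^2/s).
#' @examples
#' corrected_diffusivity(6.7e-6, 1.00, 5.39)
#' @export
corrected_diffusivity <- function(D_ref, eta_ref = 1.00, eta) {
  check_positive(D_ref, "D_ref", strict = FALSE)
  check_positive(eta_ref, "eta_ref")
  check_positive(eta, "eta")
  D_ref * eta_ref / eta
}

#' Transport properties of the working liquor
#'
#' @inheritParams corrected_diffusivity
#' @return A `transport_properties` list with the corrected diffusivity `D`
#'   (cm^2/s) alongside the inputs.
#' @examples
#' transport_properties(D_ref = 6.7e-6, eta = 5.39)
#' @export
transport_properties <- function(D_ref, eta_ref = 1.00, eta) {
  structure(
    list(
      D_ref = D_ref, eta_ref = eta_ref, eta = eta,
      D = corrected_diffusivity(D_ref, eta_ref, eta)
    ),
    class = "transport_properties"
  )
}

#' Parabolic (plane-Poiseuille) velocity profile
#'
#' Streamwise velocity between the two side walls of the mixing channel,
#' u(y) = 6 v_mean (y/w)(1 - y/w): zero at the walls, 1.5 v_mean at the
#' centerline.
#'
#' @param y Transverse position(s) (um), measured from the crystal-side wall.
#' @param w Channel width (um).
#' @param v_mean Mean velocity (um/s).
#' @return Velocity (um/s), vectorized over `y`.
#' @export
velocity_profile <- function(y, w, v_mean) {
  check_positive(w, "w")
  if (any(y < 0 | y > w)) abort("`y` must lie within [0, w].")
  6 * v_mean * (y / w) * (1 - y / w)
}

#' Inlet interface position between the two aqueous streams
#'
#' Under the parabolic profile the two co-flowing streams split the channel
#' width so that each carries its share of the volumetric flow. The
#' cumulative flow fraction below y is F(y/w) = 3 (y/w)^2 - 2 (y/w)^3; the
#' substrate-layer thickness y* (measured from the substrate-side wall)
#' solves F(y*/w) = Q_S / (Q_S + Q_X), found by bisection.
#'
#' @param Q_S,Q_X Substrate and crystal flow rates (uL/min).
#' @param w Channel width (um).
#' @return Substrate-layer thickness y* (um) from the substrate-side wall.
#'   The interface sits at `w - y*` from the crystal-side wall.
#' @examples
#' inlet_interface_position(Q_S = 0.4, Q_X = 0.5, w = 150)
#' @export
inlet_interface_position <- function(Q_S, Q_X, w) {
  check_positive(Q_S, "Q_S")
  check_positive(Q_X, "Q_X")
  check_positive(w, "w")
  f_s <- Q_S / (Q_S + Q_X)
  u <- uniroot(function(u) 3 * u^2 - 2 * u^3 - f_s,
    lower = 0, upper = 1, tol = 1e-12
  )$root
  u * w
}

#' Discretization grid for the mixing solver
#'
#' @param nx,ny Number of axial and transverse nodes (>= 16 each).
#' @param x_max Axial extent (um); defaults to the device's section A length.
#' @param w Channel width (um); defaults to the device's section A width.
#' @return A `mixing_grid` list.
#' @export
mixing_grid <- function(nx = 512, ny = 257, x_max = NULL, w = NULL) {
  if (nx < 16 || ny < 16) abort("`nx` and `ny` must both be >= 16.")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), x_max = x_max, w = w),
    class = "mixing_grid"
  )
}

erfc_base <- function(z) 2 * stats::pnorm(z * sqrt(2), lower.tail = FALSE)

# Inlet step profile with area-weighted fill of the straddling cell, so the
# discrete advective flux matches the flow split to within one cell.
inlet_profile <- function(y, dy, y_interface, c0) {
  lo <- y - dy / 2
  hi <- y + dy / 2
  frac <- pmin(pmax((hi - y_interface) / dy, 0), 1)
  c0 * frac
}

#' Solve the laminar advection-diffusion mixing field in the mixer channel
#'
#' Computes the steady substrate concentration c(x, y) in section A of a
#' mixer device from the parabolized transport equation
#' u(y) dc/dx = D d2c/dy2, marched downstream with an implicit
#' (unconditionally stable, positivity-preserving) step and zero-flux walls.
#' Axial diffusion is neglected; this requires a Peclet number
#' v_mean w / D > 50, otherwise the solver refuses. The inlet is a step
#' profile: substrate at `c0` above the interface set by the flow split
#' ([inlet_interface_position()]), crystal stream at zero below.
#'
#' The model is single-phase: it covers the co-flowing aqueous streams only
#' and does not include the two-phase droplet pinch-off or the transverse
#' drift it induces near the oil junction.
#'
#' @param device A [device_geometry()]; section A supplies the default
#'   channel width and axial extent.
#' @param flows A [flow_config()].
#' @param props A [transport_properties()].
#' @param c0 Inlet substrate concentration (mM).
#' @param grid A [mixing_grid()].
#' @param profile `"parabolic"` for the plane-Poiseuille profile, `"plug"`
#'   for a uniform profile (used to validate against the closed-form
#'   complementary-error-function solution).
#' @return A `mixing_field` object: axial nodes `x` (um), transverse nodes
#'   `y` (um, 0 at the crystal-side wall), concentration matrix `conc`
#'   (`nx` rows by `ny` columns, mM), plus `c0`, `interface_y` (um from the
#'   crystal-side wall), `w`, `v_mean`, `D_um2_s`, and the Peclet number.
#' @examples
#' dev <- preset_device("DG300-Y")
#' fl <- flow_config(Q_X = 0.5, Q_S = 0.4, Q_O = 18.3)
#' pr <- transport_properties(D_ref = 6.7e-6, eta = 5.39)
#' fld <- solve_mixing_field(dev, fl, pr, c0 = 300, grid = mixing_grid(64, 65))
#' @export
solve_mixing_field <- function(device, flows, props, c0 = 300,
                               grid = mixing_grid(),
                               profile = c("parabolic", "plug")) {
  stopifnot(
    inherits(device, "device_geometry"), inherits(flows, "flow_config"),
    inherits(props, "transport_properties"), inherits(grid, "mixing_grid")
  )
  profile <- match.arg(profile)
  check_positive(c0, "c0")
  secA <- device[device$label == "A", ]
  w <- grid$w %||% secA$width_um
  x_max <- grid$x_max %||% secA$length_um
  if (x_max > secA$length_um + 1e-9) {
    abort("`x_max` must not exceed the section A length.")
  }
  v_mean <- mean_velocity(flows$Q_aq, cross_section("rectangular",
    width = secA$width_um, height = secA$height_um
  ))
  D <- cm2_s_to_um2_s(props$D)
  Pe <- v_mean * w / D
  if (D > 0 && Pe <= 50) {
    abort(sprintf(
      paste0(
        "Peclet number v_mean*w/D = %.1f <= 50: the neglected axial-",
        "diffusion term D d2c/dx2 is not negligible; the parabolized ",
        "marching solver does not apply."
      ), Pe
    ))
  }

  nx <- grid$nx
  ny <- grid$ny
  x <- seq(0, x_max, length.out = nx)
  y <- seq(0, w, length.out = ny)
  dx <- x[2] - x[1]
  dy <- y[2] - y[1]

  u <- switch(profile,
    parabolic = velocity_profile(y, w, v_mean),
    plug = rep(v_mean, ny)
  )

  y_star <- inlet_interface_position(flows$Q_S, flows$Q_X, w)
  y_interface <- w - y_star
  conc <- matrix(0, nrow = nx, ncol = ny)
  conc[1, ] <- inlet_profile(y, dy, y_interface, c0)

  if (D > 0) {
    # A c_new = (u/dx) c_old with A = diag(u/dx) + D K, K the negative
    # second-difference operator with reflecting (zero-flux) walls. A is an
    # M-matrix, so the march is positivity-preserving and bounded by c0;
    # with trapezoidal weights the advective flux is conserved exactly.
    r <- D / dy^2
    main <- u / dx + 2 * r
    A <- diag(main)
    for (j in seq_len(ny - 1)) {
      A[j, j + 1] <- A[j + 1, j] <- -r
    }
    A[1, 2] <- A[ny, ny - 1] <- -2 * r
    step <- solve(A, diag(u / dx))
    for (i in seq_len(nx - 1)) {
      conc[i + 1, ] <- step %*% conc[i, ]
    }
  } else {
    conc[] <- rep(conc[1, ], each = nx)
  }

  structure(
    list(
      x = x, y = y, conc = conc, c0 = c0, interface_y = y_interface,
      w = w, v_mean = v_mean, D_um2_s = D, Pe = Pe, profile = profile
    ),
    class = "mixing_field"
  )
}

#' @export
print.mixing_field <- function(x, ...) {
  cat(sprintf(
    "<mixing_field> %d x %d nodes over %g x %g um, c0 = %g mM, Pe = %.0f (%s)\n",
    length(x$x), length(x$y), max(x$x), x$w, x$c0, x$Pe, x$profile
  ))
  invisible(x)
}

#' @rdname solve_mixing_field
#' @param x A `mixing_field`.
#' @param ... Unused.
#' @method tidy mixing_field
#' @export
tidy.mixing_field <- function(x, ...) {
  tidyr::expand_grid(x_um = x$x, y_um = x$y) |>
    dplyr::mutate(concentration_mM = as.vector(t(x$conc)))
}

#' Closed-form plug-flow mixing profile
#'
#' Analytic solution of transverse diffusion in a uniform stream with a
#' semi-infinite step inlet: c = c0/2 erfc((y_i - y) / (2 sqrt(D x / v))).
#' Used as the independent reference for the marching solver in the
#' plug-flow limit, valid while the walls remain unfelt.
#'
#' @param x,y Axial and transverse positions (um); vectorized.
#' @param y_interface Inlet interface position (um from the crystal-side wall).
#' @param D Diffusivity (um^2/s).
#' @param v Plug velocity (um/s).
#' @param c0 Inlet substrate concentration (mM).
#' @return Concentration (mM) for each (x, y) pair (recycled).
#' @export
plug_flow_erfc <- function(x, y, y_interface, D, v, c0) {
  tau <- x / v
  z <- (y_interface - y) / (2 * sqrt(pmax(D * tau, .Machine$double.xmin)))
  c0 / 2 * erfc_base(z)
}

#' Advective substrate flux across the channel
#'
#' Trapezoidal quadrature of u(y) c(x, y) over y at every axial station;
#' constant along x when mass is conserved.
#'
#' @param field A `mixing_field`.
#' @return A tibble with `x_um` and `flux` (mM um^2/s).
#' @export
advective_flux <- function(field) {
  stopifnot(inherits(field, "mixing_field"))
  u <- switch(field$profile,
    parabolic = velocity_profile(field$y, field$w, field$v_mean),
    plug = rep(field$v_mean, length(field$y))
  )
  wts <- rep(1, length(field$y))
  wts[c(1, length(wts))] <- 0.5
  dy <- field$y[2] - field$y[1]
  tibble::tibble(
    x_um = field$x,
    flux = as.vector(field$conc %*% (u * wts)) * dy
  )
}

#' Distance to the equimolarity condition along an offset line
#'
#' Finds the smallest axial distance L at which the substrate concentration
#' on the line `y_offset` um from the crystal-side wall reaches `c_eq`, the
#' protein concentration inside the crystals (mixing is deemed complete for
#' a crystal once the surrounding substrate matches the in-crystal protein
#' concentration). The offset reflects the finite crystal size: crystals
#' cannot approach the wall closer than their radius.
#'
#' @param field A `mixing_field`.
#' @param c_eq Equimolarity concentration (mM); must be below `c0`.
#' @param y_offset Offset of the evaluation line from the crystal-side wall
#'   (um).
#' @return Distance L (um), linearly interpolated between axial nodes, or
#'   `NA` with a `"not reached"` message attribute if `c_eq` is not attained
#'   within the solved domain.
#' @export
equimolar_distance <- function(field, c_eq = 23, y_offset = 20) {
  stopifnot(inherits(field, "mixing_field"))
  if (c_eq >= field$c0) {
    abort("`c_eq` must be below the inlet concentration `c0` (unreachable).")
  }
  if (y_offset < 0 || y_offset > field$w) abort("`y_offset` outside the channel.")
  c_line <- apply(field$conc, 1, function(row) {
    approx(field$y, row, xout = y_offset, rule = 2)$y
  })
  if (c_line[[1]] >= c_eq) {
    return(0)
  }
  idx <- which(c_line >= c_eq)
  if (length(idx) == 0) {
    return(structure(NA_real_, status = "not reached"))
  }
  i <- idx[[1]]
  # linear interpolation between the bracketing axial nodes
  x0 <- field$x[i - 1]
  x1 <- field$x[i]
  f <- (c_eq - c_line[i - 1]) / (c_line[i] - c_line[i - 1])
  x0 + f * (x1 - x0)
}

#' Mixing-time spread across streamlines
#'
#' Over the mixing distance L, the fastest crystals ride the centerline at
#' u(w/2) = 1.5 v_mean while the slowest admissible crystals ride the offset
#' line at u(y_offset); their residence-time difference is the mixing-time
#' spread delta_t_m.
#'
#' @param L Mixing distance (um).
#' @param w Channel width (um).
#' @param v_mean Mean aqueous velocity in the mixing channel (um/s).
#' @param y_offset Offset of the slow line from the wall (um); must not sit
#'   on a wall.
#' @return A one-row tibble: `t_fast`, `t_slow`, `delta_t_m` (s), and the
#'   velocity ratio `u_center_over_u_offset`.
#' @examples
#' mixing_spread(L = 165, w = 150, v_mean = 666.7, y_offset = 20)
#' @export
mixing_spread <- function(L, w, v_mean, y_offset = 20) {
  check_positive(L, "L")
  u_off <- velocity_profile(y_offset, w, v_mean)
  if (u_off <= 0) abort("`y_offset` sits on a wall: zero velocity there.")
  u_mid <- velocity_profile(w / 2, w, v_mean)
  t_fast <- L / u_mid
  t_slow <- L / u_off
  tibble::tibble(
    t_fast = t_fast, t_slow = t_slow, delta_t_m = t_slow - t_fast,
    u_center_over_u_offset = u_mid / u_off
  )
}

#' Total reaction-initiation spread
#'
#' Adds the intra-crystal diffusion time to the streamline mixing spread and
#' expresses the total as a fraction of the reaction time point.
#'
#' @param delta_t_m Streamline mixing-time spread (s).
#' @param t_crystal Diffusion time into the crystal interior (s); ~15 ms for
#'   shoebox crystals of 10 x 20 x 30 um.
#' @param t_R Reaction time point (s).
#' @return A one-row tibble: `delta_t_total` (s) and `fraction_of_tR`.
#' @examples
#' total_initiation_spread(delta_t_m = 0.0056, t_crystal = 0.015, t_R = 0.3)
#' @export
total_initiation_spread <- function(delta_t_m, t_crystal = 0.015, t_R) {
  check_positive(delta_t_m, "delta_t_m", strict = FALSE)
  check_positive(t_crystal, "t_crystal", strict = FALSE)
  check_positive(t_R, "t_R")
  total <- delta_t_m + t_crystal
  tibble::tibble(delta_t_total = total, fraction_of_tR = total / t_R)
}

#' Fraction of the crystal stream past the equimolarity condition
#'
#' Given the transverse position where equimolarity is met and the position
#' of the oil/aqueous interface (both measured along the same analysis line),
#' returns the fraction of the aqueous stream - hence of the crystals - that
#' has reached the equimolarity condition.
#'
#' @param equimolar_pos Position where equimolarity is met (um).
#' @param interface_pos Position of the oil/aqueous interface (um).
#' @return Fraction in (0, 1].
#' @examples
#' fraction_equimolar(68, 80)
#' @export
fraction_equimolar <- function(equimolar_pos, interface_pos) {
  check_positive(interface_pos, "interface_pos")
  check_positive(equimolar_pos, "equimolar_pos")
  if (equimolar_pos > interface_pos) {
    abort("`equimolar_pos` must not exceed `interface_pos`.")
  }
  equimolar_pos / interface_pos
}

#' @rdname solve_mixing_field
#' @param object A `mixing_field`.
#' @method autoplot mixing_field
#' @export
autoplot.mixing_field <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$x_um, .data$y_um,
      fill = .data$concentration_mM
    )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "c (mM)") +
    ggplot2::labs(
      x = "axial distance x (µm)",
      y = "transverse position y (µm)",
      title = "Substrate concentration in the mixing channel"
    ) +
    ggplot2::coord_cartesian(expand = FALSE)
}
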