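test_that("Einstein-relation viscosity correction of diffusivity", {
  D <- corrected_diffusivity(6.7e-6, 1.00, 5.39)
  expect_equal(signif(D, 2), 1.2e-6)
  expect_equal(corrected_diffusivity(3e-6, 2, 2), 3e-6) # eta = eta_ref
  expect_equal(
    corrected_diffusivity(3e-6, 1, 4),
    corrected_diffusivity(3e-6, 1, 2) / 2
  )
  # round trip with swapped viscosities recovers D_ref to machine precision
  expect_equal(corrected_diffusivity(D, 5.39, 1.00), 6.7e-6)
  expect_error(corrected_diffusivity(1e-6, 1, 0), "eta")
})

test_that("parabolic profile has no-slip walls and 1.5x centerline", {
  expect_equal(velocity_profile(75, 150, 100), 150)
  expect_equal(velocity_profile(0, 150, 100), 0)
  expect_equal(velocity_profile(150, 150, 100), 0)
  expect_equal(velocity_profile(20, 150, 1), 6 * (20 / 150) * (130 / 150))
  expect_error(velocity_profile(-1, 150, 100), "within")
})

test_that("inlet interface splits the parabolic flow by flow-rate fraction", {
  # symmetric split
  expect_equal(inlet_interface_position(1, 1, 150), 75)
  # brute-force quadrature oracle for the DG300 flow split
  w <- 150
  y_star <- inlet_interface_position(Q_S = 0.4, Q_X = 0.5, w = w)
  carried <- parabolic_flow_between(w - y_star, w, w)
  total <- parabolic_flow_between(0, w, w)
  expect_equal(carried / total, 0.4 / 0.9, tolerance = 1e-8)
  # vanishing substrate stream pushes the interface to the wall
  expect_lt(inlet_interface_position(1e-6, 1, w), 1)
})

test_that("zero diffusivity transports the inlet step unchanged", {
  dev <- preset_device("DG300-Y")
  props0 <- transport_properties(D_ref = 0, eta = 5.39)
  fld <- solve_mixing_field(dev, dg300_flows(), props0,
    grid = mixing_grid(32, 33)
  )
  for (i in seq_along(fld$x)) expect_equal(fld$conc[i, ], fld$conc[1, ])
})

test_that("plug-flow solver matches the erfc closed form", {
  dev <- preset_device("DG300-Y")
  fld <- solve_mixing_field(dev, dg300_flows(), nadh_props(),
    grid = mixing_grid(256, 257, x_max = 200), profile = "plug"
  )
  ref <- outer(fld$x, fld$y, function(x, y) {
    plug_flow_erfc(x, y, fld$interface_y, fld$D_um2_s, fld$v_mean, fld$c0)
  })
  rms <- sqrt(mean((fld$conc[-1, ] - ref[-1, ])^2)) / fld$c0
  expect_lt(rms, 0.02)
})

test_that("advective flux is conserved along the channel", {
  fld <- solve_mixing_field(
    preset_device("DG300-Y"), dg300_flows(), nadh_props(),
    grid = mixing_grid(128, 129)
  )
  fx <- advective_flux(fld)
  expect_lt(diff(range(fx$flux)) / fx$flux[[1]], 0.01)
})

test_that("concentration stays within [0, c0]", {
  fld <- solve_mixing_field(
    preset_device("DG300-Y"), dg300_flows(), nadh_props(),
    grid = mixing_grid(128, 129)
  )
  expect_gte(min(fld$conc), 0)
  expect_lte(max(fld$conc), fld$c0 * (1 + 1e-12))
})

test_that("long channels relax to the flow-weighted mean concentration", {
  long_dev <- device_geometry("long-A", tibble::tibble(
    label = c("A", "B", "C"),
    length_um = c(2e5, 285, 15400),
    shape = c("rectangular", "rectangular", "circular"),
    width_um = c(150, 150, NA), height_um = c(150, 150, NA),
    diameter_um = c(NA, NA, 100),
    flow_scope = c("aqueous_only", "total", "total")
  ))
  # slow flows so the full width equilibrates well before the outlet
  fl <- flow_config(Q_X = 0.04, Q_S = 0.032, Q_O = 1)
  fld <- solve_mixing_field(long_dev, fl, nadh_props(),
    grid = mixing_grid(256, 65)
  )
  target <- fld$c0 * 0.032 / 0.072
  expect_equal(fld$conc[nrow(fld$conc), ],
    rep(target, length(fld$y)),
    tolerance = 1e-3
  )
})

test_that("solver refuses low-Peclet problems by naming the neglected term", {
  thick <- transport_properties(D_ref = 6.7e-3, eta = 1) # absurdly diffusive
  expect_error(
    solve_mixing_field(
      preset_device("DG300-Y"), dg300_flows(), thick,
      grid = mixing_grid(32, 33)
    ),
    "axial"
  )
})

test_that("equimolar distance: edge cases and sentinel", {
  fld <- solve_mixing_field(
    preset_device("DG300-Y"), dg300_flows(), nadh_props(),
    grid = mixing_grid(128, 129)
  )
  expect_equal(equimolar_distance(fld, c_eq = 0, y_offset = 20), 0)
  expect_error(equimolar_distance(fld, c_eq = 300), "c_eq")
  # flow-weighted mean is ~133 mM: unreachable at the crystal wall in-domain
  near_mean <- equimolar_distance(fld, c_eq = 130, y_offset = 2)
  expect_true(is.na(near_mean))
  expect_equal(attr(near_mean, "status"), "not reached")
})

test_that("equimolar distance converges under grid refinement and responds
           monotonically to D and v", {
  dev <- preset_device("DG300-Y")
  # evaluate near the interface so equimolarity falls inside the domain
  L_coarse <- equimolar_distance(
    solve_mixing_field(dev, dg300_flows(), nadh_props(),
      grid = mixing_grid(128, 65)
    ),
    c_eq = 23, y_offset = 70
  )
  L_fine <- equimolar_distance(
    solve_mixing_field(dev, dg300_flows(), nadh_props(),
      grid = mixing_grid(256, 129)
    ),
    c_eq = 23, y_offset = 70
  )
  expect_lt(abs(L_fine - L_coarse) / L_fine, 0.05)

  L_fastD <- equimolar_distance(
    solve_mixing_field(dev, dg300_flows(),
      transport_properties(D_ref = 2 * 6.7e-6, eta = 5.39),
      grid = mixing_grid(256, 129)
    ),
    c_eq = 23, y_offset = 70
  )
  expect_lt(L_fastD, L_fine)

  L_fastflow <- equimolar_distance(
    solve_mixing_field(dev, flow_config(Q_X = 1.0, Q_S = 0.8, Q_O = 18.3),
      nadh_props(),
      grid = mixing_grid(256, 129)
    ),
    c_eq = 23, y_offset = 70
  )
  expect_gt(L_fastflow, L_fine)
})

test_that("mixing spread follows the streamline velocity ratio", {
  sp <- mixing_spread(L = 100, w = 150, v_mean = 1000, y_offset = 20)
  expect_equal(sp$t_fast, 100 / 1500)
  expect_equal(sp$t_slow / sp$t_fast, 1.5 / (6 * (20 / 150) * (130 / 150)))
  expect_equal(sp$delta_t_m, sp$t_slow - sp$t_fast)
  # same streamline: no spread
  expect_equal(mixing_spread(100, 150, 1000, y_offset = 75)$delta_t_m, 0)
  # linear in L
  sp2 <- mixing_spread(200, 150, 1000, 20)
  expect_equal(sp2$delta_t_m, 2 * sp$delta_t_m)
  expect_error(mixing_spread(100, 150, 1000, y_offset = 0), "wall")
})

test_that("total initiation spread adds crystal diffusion and normalizes", {
  tot <- total_initiation_spread(0.0056, 0.015, 0.3)
  expect_equal(tot$delta_t_total, 0.0206)
  expect_equal(round(100 * tot$fraction_of_tR), 7)
  expect_equal(total_initiation_spread(0.004, 0, 1)$delta_t_total, 0.004)
  expect_equal(total_initiation_spread(0, 0.015, 1.5)$fraction_of_tR, 0.01)
  expect_error(total_initiation_spread(0.01, 0.01, 0), "t_R")
})

test_that("equimolar crystal fraction is a position ratio", {
  expect_equal(fraction_equimolar(68, 80), 0.85)
  expect_equal(fraction_equimolar(80, 80), 1)
  expect_equal(fraction_equimolar(40, 80), 0.5)
  expect_error(fraction_equimolar(90, 80), "exceed")
  expect_error(fraction_equimolar(40, 0), "interface_pos")
})

test_that("mixing field tidies to a long tibble and plots", {
  fld <- solve_mixing_field(
    preset_device("DG300-Y"), dg300_flows(), nadh_props(),
    grid = mixing_grid(32, 33)
  )
  td <- tidy(fld)
  expect_equal(nrow(td), 32 * 33)
  expect_equal(
    td$concentration_mM[td$x_um == 0 & td$y_um == 150], fld$c0
  )
  expect_s3_class(autoplot(fld), "ggplot")
})
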