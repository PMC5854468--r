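test_that("normal curvature follows Euler's relation on cylinders and spheres", {
  cyl <- cylinder_surface(0.45)
  expect_identical(normal_curvature(cyl, 0), 0)
  expect_equal(normal_curvature(cyl, 90), -1 / 0.45)
  expect_equal(normal_curvature(cyl, 45), -0.5 / 0.45)
  sph <- sphere_surface(0.45)
  expect_equal(normal_curvature(sph, c(0, 30, 77)), rep(-1 / 0.45, 3))
})

test_that("energy profile minimum is circumferential with default parameters", {
  prof <- energy_profile(mechanics_params())
  expect_equal(prof$argmin_theta, 90)
  expect_gt(prof$well_depth, 1)             # well beyond thermal energy
  expect_true(prof$thermal_flag)
  expect_equal(prof$profile$delta_E_kT[prof$profile$theta_deg == 90], 0)
  # monotone non-increasing well on a cylinder less curved than kappa0
  expect_true(all(diff(prof$profile$delta_E_kT) < 1e-9))
})

test_that("umbilic surfaces give flat landscapes", {
  p <- mechanics_params()
  prof <- energy_profile(p, sphere_surface(0.45))
  expect_equal(max(abs(prof$profile$delta_E_kT)), 0, tolerance = 1e-6)
  expect_equal(filament_energy(p, sphere_surface(0.45), 10, 0),
               filament_energy(p, sphere_surface(0.45), 73, 0))
})

test_that("landscape is symmetric about 90 deg on quadric surfaces", {
  p <- mechanics_params()
  s <- cylinder_surface(0.45)
  for (th in c(10, 35, 60))
    expect_equal(filament_energy(p, s, th, 2),
                 filament_energy(p, s, 180 - th, 2), tolerance = 1e-12)
})

test_that("rigid-membrane numeric minimum matches the closed form to 1e-3 kT", {
  p <- mechanics_params(membrane_bending_modulus = 1e9)
  prof <- energy_profile(p)
  B <- curvtrack:::.flexural_rigidity(p)
  L <- p$filament_length
  k0 <- p$preferred_curvature * 1e-3
  R <- p$cell_radius * 1000
  kn <- abs(normal_curvature(cylinder_surface(p$cell_radius),
                             prof$profile$theta_deg)) * 1e-3
  closed <- 0.5 * B * L * ((kn - k0)^2 - (1 / R - k0)^2)
  expect_lt(max(abs(prof$profile$delta_E_kT - closed)), 1e-3)
  expect_lt(max(prof$profile$amplitude_nm), 1e-3)   # membrane undeformed
})

test_that("pressure-free floppy membrane lets the filament reach its preferred curvature", {
  # short filament so the preferred shape is reachable within the
  # amplitude bound
  p <- mechanics_params(membrane_bending_modulus = 1e-9,
                        osmotic_pressure = 0, filament_length = 100,
                        regime = "liposome")
  s <- cylinder_surface(0.45)
  opt <- curvtrack:::.min_over_amplitude(p, s, 0)
  k_adopt <- normal_curvature(s, 0) * 1e-3 - 8 * opt$amplitude / 100^2
  expect_equal(k_adopt, -p$preferred_curvature * 1e-3, tolerance = 1e-4)
  # and the landscape flattens: orientation preference vanishes
  prof <- energy_profile(p, s)
  expect_lt(max(abs(prof$profile$delta_E_kT)), 0.05)
})

test_that("negative amplitudes and invalid parameters are rejected", {
  p <- mechanics_params()
  expect_error(filament_energy(p, cylinder_surface(0.45), 45, -1),
               "amplitude")
  expect_error(mechanics_params(young_modulus = -1), "young_modulus")
  expect_error(mechanics_params(cell_radius = 0), "cell_radius")
})

test_that("well depth decreases with cell radius and scales with length when rigid", {
  sw <- sensitivity_sweep(mechanics_params(),
                          list(cell_radius = c(0.45, 1, 2.5)))
  expect_true(all(diff(sw$well_depth_kT) < 0))
  expect_true(all(sw$argmin_theta_deg == 90))
  # linearity of the bending term: rigid limit, well depth ~ L
  swl <- sensitivity_sweep(mechanics_params(membrane_bending_modulus = 1e9),
                           list(filament_length = c(100, 200, 400)))
  expect_equal(swl$well_depth_kT[2] / swl$well_depth_kT[1], 2,
               tolerance = 1e-3)
  expect_equal(swl$well_depth_kT[3] / swl$well_depth_kT[1], 4,
               tolerance = 1e-3)
})

test_that("adhesion energy shifts the landscape without moving its minimum", {
  sw <- sensitivity_sweep(mechanics_params(),
                          list(eps_bind = c(1, 10, 100)))
  expect_true(all(sw$argmin_theta_deg == 90))
  expect_equal(sw$well_depth_kT, rep(sw$well_depth_kT[1], 3),
               tolerance = 1e-6)
  expect_error(sensitivity_sweep(mechanics_params(), list(nonsense = 1)),
               "nonsense")
})

test_that("alignment-energy map orders neck > rod > sphere misalignment penalties", {
  p <- mechanics_params()
  m <- alignment_energy_map(
    p,
    kappa1 = c(0, 2, -1 / 0.45, 0),
    kappa2 = c(-1 / 0.45, -1 / 0.45, -1 / 0.45, 0))
  rod <- m$penalty_kT[1]; neck <- m$penalty_kT[2]
  sphere <- m$penalty_kT[3]; flat <- m$penalty_kT[4]
  expect_gt(neck, rod)          # saddle is the strongest aligner
  expect_gt(rod, 0)
  expect_equal(sphere, 0, tolerance = 1e-6)
  expect_equal(flat, 0, tolerance = 1e-6)
})
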