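test_that("random-field null tracks have the prescribed displacement, speed and metadata", {
  ts <- generate_tracks(trajectory_scenario("random_field", n_tracks = 50,
                                            seed = 1))
  expect_length(ts, 50)
  for (tr in ts) {
    disp <- sqrt(diff(range(tr$x))^2 + diff(range(tr$y))^2)
    expect_equal(disp, 1, tolerance = 1e-12)
    expect_equal(tr$meta$r2, 0.95)
    expect_equal(tr$meta$velocity, 0.025)
    expect_true(all(diff(tr$frames) > 0))
  }
  # placed on a 100 x 100 um field
  allx <- unlist(lapply(ts, `[[`, "x"))
  expect_true(all(allx > -1) && all(allx < 101))
})

test_that("random-field angles are uniform on [0, 180) (KS test)", {
  ts <- generate_tracks(trajectory_scenario("random_field", n_tracks = 1e4,
                                            seed = 42))
  ang <- vapply(ts, function(tr) fit_track_line(tr)$line_angle, numeric(1))
  ks <- suppressWarnings(ks.test(ang / 180, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("identical scenario and seed give bit-identical tracks", {
  sc <- trajectory_scenario("diffusive", n_tracks = 5, seed = 99,
                            localization_sigma = 0.01)
  a <- generate_tracks(sc)
  b <- generate_tracks(sc)
  expect_identical(a, b)
  c <- generate_tracks(trajectory_scenario("diffusive", n_tracks = 5,
                                           seed = 100,
                                           localization_sigma = 0.01))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("ballistic tracks are exactly collinear with unit line-fit quality", {
  ts <- generate_tracks(trajectory_scenario("ballistic", n_tracks = 3,
                                            speed = 0.04, seed = 2))
  for (tr in ts) expect_equal(fit_track_line(tr)$r2_orth, 1,
                              tolerance = 1e-12)
})

test_that("circumferential tracks concentrate at 90 deg to the midline as noise vanishes", {
  rod <- make_rod()
  # near-infinite von Mises concentration: all angles at 90
  ts <- generate_tracks(trajectory_scenario("circumferential", n_tracks = 20,
                                            angular_noise = 1e8, seed = 5),
                        rod)
  su <- summarize_tracks(ts)
  ang <- angle_to_midline(su$line_angle, su$mean_x, su$mean_y, rod)
  expect_true(all(abs(ang - 90) < 0.1))
  # sigma90 decreases as the concentration parameter grows
  s90 <- vapply(c(0.5, 4, 20), function(k) {
    ts <- generate_tracks(
      trajectory_scenario("circumferential", n_tracks = 150,
                          angular_noise = k, seed = 7), rod)
    su <- summarize_tracks(ts)
    sigma90(angle_to_midline(su$line_angle, su$mean_x, su$mean_y, rod))
  }, numeric(1))
  expect_true(all(diff(s90) < 0))
})

test_that("unknown trajectory kind is rejected by name", {
  expect_error(trajectory_scenario("levy_flight"), "levy_flight")
})

test_that("MSD fixtures obey their closed forms", {
  # pure drift: MSD(t) = (Vt)^2, log-log slope exactly 2
  tr <- generate_msd_fixture("ballistic", list(speed = 0.025, n_frames = 60))
  msd <- track_msd(tr)
  expect_equal(msd$msd, (0.025 * msd$t_s)^2, tolerance = 1e-10)
  expect_equal(fit_msd(tr)$alpha_loglog, 2, tolerance = 1e-8)
  # stationary: MSD identically zero
  tr0 <- generate_msd_fixture("ballistic", list(speed = 0, n_frames = 20))
  expect_true(all(track_msd(tr0)$msd == 0))
  # diffusive with fixed seed: alpha within [0.9, 1.1]
  trd <- generate_msd_fixture("diffusive",
                              list(diffusion_coeff = 0.01, n_frames = 1e4),
                              seed = 7)
  fd <- fit_msd(trd, max_lag = 100)
  expect_gt(coef(fd)[["alpha"]], 0.9)
  expect_lt(coef(fd)[["alpha"]], 1.1)
  expect_error(generate_msd_fixture("diffusive",
                                    list(diffusion_coeff = -1)),
               "diffusion_coeff")
})

test_that("synthetic contours match their defining geometry", {
  circ <- make_circle(radius = 0.7, n = 64)
  r <- sqrt((circ$x - mean(circ$x))^2 + (circ$y - mean(circ$y))^2)
  expect_equal(r, rep(0.7, length(r)), tolerance = 1e-9)
  rod <- make_rod(width = 0.9, length = 3)
  expect_equal(diff(range(rod$y)), 0.9, tolerance = 1e-3)
  expect_gt(curvtrack:::.polygon_signed_area(rod$x, rod$y), 0)  # CCW
  expect_error(generate_contour(
    contour_scenario("bulged_sphere", radius = 0.5, bulge_width = 1.2)),
    "bulge_width")
})

test_that("bulged-sphere neck curvature is sign-opposite to the body", {
  bs <- generate_contour(contour_scenario("bulged_sphere", radius = 0.5,
                                          bulge_width = 0.5,
                                          neck_depth = 0.2,
                                          n_vertices = 160))
  k <- sidewall_curvature(bs, smooth_window = 0)
  sect <- bs$meta$section
  # interior vertices only: triples straddling section joints mix signs
  interior <- function(lbl) {
    i <- which(sect == lbl)
    i[c(-1, -2, -(length(i) - 1), -length(i))]
  }
  expect_true(all(k[interior("neck")] < 0))
  expect_true(all(k[interior("body")] > 0))
  expect_true(all(k[interior("bulge")] > 0))
})
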