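test_that("orthogonal line fit recovers exact lines and flags degenerate tracks", {
  lf <- fit_track_line(make_line_track(30))
  expect_equal(lf$line_angle, 30, tolerance = 1e-9)
  expect_equal(lf$r2_orth, 1, tolerance = 1e-12)
  # two-point vertical track
  v <- track("v", 1:2, c(0, 0), c(0, 1), 1)
  expect_equal(fit_track_line(v)$line_angle, 90)
  expect_error(fit_track_line(track("z", 1:5, rep(1, 5), rep(2, 5), 1)),
               "zero-variance")
  # isotropic cloud: explained variance fraction near 1/2
  set.seed(11)
  cl <- track("c", 1:2000, rnorm(2000), rnorm(2000), 1)
  expect_equal(fit_track_line(cl)$r2_orth, 0.5, tolerance = 0.05)
})

test_that("fold transform matches the two-step definition and is idempotent", {
  expect_equal(fold_angle_90(-30), 30)   # -30 -> 150 -> 30
  expect_equal(fold_angle_90(150), 30)
  expect_equal(fold_angle_90(c(0, 90, 91, 180, -180, 270)),
               c(0, 90, 89, 0, 0, 90))
  set.seed(3)
  d <- runif(200, -720, 720)
  f <- fold_angle_90(d)
  expect_true(all(f >= 0 & f <= 90))
  expect_equal(fold_angle_90(f), f)                      # idempotent
  expect_equal(fold_angle_90(180 - d), f)                # axial symmetry
})

test_that("sigma90 matches hand values and the uniform-angle limit", {
  expect_equal(sigma90(c(90, 90, 90)), 0)
  expect_equal(sigma90(c(60, 120)), 30)
  set.seed(4)
  u <- runif(1e5, 0, 180)
  expect_equal(sigma90(u), 90 / sqrt(3), tolerance = 0.01)
  expect_equal(sigma90(u), sigma90(180 - u))             # axial symmetry
  expect_error(sigma90(numeric(0)), "empty")
})

test_that("angle to midline folds correctly for parallel and perpendicular tracks", {
  rod <- make_rod(width = 1, length = 4)
  expect_equal(angle_to_midline(0, 0, 0, rod), 0, tolerance = 0.5)
  expect_equal(angle_to_midline(90, 0, 0, rod), 90, tolerance = 0.5)
  expect_equal(angle_to_midline(120, 0, 0, rod), 60, tolerance = 0.5)
  expect_warning(a <- angle_to_midline(45, 0, 0, make_circle()), "round")
  expect_true(is.na(a))
})

test_that("MSD fits recover generator parameters across model variants", {
  # drift model: V exact, D ~ 0 on a noiseless ballistic track
  tr <- generate_msd_fixture("ballistic", list(speed = 0.025, n_frames = 60))
  cf <- coef(fit_msd(tr))
  expect_equal(cf[["V"]], 0.025, tolerance = 1e-6)
  expect_lt(cf[["D"]], 1e-8)
  # diffusive: D within Monte-Carlo tolerance of the generator value
  trd <- generate_msd_fixture("diffusive",
                              list(diffusion_coeff = 0.01, n_frames = 1e4),
                              seed = 7)
  cfd <- coef(fit_msd(trd, max_lag = 100))
  expect_equal(cfd[["D"]], 0.01, tolerance = 0.15)
  expect_lt(cfd[["V"]], 0.005)
  # stationary + localization noise: flat MSD at 4 sigma^2, alpha ~ 0
  set.seed(8)
  sig <- 0.02
  trs <- track("s", 1:200, rnorm(200, 0, sig), rnorm(200, 0, sig), 1)
  f <- fit_msd(trs, "drift_diffusion_locnoise", max_lag = 50)
  expect_equal(coef(f)[["sigma_loc"]], sig, tolerance = 0.25)
  expect_lt(abs(f$alpha_loglog), 0.25)
  # power-law variant on a ballistic track: alpha = 2, C = V^2
  fp <- fit_msd(tr, "powerlaw_locnoise")
  expect_equal(coef(fp)[["alpha"]], 2, tolerance = 1e-3)
  expect_equal(coef(fp)[["C"]], 0.025^2, tolerance = 1e-4)
  expect_error(fit_msd(track("x", 1:3, 1:3, 1:3, 1)), "fewer than 5")
})

test_that("directional filters apply the standard cutoffs with per-predicate attrition", {
  ts <- generate_tracks(trajectory_scenario("random_field", n_tracks = 30,
                                            seed = 6))
  su <- summarize_tracks(ts)
  expect_true(all(su$r2_orth == 0.95))       # recorded metadata is honored
  rep <- apply_filters(su)
  expect_equal(rep$n_out, 30)                # null tracks pass by design
  # a short-displacement track is dropped by the displacement predicate
  small <- make_line_track(20, n = 10, step = 0.01, id = "small")
  su2 <- rbind(su, summarize_tracks(list(small)))
  rep2 <- apply_filters(su2)
  expect_equal(rep2$n_out, 30)
  expect_equal(unname(rep2$attrition[["displacement"]]), 1L)
  # identity filter with all thresholds released
  open <- filter_policy(r2_orth_min = -Inf, displacement_min_um = -Inf,
                        velocity_min_um_s = -Inf, r2_loglog_min = -Inf,
                        min_frames = 0L)
  expect_equal(apply_filters(su2, open)$n_out, 31)
})

test_that("tightening any threshold never enlarges the retained set", {
  set.seed(12)
  ts <- c(generate_tracks(trajectory_scenario("ballistic", n_tracks = 10,
                                              speed = 0.02, seed = 1,
                                              localization_sigma = 0.02)),
          generate_tracks(trajectory_scenario("diffusive", n_tracks = 10,
                                              diffusion_coeff = 0.005,
                                              seed = 2)))
  su <- summarize_tracks(track_set(ts))
  base <- filter_policy(r2_orth_min = 0.5, displacement_min_um = 0.05,
                        velocity_min_um_s = 1e-9, r2_loglog_min = 0.3)
  kept <- apply_filters(su, base)$retained$track_id
  for (fld in c("r2_orth_min", "displacement_min_um", "velocity_min_um_s",
                "r2_loglog_min")) {
    tight <- base
    tight[[fld]] <- base[[fld]] + abs(base[[fld]]) * 0.5 + 0.1
    kept2 <- apply_filters(su, tight)$retained$track_id
    expect_true(all(kept2 %in% kept))
  }
})

test_that("single-molecule policy enforces track-length and stricter fit bounds", {
  pol <- single_molecule_policy()
  su <- data.frame(track_id = c("a", "b", "c"), n_frames = c(9L, 50L, 121L),
                   mean_x = 0, mean_y = 0, line_angle = 0, r2_orth = 1,
                   displacement = 1, velocity_msd = 1e-3,
                   diffusion_D = 0, alpha = 2, r2_loglog = 0.99,
                   converged = TRUE)
  rep <- apply_filters(su, pol)
  expect_equal(rep$retained$track_id, "b")   # 10-120 frame window
  su$r2_loglog <- 0.9                        # below the 0.95 cutoff
  expect_equal(apply_filters(su, pol)$n_out, 0)
})

test_that("pairwise statistics: parallel, orthogonal, and rotation invariance", {
  # all tracks parallel: median angle difference 0, mean DP 1 in all bins
  su <- do.call(rbind, lapply(1:6, function(i)
    summarize_tracks(list(make_line_track(25, x0 = i * 0.4, id = i)))))
  ps <- pairwise_statistics(su, neighborhood_min = 0)
  expect_equal(ps$median_dtheta_close, 0, tolerance = 1e-9)
  occupied <- !is.na(ps$bins$mean_dp)
  expect_equal(ps$bins$mean_dp[occupied],
               rep(1, sum(occupied)), tolerance = 1e-9)
  # two orthogonal tracks: delta-theta 90, DP = cos(90) = 0
  su2 <- rbind(summarize_tracks(list(make_line_track(0, id = "h"))),
               summarize_tracks(list(make_line_track(90, x0 = 0.5, id = "v"))))
  ps2 <- pairwise_statistics(su2, neighborhood_min = 0)
  expect_equal(ps2$pairs$delta_theta, 90, tolerance = 1e-9)
  expect_equal(ps2$pairs$dp, 0, tolerance = 1e-9)
  # global rotation leaves the mean dot product unchanged
  set.seed(9)
  angs <- runif(12, 0, 180)
  mk <- function(shift) do.call(rbind, lapply(seq_along(angs), function(i)
    summarize_tracks(list(make_line_track((angs[i] + shift) %% 180,
                                          x0 = (i %% 4) * 0.7,
                                          y0 = (i %/% 4) * 0.7, id = i)))))
  psA <- pairwise_statistics(mk(0), neighborhood_min = 0)
  psB <- pairwise_statistics(mk(33), neighborhood_min = 0)
  expect_equal(abs(psA$pairs$dp), abs(psB$pairs$dp), tolerance = 1e-9)
  expect_equal(psA$pairs$delta_theta, psB$pairs$delta_theta,
               tolerance = 1e-9)
})

test_that("uniform-null pairwise folded angles are uniform on [0, 90] with median 45", {
  set.seed(21)
  n <- 300
  su <- data.frame(track_id = seq_len(n), n_frames = 20L,
                   mean_x = runif(n, 0, 10), mean_y = runif(n, 0, 10),
                   line_angle = runif(n, 0, 180), r2_orth = 1,
                   displacement = 1, velocity_msd = 0.025, diffusion_D = 0,
                   alpha = 2, r2_loglog = 1, converged = TRUE)
  ps <- pairwise_statistics(su, max_distance = 15)
  expect_equal(median(ps$pairs$delta_theta), 45, tolerance = 0.06)
  ks <- suppressWarnings(ks.test(ps$pairs$delta_theta / 90, "punif"))
  expect_gt(ks$p.value, 1e-4)   # pairs are correlated; crude uniformity only
})

test_that("angle-width binning separates aligned rods from isotropic spheres", {
  rod <- make_rod(width = 1, length = 4)
  ts <- generate_tracks(trajectory_scenario("circumferential",
                                            n_tracks = 120,
                                            angular_noise = 8, seed = 13),
                        rod)
  su <- summarize_tracks(ts)
  ang_rod <- angle_to_midline(su$line_angle, su$mean_x, su$mean_y, rod)
  w_rod <- vapply(seq_len(nrow(su)), function(i)
    local_width(rod, su$mean_x[i], su$mean_y[i]), numeric(1))
  # isotropic population, nominal 2.5 um width
  set.seed(14)
  ang_iso <- fold_angle_90(runif(120, 0, 180))
  w_iso <- rep(2.5, 120)
  tab <- angle_width_binning(c(ang_rod, ang_iso), c(w_rod, w_iso),
                             bin_width = 0.5)
  narrow <- tab$median_angle[tab$width_mid < 1.5]
  wide <- tab$median_angle[tab$width_mid > 2]
  expect_gt(min(narrow), 65)
  expect_lt(max(wide), 55)
  expect_true(all(tab$n >= 5))
})
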