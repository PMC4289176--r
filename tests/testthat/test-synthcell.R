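test_that("two-stroke trajectory honors the phase model and its limits", {
  # zero motion: both series constant
  cfg0 <- scene_config(n_frames = 6, nucleus_speed_um_s = 0,
                       lead_amplitude_um = 0)
  tr0 <- two_stroke_trajectory(cfg0)
  expect_equal(diff(tr0$nucleus_um), rep(0, 5))
  expect_equal(diff(tr0$organelle_um), rep(0, 5))

  # constant-speed mode: mean step length exactly v * dt
  cfgv <- scene_config(n_frames = 10, nucleus_speed_um_s = 0.012,
                       lead_amplitude_um = 0, frame_interval_s = 120)
  trv <- two_stroke_trajectory(cfgv)
  expect_equal(mean(diff(trv$nucleus_um)), 0.012 * 120)

  # organelle leads (or coincides) at all times; per-cycle advance = v*P
  cfg <- scene_config(n_frames = 13, nucleus_speed_um_s = 0.009,
                      lead_amplitude_um = 5, cycle_period_s = 480,
                      frame_interval_s = 120)
  tr <- two_stroke_trajectory(cfg)
  expect_true(all(tr$organelle_um - tr$nucleus_um >= -1e-12))
  i0 <- which(tr$time_s == 0); i1 <- which(tr$time_s == 480)
  expect_equal(tr$nucleus_um[i1] - tr$nucleus_um[i0], 0.009 * 480,
               tolerance = 1e-9)
})

test_that("post-drug step sizes scale by the stated factor", {
  cfg <- scene_config(n_frames = 31, frame_interval_s = 120,
                      nucleus_speed_um_s = 0.01, lead_amplitude_um = 0,
                      drug_time_s = 24 * 60, post_drug_factor = 0.25,
                      n_x = 320)
  tr <- two_stroke_trajectory(cfg)
  steps <- diff(tr$nucleus_um)
  pre <- steps[tr$time_s[-1] <= 24 * 60]
  post <- steps[tr$time_s[-1] > 24 * 60]
  expect_equal(mean(post) / mean(pre), 0.25, tolerance = 1e-9)
})

test_that("invalid trajectory configs are rejected", {
  expect_error(scene_config(frame_interval_s = 0),
               class = "neurokym_config_error")
  expect_error(scene_config(cycle_period_s = 100, frame_interval_s = 120),
               class = "neurokym_config_error")
  expect_error(scene_config(post_drug_factor = 1.5),
               class = "neurokym_config_error")
})

test_that("rendered static scenes are identical across frames", {
  cfg <- scene_config(n_frames = 3, n_z = 7, n_y = 40, n_x = 120,
                      voxel_z_um = 1, soma_radius_um = 3,
                      process_length_um = 10, nucleus_speed_um_s = 0,
                      lead_amplitude_um = 0, start_x_um = 8,
                      trailing_length_um = 6, adhesion_x_um = c(12, 16))
  sc <- render_scene(cfg)
  expect_identical(sc$stack$data[1, , , , ], sc$stack$data[2, , , , ])
  expect_identical(sc$stack$data[1, , , , ], sc$stack$data[3, , , , ])
})

test_that("organelle channel centroid matches ground truth every frame", {
  sc <- test_scene()
  st <- sc$stack
  vmax <- max(st$voxel_size_um)
  for (t in seq_len(dim(st)[1])) {
    v <- st$data[t, 2, , , ]
    idx <- which(v > 0)
    pts <- neurokym:::ind_to_um(arrayInd(idx, dim(v)), st$voxel_size_um)
    ctr <- colSums(pts * v[idx]) / sum(v[idx])
    truth <- unlist(sc$truth$frames[t, c("organelle_x_um", "organelle_y_um",
                                         "organelle_z_um")])
    expect_lt(sqrt(sum((ctr - truth)^2)), 0.5 * vmax)
  }
})

test_that("seed changes voxel noise but never the ground truth", {
  base <- list(n_frames = 2, n_z = 7, n_y = 40, n_x = 100, voxel_z_um = 1,
               soma_radius_um = 3, process_length_um = 8, start_x_um = 8,
               trailing_length_um = 6, gaussian_noise_sd = 3,
               poisson_noise = TRUE)
  s1 <- render_scene(do.call(scene_config, c(base, seed = 1)))
  s2 <- render_scene(do.call(scene_config, c(base, seed = 2)))
  s1b <- render_scene(do.call(scene_config, c(base, seed = 1)))
  expect_identical(s1$truth$frames, s2$truth$frames)
  expect_false(identical(s1$stack$data, s2$stack$data))
  expect_identical(s1$stack$data, s1b$stack$data)
})

test_that("noise-free cytoplasm intensity is conserved as the cell translates", {
  cfg <- scene_config(n_frames = 5, n_z = 9, n_y = 40, n_x = 200,
                      voxel_z_um = 1, soma_radius_um = 3,
                      process_length_um = 14, nucleus_speed_um_s = 0.02,
                      lead_amplitude_um = 4, cycle_period_s = 480,
                      hotspot_sigma_um = 1.5, start_x_um = 12)
  sc <- render_scene(cfg)
  totals <- vapply(seq_len(cfg$n_frames), function(t)
    sum(sc$stack$data[t, 3, , , ]), numeric(1))
  expect_equal(totals, rep(totals[1], length(totals)), tolerance = 1e-8)
})

test_that("adhesion puncta stay fixed in the lab frame", {
  sc <- test_scene()
  for (t in 2:dim(sc$stack)[1])
    expect_identical(sc$stack$data[t, 4, , , ], sc$stack$data[1, 4, , , ])
})

test_that("a cell larger than the grid raises a geometry error naming the frame", {
  expect_error(
    render_scene(scene_config(n_frames = 8, n_x = 100,
                              nucleus_speed_um_s = 0.05,
                              lead_amplitude_um = 0,
                              frame_interval_s = 600,
                              cycle_period_s = 1200,
                              process_length_um = 15, start_x_um = 6)),
    "frame", class = "neurokym_geometry_error")
})

test_that("FRAP traces follow the recovery model exactly when noise is off", {
  g <- generate_frap_trace(k = log(2) / 10, mobile_fraction = 0.7,
                           pre_level = 100, bleach_depth = 0.8,
                           interval_s = 2, duration_s = 60)
  tr <- g$trace
  expect_equal(tr$intensity[1], 20)                 # floor at t = 0
  expect_equal(g$truth$t_half_s, 10)
  # half-life definition: value at t = 10 is midway floor -> plateau
  mid <- (g$truth$post_level + g$truth$plateau) / 2
  expect_equal(tr$intensity[tr$time_s == 10], mid)

  # full recovery limit
  g1 <- generate_frap_trace(k = 0.5, mobile_fraction = 1, pre_level = 100,
                            interval_s = 2, duration_s = 20 / 0.5)
  expect_equal(utils::tail(g1$trace$intensity, 1), 100, tolerance = 1e-6)

  expect_error(generate_frap_trace(k = 0.1, mobile_fraction = 0.5,
                                   bleach_depth = 0),
               class = "neurokym_config_error")
  # determinism under seed
  a <- generate_frap_trace(0.2, 0.8, noise_sd = 2, seed = 5)$trace
  b <- generate_frap_trace(0.2, 0.8, noise_sd = 2, seed = 5)$trace
  expect_identical(a, b)
})
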