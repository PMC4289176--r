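test_that("walls zero exactly the rasterized line and nothing else", {
  vol <- array(7, c(4, 10, 10))
  expect_identical(apply_walls(vol, list()), vol)

  w <- wall(rbind(c(5, 0), c(5, 9)))
  out <- apply_walls(vol, list(w))
  expect_equal(sum(out == 0), 10 * 4)      # 10 raster pixels x z-extent
  expect_true(all(out[, , 6] == 0))        # x = 5 (0-based) column
  expect_equal(sum(out), 7 * (4 * 10 * 10 - 40))

  # diagonal wall: brute-force Bresenham count
  wd <- wall(rbind(c(0, 0), c(9, 6)))
  px <- neurokym:::rasterize_wall(wd)
  outd <- apply_walls(vol, list(wd))
  expect_equal(sum(outd == 0), nrow(px) * 4)

  expect_error(apply_walls(vol, list(wall(rbind(c(-2, 0), c(5, 5))))),
               class = "neurokym_geometry_error")
})

test_that("seeded segmentation equals a brute-force flood fill", {
  set.seed(7)
  for (rep in 1:10) {
    vol <- array(runif(5 * 8 * 8), c(5, 8, 8))
    thr <- 0.45
    above <- vol >= thr
    seeds <- which(above)
    if (!length(seeds)) next
    sv <- arrayInd(seeds[1], dim(vol))  # (z, y, x) 1-based
    res <- segment_frame(vol, thr, c(sv[3], sv[2], sv[1]) - 1L)
    oracle <- brute_flood(above, sv)
    expect_identical(res$mask, oracle)
  }
})

test_that("uniform volumes and separated blobs segment as expected", {
  vol <- array(10, c(3, 6, 6))
  res <- segment_frame(vol, 5, c(0, 0, 0))
  expect_true(all(res$mask))

  # two blobs separated by background: only the seeded one
  vol <- array(0, c(3, 8, 12))
  vol[, 3:6, 2:4] <- 10   # blob A
  vol[, 3:6, 8:11] <- 10  # blob B
  res <- segment_frame(vol, 5, c(2, 3, 1))
  expect_true(all(which(res$mask) %in% which(vol == 10)))
  expect_equal(res$n_voxels, 3 * 4 * 3)

  expect_error(segment_frame(vol, 5, c(5, 0, 0)),
               class = "neurokym_data_error")
  expect_warning(segment_frame(array(1, c(2, 3, 3)), 0, c(0, 0, 0)),
                 "all-positive")
})

test_that("walls separate abutting blobs from a seeded segmentation", {
  vol <- array(0, c(3, 8, 13))
  vol[, 2:7, 2:6] <- 10
  vol[, 2:7, 7:11] <- 10   # abutting: one 6-connected component
  res_nowall <- segment_frame(vol, 5, c(3, 4, 1))
  expect_equal(res_nowall$n_voxels, 3 * 6 * 10)
  w <- wall(rbind(c(6, 0), c(6, 7)))
  res <- segment_frame(vol, 5, c(3, 4, 1), walls = list(w))
  ind <- arrayInd(which(res$mask), dim(vol))
  expect_true(all(ind[, 3] <= 6))  # nothing at or beyond the wall (x >= 6)
})

test_that("mask volume of the synthetic neuron matches the analytic solid", {
  cfg <- scene_config(n_frames = 1, n_z = 11, n_y = 40, n_x = 120,
                      voxel_z_um = 1, soma_radius_um = 3,
                      process_length_um = 14,
                      process_halfwidth_base_um = 1.5,
                      process_halfwidth_tip_um = 0.4,
                      trailing_length_um = 8, trailing_halfwidth_um = 1.2,
                      nucleus_speed_um_s = 0, lead_amplitude_um = 0,
                      hotspot_amplitude = 0, start_x_um = 10)
  sc <- render_scene(cfg)
  vol <- sc$stack$data[1, 3, , , ]
  seed0 <- truth_seed_voxel(sc, 1)
  res <- segment_frame(vol, cfg$actin_baseline / 2, seed0)
  vox_vol <- prod(c(0.25, 0.25, 1))
  # analytic union: sphere + tapered cone and trailing tube beyond it
  R <- 3; L <- 14; w0 <- 1.5; w1 <- 0.4; Tl <- 8; wt <- 1.2
  wfun <- function(x) w0 + (w1 - w0) * x / L
  xstar <- uniroot(function(x) sqrt(pmax(R^2 - x^2, 0)) - wfun(x),
                   c(0, R))$root
  v_analytic <- 4 / 3 * pi * R^3 +
    integrate(function(x) pi * wfun(x)^2, xstar, L)$value +
    pi * wt^2 * (Tl - sqrt(R^2 - wt^2))
  expect_lt(abs(res$n_voxels * vox_vol - v_analytic) / v_analytic, 0.1)
})

test_that("segmentation is idempotent and monotone in the threshold", {
  sc <- test_scene()
  vol <- sc$stack$data[1, 3, , , ]
  seed0 <- truth_seed_voxel(sc, 1)
  thr <- sc$cfg$actin_baseline / 2
  res <- segment_frame(vol, thr, seed0)
  masked <- vol * res$mask
  res2 <- segment_frame(masked, thr, seed0)
  expect_identical(res2$mask, res$mask)

  hi <- segment_frame(vol, thr * 1.4, seed0)
  expect_true(all(which(hi$mask) %in% which(res$mask)))
})

test_that("sequence segmentation tracks the moving cell and flags failures", {
  sc <- test_scene()
  seg <- test_segmentation()
  expect_false(any(seg$qc$flagged))
  # every true nucleus position lies inside its frame's mask
  vs <- sc$stack$voxel_size_um
  for (t in seq_len(dim(sc$stack)[1])) {
    fr <- sc$truth$frames[t, ]
    zyx <- round(c(fr$nucleus_z_um / vs[["z"]], fr$nucleus_y_um / vs[["y"]],
                   fr$nucleus_x_um / vs[["x"]])) + 1L
    expect_true(seg$masks[[t]][zyx[1], zyx[2], zyx[3]])
  }

  # static noiseless scene: identical masks at all frames
  cfg0 <- scene_config(n_frames = 3, n_z = 7, n_y = 40, n_x = 100,
                       voxel_z_um = 1, soma_radius_um = 3,
                       process_length_um = 8, nucleus_speed_um_s = 0,
                       lead_amplitude_um = 0, hotspot_amplitude = 0,
                       trailing_length_um = 6, start_x_um = 8)
  sc0 <- render_scene(cfg0)
  seg0 <- segment_sequence(sc0$stack, "actin", cfg0$actin_baseline / 2,
                           truth_seed_voxel(sc0, 1))
  expect_identical(seg0$masks[[1]], seg0$masks[[2]])
  expect_identical(seg0$masks[[1]], seg0$masks[[3]])

  # a frame with no cell signal is flagged, not silently empty
  dark <- sc0$stack
  dark$data[2, 3, , , ] <- 0
  expect_warning(
    segd <- segment_sequence(dark, "actin", cfg0$actin_baseline / 2,
                             truth_seed_voxel(sc0, 1)),
    "flagged")
  expect_true(segd$qc$flagged[2])
  expect_false(any(segd$qc$flagged[-2]))
})

test_that("an extruded 8-connected wall blocks every 6-connected path", {
  set.seed(21)
  for (rep in 1:12) {
    nz <- sample(2:4, 1); ny <- 10; nx <- 12
    vol <- array(0, c(nz, ny, nx))
    wx <- sample(4:7, 1)
    # random blobs touching the wall column from both sides
    for (k in 1:12) {
      y <- sample(ny, 1); xa <- sample(1:wx, 1); xb <- sample((wx + 2):nx, 1)
      vol[, y, xa:(wx + 1)] <- 10     # A side reaches the wall column
      vol[, y, (wx + 1):xb] <- 10     # B side reaches it too
    }
    w <- wall(rbind(c(wx, 0), c(wx, ny - 1)))
    seed <- c(sample(1:wx, 1) - 1, sample(ny, 1) - 1, 0)
    vol[seed[3] + 1, seed[2] + 1, seed[1] + 1] <- 10
    res <- segment_frame(vol, 5, seed, walls = list(w))
    ind <- arrayInd(which(res$mask), dim(vol))
    expect_true(all(ind[, 3] <= wx))  # no voxel at/right of the wall column
    # cross-check with the brute-force flood on the walled volume
    walled <- apply_walls(vol, list(w))
    oracle <- brute_flood(walled >= 5, c(seed[3], seed[2], seed[1]) + 1L)
    expect_identical(res$mask, oracle)
  }
})

test_that("segmentation masks round-trip through TIFF", {
  seg <- test_segmentation()
  path <- tempfile(fileext = ".tif")
  write_segmentation(seg, path)
  back <- read_segmentation(path)
  expect_identical(back$masks, seg$masks)
  expect_equal(back$threshold, seg$threshold)
  expect_equal(back$qc$mask_voxels, seg$qc$mask_voxels)
})
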