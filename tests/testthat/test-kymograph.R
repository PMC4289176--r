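test_that("migration axis construction and projection are exact", {
  ax <- migration_axis(c(0, 0, 0), c(30, 40, 0))
  expect_equal(ax$direction, c(0.6, 0.8, 0))
  expect_error(migration_axis(c(1, 2, 3), c(1, 2, 3)),
               class = "neurokym_geometry_error")

  tr <- track("t", 0:2, rbind(c(0, 0, 0), c(3, 4, 0), c(6, 8, 0)))
  pr <- project_track(tr, ax)
  expect_equal(pr$s_um, c(0, 5, 10))

  # random tracks match brute-force dot products
  set.seed(5)
  for (i in 1:5) {
    o <- rnorm(3); d <- random_unit_vector()
    axr <- migration_axis(o, o + 7 * d)
    pos <- matrix(rnorm(12), 4, 3)
    trr <- track("r", 0:3, pos)
    manual <- apply(pos, 1, function(p) sum((p - o) * d))
    expect_equal(project_track(trr, axr)$s_um, manual)
  }
})

test_that("auto-selected axis on a straight synthetic neuron is accurate", {
  sc <- test_scene()
  seg <- test_segmentation()
  origin <- sc$truth$axis_origin_um
  ax <- migration_axis(origin, mask = seg$masks[[1]],
                       voxel_size_um = sc$stack$voxel_size_um)
  cosang <- sum(ax$direction * sc$truth$axis_direction)
  expect_gt(cosang, cos(5 * pi / 180))
})

test_that("kymograph binning matches the definition on hand cases", {
  # one masked voxel with s = 2.5 * delta lands in bin 2 for both statistics
  vol <- array(0, c(1, 1, 6)); vol[1, 1, 4] <- 7   # x index 3 (0-based)
  mask <- vol > 0
  st <- make_stack(list(list(vol)), voxel = c(x = 1, y = 1, z = 1))
  seg <- fake_segmentation(list(mask))
  ax <- migration_axis(c(0.5, 0, 0), c(6, 0, 0))   # s = 3 - 0.5 = 2.5
  for (stat in c("sum", "max")) {
    k <- volumetric_kymograph(st, 0, seg, ax, stat)
    expect_equal(k$bin0_offset_um, 2)     # the only occupied bin is bin 2
    expect_equal(as.vector(k$matrix), 7)
  }

  # a cross-section holding {1, 2, 3}: sum 6, max 3
  vol <- array(0, c(3, 1, 1)); vol[, 1, 1] <- 1:3
  st <- make_stack(list(list(vol)))
  seg <- fake_segmentation(list(vol > 0))
  ax <- migration_axis(c(0, 0, 0), c(1, 0, 0))  # all voxels at s = 0
  ks <- volumetric_kymograph(st, 0, seg, ax, "sum")
  km <- volumetric_kymograph(st, 0, seg, ax, "max")
  expect_equal(as.vector(ks$matrix), 6)
  expect_equal(as.vector(km$matrix), 3)
})

test_that("kymographs agree with a brute-force voxel loop on random volumes", {
  set.seed(17)
  for (rep in 1:8) {
    vol <- array(sample(0:50, 4 * 5 * 8, replace = TRUE), c(4, 5, 8))
    mask <- array(runif(length(vol)) < 0.5, dim(vol))
    if (!any(mask)) next
    voxel <- c(x = 0.4, y = 0.4, z = 1.1)
    o <- c(0.3, -0.2, 0.1); d <- random_unit_vector()
    ax <- migration_axis(o, o + 5 * d)
    st <- make_stack(list(list(vol)), voxel = voxel)
    seg <- fake_segmentation(list(mask), voxel = voxel)
    for (stat in c("sum", "max")) {
      k <- volumetric_kymograph(st, 0, seg, ax, stat)
      oracle <- brute_kymograph(vol, mask, voxel, o, d, k$bin_width_um, stat)
      got <- k$matrix[, 1]
      names(got) <- as.character(seq_len(nrow(k$matrix)) - 1 +
                                   round(k$bin0_offset_um / k$bin_width_um))
      expect_equal(got[names(oracle)], oracle[names(oracle)])
      # bins the oracle never saw must be empty
      expect_true(all(got[setdiff(names(got), names(oracle))] == 0))
    }
    # conservation: sum-statistic column total equals the masked total
    k <- volumetric_kymograph(st, 0, seg, ax, "sum")
    expect_identical(sum(k$matrix[, 1]), as.numeric(sum(vol[mask])))
    # max statistic never exceeds the frame's masked maximum
    k2 <- volumetric_kymograph(st, 0, seg, ax, "max")
    expect_lte(max(k2$matrix), max(vol[mask]))
  }
})

test_that("a forward-translating cell shifts the kymograph to higher bins", {
  cfg <- scene_config(n_frames = 6, n_z = 9, n_y = 40, n_x = 180,
                      voxel_z_um = 1, soma_radius_um = 3,
                      process_length_um = 12, nucleus_speed_um_s = 0.02,
                      lead_amplitude_um = 0, cycle_period_s = 480,
                      hotspot_amplitude = 0, start_x_um = 12)
  sc <- render_scene(cfg)
  seg <- segment_sequence(sc$stack, "actin", cfg$actin_baseline / 2,
                          truth_seed_voxel(sc, 1))
  ax <- scene_axis(sc)
  k <- volumetric_kymograph(sc$stack, "nucleus", seg, ax, "sum")
  com <- apply(k$matrix, 2, function(col) sum(col * k$s_um) / sum(col))
  expect_true(all(diff(com) >= -1e-9))
  expect_gt(com[length(com)], com[1])
})

test_that("soma overlay recovers an analytic sphere and the moving nucleus", {
  # solid sphere of radius 3 centered at s = 10 on a fine grid
  nz <- 17; ny <- 17; nx <- 33
  voxel <- c(x = 0.5, y = 0.5, z = 0.5)
  zc <- (nz - 1) / 2 * 0.5; yc <- (ny - 1) / 2 * 0.5
  vol <- array(0, c(nz, ny, nx))
  for (z in 1:nz) for (y in 1:ny) for (x in 1:nx) {
    p <- c((x - 1) * 0.5, (y - 1) * 0.5, (z - 1) * 0.5)
    if (sum((p - c(10, yc, zc))^2) <= 9) vol[z, y, x] <- 100
  }
  st <- make_stack(list(list(vol)), voxel = voxel)
  seg <- fake_segmentation(list(array(TRUE, dim(vol))), voxel = voxel)
  ax <- migration_axis(c(0, yc, zc), c(1, yc, zc))
  ov <- soma_overlay(st, 0, seg, ax, margin_um = 0, threshold = 50)
  expect_equal(ov$s_min_um, 7, tolerance = 0.26)
  expect_equal(ov$s_center_um, 10, tolerance = 0.26)
  expect_equal(ov$s_max_um, 13, tolerance = 0.26)

  # empty nucleus channel: every frame flagged
  dark <- make_stack(list(list(vol * 0)), voxel = voxel)
  ovd <- soma_overlay(dark, 0, seg, ax)
  expect_true(all(ovd$flagged))

  # synthetic scene: projected soma center follows the true nucleus
  sc <- test_scene(); segsc <- test_segmentation()
  axs <- scene_axis(sc)
  ovs <- soma_overlay(sc$stack, "nucleus", segsc, axs)
  s_true <- sc$truth$frames$nucleus_x_um - axs$origin_um[1]
  expect_true(all(abs(ovs$s_center_um - s_true) < 0.5))
})
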