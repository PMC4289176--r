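# Independent brute-force oracles and shared fixtures.

.fixtures <- new.env()

# A moderate rendered scene shared across tests (built once per run).
test_scene <- function() {
  if (is.null(.fixtures$scene)) {
    cfg <- scene_config(
      n_frames = 6, n_z = 9, n_y = 40, n_x = 140,
      voxel_xy_um = 0.25, voxel_z_um = 1, frame_interval_s = 120,
      soma_radius_um = 3, process_length_um = 14,
      process_halfwidth_base_um = 1.5, process_halfwidth_tip_um = 0.4,
      nucleus_speed_um_s = 0.01, lead_amplitude_um = 4,
      cycle_period_s = 480, hotspot_amplitude = 150,
      hotspot_sigma_um = 1.5, start_x_um = 10,
      adhesion_x_um = c(14, 17, 20), seed = 11)
    .fixtures$scene <- c(list(cfg = cfg), render_scene(cfg))
  }
  .fixtures$scene
}

# Same geometry, segmented on the actin channel (threshold half plateau).
test_segmentation <- function() {
  if (is.null(.fixtures$seg)) {
    sc <- test_scene()
    seed0 <- truth_seed_voxel(sc, 1)
    .fixtures$seg <- segment_sequence(sc$stack, "actin",
                                      sc$cfg$actin_baseline / 2, seed0)
  }
  .fixtures$seg
}

# 0-based (x, y, z) voxel index of the true nucleus position at a frame.
truth_seed_voxel <- function(sc, frame_1based) {
  fr <- sc$truth$frames[frame_1based, ]
  vs <- sc$stack$voxel_size_um
  round(c(fr$nucleus_x_um / vs[["x"]], fr$nucleus_y_um / vs[["y"]],
          fr$nucleus_z_um / vs[["z"]]))
}

scene_axis <- function(sc) {
  migration_axis(sc$truth$axis_origin_um,
                 sc$truth$axis_origin_um + 10 * sc$truth$axis_direction)
}

# Soma intervals straight from ground truth, shaped for compartment_fractions.
truth_soma_intervals <- function(sc, axis) {
  fr <- sc$truth$frames
  s0 <- axis$origin_um[1]
  data.frame(frame = fr$frame,
             s_min_um = fr$soma_s_min_um - s0,
             s_max_um = fr$soma_s_max_um - s0)
}

# Brute-force volumetric kymograph by explicit voxel loop.
brute_kymograph <- function(vol, mask, voxel_size_um, origin, direction,
                            delta, statistic) {
  d <- dim(vol)
  bins <- list()
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (!mask[z, y, x]) next
    p <- c((x - 1) * voxel_size_um[["x"]], (y - 1) * voxel_size_um[["y"]],
           (z - 1) * voxel_size_um[["z"]])
    s <- sum((p - origin) * direction)
    b <- as.character(floor(s / delta))
    bins[[b]] <- c(bins[[b]], vol[z, y, x])
  }
  f <- if (statistic == "sum") sum else max
  vapply(bins, f, numeric(1))
}

# Brute-force 6-connected flood fill with explicit neighbor loops.
brute_flood <- function(above, seed_zyx) {
  d <- dim(above)
  vis <- array(FALSE, d)
  if (!above[seed_zyx[1], seed_zyx[2], seed_zyx[3]]) return(vis)
  queue <- list(seed_zyx)
  vis[seed_zyx[1], seed_zyx[2], seed_zyx[3]] <- TRUE
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    cur <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (i in 1:6) {
      p <- cur + nb[i, ]
      if (any(p < 1) || any(p > d)) next
      if (vis[p[1], p[2], p[3]] || !above[p[1], p[2], p[3]]) next
      vis[p[1], p[2], p[3]] <- TRUE
      queue[[length(queue) + 1L]] <- p
    }
  }
  vis
}

# Closed-form Welch statistic for cross-checking.
brute_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Quick stack constructor for hand-built volumes.
make_stack <- function(vols, voxel = c(x = 1, y = 1, z = 1), dt = 1,
                       channels = NULL) {
  # vols: list over frames of list over channels of (z,y,x) arrays
  nt <- length(vols); nc <- length(vols[[1]])
  d3 <- dim(vols[[1]][[1]])
  data <- array(0, c(nt, nc, d3))
  for (t in seq_len(nt)) for (ch in seq_len(nc))
    data[t, ch, , , ] <- vols[[t]][[ch]]
  image_stack(data, voxel, dt, channels)
}

fake_segmentation <- function(masks, voxel = c(x = 1, y = 1, z = 1),
                              threshold = 0) {
  structure(list(masks = masks, threshold = threshold, walls = list(),
                 qc = data.frame(frame = seq_along(masks) - 1L,
                                 mask_voxels = vapply(masks, sum, integer(1)),
                                 flagged = FALSE),
                 voxel_size_um = voxel),
            class = "segmentation")
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}
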