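#' Render a synthetic 4D migrating-neuron scene
#'
#' Builds a multi-channel voxel stack from a [scene_config()] together with
#' the ground truth every downstream module can be checked against. Channels:
#' \describe{
#'   \item{0 `nucleus`}{Gaussian nuclear blob riding with the soma.}
#'   \item{1 `organelle`}{diffraction-limited punctum performing two-stroke
#'     motion ahead of the nucleus.}
#'   \item{2 `actin`}{cytoplasmic marker filling the cell (soma + tapered
#'     leading process, PSF-blurred), plus a Gaussian hotspot riding on the
#'     organelle.}
#'   \item{3 `adhesion`}{puncta at fixed lab-frame positions that the soma
#'     slides past.}
#' }
#' The cell body is voxelized once at frame 0 and translated to later frames
#' by linear-interpolation sub-voxel shifts, so with noise off the total
#' intensity of each component is constant across frames. Noise (optional
#' Poisson on the signal, then additive Gaussian, clipped at zero) is applied
#' after geometry under the config seed; identical configs give
#' byte-identical stacks, and configs differing only in seed share identical
#' ground truth.
#'
#' @param config a [scene_config()].
#' @return A list with elements `stack` (an [image_stack()]) and `truth`
#'   (class `scene_truth`): per-frame true nucleus/organelle positions,
#'   the soma interval along the axis, true adhesion compartment fractions,
#'   per-phase speeds, and the migration axis used.
#' @export
render_scene <- function(config) {
  if (!inherits(config, "scene_config"))
    stop_config("'config' must be a scene_config object")
  cfg <- config
  traj <- two_stroke_trajectory(cfg)

  dx <- cfg$voxel_xy_um; dz <- cfg$voxel_z_um
  xs <- (seq_len(cfg$n_x) - 1) * dx
  ys <- (seq_len(cfg$n_y) - 1) * dx
  zs <- (seq_len(cfg$n_z) - 1) * dz
  yc <- ys[length(ys)] / 2
  zc <- zs[length(zs)] / 2
  psf <- c(cfg$psf_sigma_xy_um, cfg$psf_sigma_xy_um, cfg$psf_sigma_z_um)

  # geometry bounds check, naming the first offending frame
  margin <- 4 * cfg$psf_sigma_xy_um
  x_lo <- traj$nucleus_um -
    max(cfg$soma_radius_um, cfg$trailing_length_um) - margin
  x_hi <- pmax(traj$nucleus_um + cfg$process_length_um,
               traj$organelle_um) + margin
  bad <- which(x_lo < 0 | x_hi > xs[length(xs)])
  if (length(bad))
    stop_geometry(
      "cell exceeds the grid along x at frame %d (needs [%.2f, %.2f] um, grid [0, %.2f])",
      bad[1] - 1L, x_lo[bad[1]], x_hi[bad[1]], xs[length(xs)])
  if (cfg$soma_radius_um + margin > yc ||
      cfg$soma_radius_um > zc + dz)  # z clipping of the blur tail is tolerated
    stop_geometry("soma does not fit the grid in y/z (radius %.2f um)",
                  cfg$soma_radius_um)

  # frame-0 cell body: soma sphere + tapered process, PSF-blurred once
  x0 <- traj$nucleus_um[1]
  co <- expand_coords(zs, ys, xs)
  r2_yz <- (co$y - yc)^2 + (co$z - zc)^2
  soma <- (co$x - x0)^2 + r2_yz <= cfg$soma_radius_um^2
  u <- (co$x - x0) / cfg$process_length_um
  w <- cfg$process_halfwidth_base_um +
    (cfg$process_halfwidth_tip_um - cfg$process_halfwidth_base_um) * u
  proc <- u >= 0 & u <= 1 & r2_yz <= w^2
  trail <- cfg$trailing_length_um > 0 &
    (x0 - co$x) > 0 & (x0 - co$x) <= cfg$trailing_length_um &
    r2_yz <= cfg$trailing_halfwidth_um^2
  body0 <- array(as.numeric(soma | proc | trail),
                 c(cfg$n_z, cfg$n_y, cfg$n_x))
  body0 <- cfg$actin_baseline *
    gauss_blur3d(body0, psf / c(dz, dx, dx))

  nt <- cfg$n_frames
  data <- array(0, c(nt, 4L, cfg$n_z, cfg$n_y, cfg$n_x))

  adhesion <- Reduce(`+`, lapply(seq_along(cfg$adhesion_x_um), function(i)
    gauss_blob(xs, ys, zs, c(cfg$adhesion_x_um[i], yc, zc), psf,
               cfg$adhesion_amplitudes[i])), array(0, c(cfg$n_z, cfg$n_y, cfg$n_x)))

  nuc_sigma <- rep(cfg$soma_radius_um * 0.5, 3)
  for (t in seq_len(nt)) {
    nx <- traj$nucleus_um[t]; ox <- traj$organelle_um[t]
    data[t, 1, , , ] <- gauss_blob(xs, ys, zs, c(nx, yc, zc), nuc_sigma,
                                   cfg$nucleus_amplitude)
    data[t, 2, , , ] <- gauss_blob(xs, ys, zs, c(ox, yc, zc), psf,
                                   cfg$organelle_amplitude)
    data[t, 3, , , ] <- shift_x(body0, (nx - x0) / dx) +
      gauss_blob(xs, ys, zs, c(ox, yc, zc), rep(cfg$hotspot_sigma_um, 3),
                 cfg$hotspot_amplitude)
    data[t, 4, , , ] <- adhesion
  }

  if (cfg$poisson_noise || cfg$gaussian_noise_sd > 0) {
    data <- with_seed(cfg$seed, {
      v <- as.vector(data)
      if (cfg$poisson_noise) v <- rpois(length(v), pmax(v, 0))
      if (cfg$gaussian_noise_sd > 0)
        v <- v + rnorm(length(v), sd = cfg$gaussian_noise_sd)
      array(pmax(v, 0), dim(data))
    })
  }

  stack <- image_stack(data,
                       voxel_size_um = c(x = dx, y = dx, z = dz),
                       frame_interval_s = cfg$frame_interval_s,
                       channels = c("nucleus", "organelle", "actin", "adhesion"))

  truth <- scene_truth(cfg, traj, yc, zc)
  list(stack = stack, truth = truth)
}

expand_coords <- function(zs, ys, xs) {
  nz <- length(zs); ny <- length(ys); nx <- length(xs)
  list(z = array(rep(zs, ny * nx), c(nz, ny, nx)),
       y = array(rep(rep(ys, each = nz), nx), c(nz, ny, nx)),
       x = array(rep(xs, each = nz * ny), c(nz, ny, nx)))
}

# Ground truth bundled with a rendered scene.
scene_truth <- function(cfg, traj, yc, zc) {
  s_min <- traj$nucleus_um - cfg$soma_radius_um
  s_max <- traj$nucleus_um + cfg$soma_radius_um
  amp <- cfg$adhesion_amplitudes
  fr <- t(vapply(seq_len(nrow(traj)), function(t) {
    lead <- sum(amp[cfg$adhesion_x_um > s_max[t]])
    trail <- sum(amp[cfg$adhesion_x_um < s_min[t]])
    soma <- sum(amp) - lead - trail
    c(lead, soma, trail) / sum(amp)
  }, numeric(3)))
  structure(list(
    frames = data.frame(
      frame = traj$frame, time_s = traj$time_s,
      nucleus_x_um = traj$nucleus_um, nucleus_y_um = yc, nucleus_z_um = zc,
      organelle_x_um = traj$organelle_um, organelle_y_um = yc,
      organelle_z_um = zc,
      soma_s_min_um = s_min, soma_s_max_um = s_max,
      f_leading = fr[, 1], f_soma = fr[, 2], f_trailing = fr[, 3]),
    axis_origin_um = c(traj$nucleus_um[1], yc, zc),
    axis_direction = c(1, 0, 0),
    speed_pre_um_s = cfg$nucleus_speed_um_s,
    speed_post_um_s = cfg$nucleus_speed_um_s * cfg$post_drug_factor,
    adhesion_x_um = cfg$adhesion_x_um,
    adhesion_amplitudes = amp,
    config = cfg
  ), class = "scene_truth")
}

#' Extract ground-truth tracks from a rendered scene
#'
#' Converts the true nucleus and organelle positions of a [render_scene()]
#' ground truth into [track()] objects, optionally adding Gaussian in-plane
#' localization noise (emulating tracking error).
#'
#' @param truth a `scene_truth` object.
#' @param noise_sd_um per-coordinate (x, y) localization noise sigma.
#' @param seed optional RNG seed.
#' @return Named list with `nucleus` and `organelle` tracks.
#' @export
truth_tracks <- function(truth, noise_sd_um = 0, seed = NULL) {
  fr <- truth$frames
  mk <- function(prefix, id, channel) {
    pos <- cbind(fr[[paste0(prefix, "_x_um")]],
                 fr[[paste0(prefix, "_y_um")]],
                 fr[[paste0(prefix, "_z_um")]])
    track(id, fr$frame, pos, channel = channel)
  }
  out <- list(nucleus = mk("nucleus", "nucleus", "nucleus"),
              organelle = mk("organelle", "organelle", "organelle"))
  if (noise_sd_um > 0) {
    out <- with_seed(seed, lapply(out, function(tr) {
      tr$pos[, 1:2] <- tr$pos[, 1:2] +
        matrix(rnorm(2 * nrow(tr$pos), sd = noise_sd_um), ncol = 2)
      tr
    }))
  }
  out
}
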