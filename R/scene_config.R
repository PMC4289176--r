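#' Configuration for a synthetic migrating-neuron scene
#'
#' Parameterizes the ground-truthed synthetic 4D scenes used to validate the
#' analysis pipeline. The rendered cell is a soma (sphere) plus a tapered
#' leading process extending along +x, filled with a cytoplasmic/actin marker.
#' Four channels are rendered: (0) nucleus, (1) a punctate organelle
#' performing two-stroke motion ahead of the nucleus, (2) actin with a
#' hotspot riding on the organelle, and (3) adhesion puncta fixed in the lab
#' frame that the soma slides past. Defaults mirror a spinning-disk
#' acquisition of cerebellar granule neurons: 13 z-sections spanning 10 um,
#' 0.25 um x-y pixels, 2-minute frames over 24 minutes.
#'
#' @param n_frames,n_z,n_y,n_x grid extents (time, z, y, x).
#' @param voxel_xy_um,voxel_z_um voxel size in micrometres. The 13-section /
#'   10-um default gives `voxel_z_um = 10/12`.
#' @param frame_interval_s time between frames, seconds.
#' @param soma_radius_um soma radius. Granule neuron somata are ~7 um across.
#' @param process_length_um length of the leading process beyond the soma
#'   center.
#' @param process_halfwidth_base_um,process_halfwidth_tip_um half-widths of
#'   the tapered leading process at its base and tip.
#' @param trailing_length_um length of the trailing process extending
#'   behind the soma center (0 for none); migrating neurons retain one, and
#'   it is what keeps passed adhesion sites inside the segmented cell.
#' @param trailing_halfwidth_um half-width of the trailing process.
#' @param nucleus_speed_um_s time-averaged nucleus (soma) speed along the
#'   migration axis.
#' @param lead_amplitude_um peak organelle lead over the nucleus within one
#'   two-stroke cycle. `0` selects the constant-speed degenerate mode in
#'   which nucleus and organelle advance together at constant speed.
#' @param cycle_period_s duration of one two-stroke cycle. Must be at least
#'   twice the frame interval.
#' @param drug_time_s optional time of drug addition; `NULL` for none.
#' @param post_drug_factor factor in `[0, 1]` applied to all step sizes after
#'   `drug_time_s`.
#' @param actin_baseline plateau intensity of the cytoplasmic actin channel
#'   inside the cell.
#' @param hotspot_amplitude,hotspot_sigma_um amplitude and width of the
#'   proximal-leading-process actin hotspot centered on the organelle.
#' @param nucleus_amplitude,organelle_amplitude peak intensities of the
#'   nucleus blob and the organelle punctum.
#' @param adhesion_x_um lab-frame x positions (um) of adhesion puncta, or
#'   `NULL` for the default three puncta spread over the migration path.
#' @param adhesion_amplitudes punctum amplitudes, recycled to match
#'   `adhesion_x_um`.
#' @param psf_sigma_xy_um,psf_sigma_z_um Gaussian point-spread sigmas.
#' @param gaussian_noise_sd additive Gaussian read-noise sigma (0 = off).
#' @param poisson_noise logical; apply Poisson noise to the signal first.
#' @param start_x_um soma center x at frame 0, or `NULL` to auto-place with a
#'   rendering margin.
#' @param seed integer RNG seed; a fixed seed makes rendering byte-identical.
#'
#' @return An object of class `scene_config` (a validated named list).
#' @seealso [render_scene()], [two_stroke_trajectory()]
#' @export
scene_config <- function(n_frames = 13, n_z = 13, n_y = 48, n_x = 200,
                         voxel_xy_um = 0.25, voxel_z_um = 10 / 12,
                         frame_interval_s = 120,
                         soma_radius_um = 3.5,
                         process_length_um = 20,
                         process_halfwidth_base_um = 1.5,
                         process_halfwidth_tip_um = 0.4,
                         trailing_length_um = 8,
                         trailing_halfwidth_um = 1.2,
                         nucleus_speed_um_s = 0.009,
                         lead_amplitude_um = 5,
                         cycle_period_s = 1200,
                         drug_time_s = NULL,
                         post_drug_factor = 1,
                         actin_baseline = 100,
                         hotspot_amplitude = 150,
                         hotspot_sigma_um = 2,
                         nucleus_amplitude = 200,
                         organelle_amplitude = 400,
                         adhesion_x_um = NULL,
                         adhesion_amplitudes = 300,
                         psf_sigma_xy_um = 0.3,
                         psf_sigma_z_um = 0.8,
                         gaussian_noise_sd = 0,
                         poisson_noise = FALSE,
                         start_x_um = NULL,
                         seed = 1L) {
  cfg <- list(
    n_frames = as.integer(n_frames), n_z = as.integer(n_z),
    n_y = as.integer(n_y), n_x = as.integer(n_x),
    voxel_xy_um = voxel_xy_um, voxel_z_um = voxel_z_um,
    frame_interval_s = frame_interval_s,
    soma_radius_um = soma_radius_um,
    process_length_um = process_length_um,
    process_halfwidth_base_um = process_halfwidth_base_um,
    process_halfwidth_tip_um = process_halfwidth_tip_um,
    trailing_length_um = trailing_length_um,
    trailing_halfwidth_um = trailing_halfwidth_um,
    nucleus_speed_um_s = nucleus_speed_um_s,
    lead_amplitude_um = lead_amplitude_um,
    cycle_period_s = cycle_period_s,
    drug_time_s = drug_time_s,
    post_drug_factor = post_drug_factor,
    actin_baseline = actin_baseline,
    hotspot_amplitude = hotspot_amplitude,
    hotspot_sigma_um = hotspot_sigma_um,
    nucleus_amplitude = nucleus_amplitude,
    organelle_amplitude = organelle_amplitude,
    adhesion_x_um = adhesion_x_um,
    adhesion_amplitudes = adhesion_amplitudes,
    psf_sigma_xy_um = psf_sigma_xy_um,
    psf_sigma_z_um = psf_sigma_z_um,
    gaussian_noise_sd = gaussian_noise_sd,
    poisson_noise = isTRUE(poisson_noise),
    start_x_um = start_x_um,
    seed = as.integer(seed)
  )
  validate_scene_config(cfg)
}

validate_scene_config <- function(cfg) {
  for (f in c("n_frames", "n_z", "n_y", "n_x"))
    if (cfg[[f]] < 1L) stop_config("grid extent '%s' must be >= 1", f)
  for (f in c("voxel_xy_um", "voxel_z_um", "frame_interval_s",
              "soma_radius_um", "process_length_um",
              "process_halfwidth_base_um", "process_halfwidth_tip_um",
              "cycle_period_s", "hotspot_sigma_um", "trailing_halfwidth_um",
              "psf_sigma_xy_um", "psf_sigma_z_um"))
    check_scalar(cfg[[f]], f, positive = TRUE)
  check_scalar(cfg$trailing_length_um, "trailing_length_um", nonneg = TRUE)
  for (f in c("nucleus_speed_um_s", "lead_amplitude_um", "actin_baseline",
              "hotspot_amplitude", "nucleus_amplitude", "organelle_amplitude",
              "gaussian_noise_sd"))
    check_scalar(cfg[[f]], f, nonneg = TRUE)
  check_scalar(cfg$post_drug_factor, "post_drug_factor", nonneg = TRUE)
  if (cfg$post_drug_factor > 1)
    stop_config("'post_drug_factor' must be in [0, 1] (got %g)",
                cfg$post_drug_factor)
  if (!is.null(cfg$drug_time_s))
    check_scalar(cfg$drug_time_s, "drug_time_s", positive = TRUE)
  if (cfg$cycle_period_s < 2 * cfg$frame_interval_s)
    stop_config("cycle_period_s (%g) must be >= 2 * frame_interval_s (%g)",
                cfg$cycle_period_s, 2 * cfg$frame_interval_s)
  if (is.null(cfg$adhesion_x_um)) {
    x0 <- scene_start_x(cfg)
    travel <- cfg$nucleus_speed_um_s * cfg$cycle_period_s *
      ceiling((cfg$n_frames - 1) * cfg$frame_interval_s / cfg$cycle_period_s)
    cfg$adhesion_x_um <- x0 + cfg$soma_radius_um +
      seq(0.25, 0.75, length.out = 3) *
        max(cfg$process_length_um, travel + cfg$soma_radius_um)
  }
  cfg$adhesion_amplitudes <- rep_len(cfg$adhesion_amplitudes,
                                     length(cfg$adhesion_x_um))
  structure(cfg, class = "scene_config")
}

# Default soma start x: leave room for the soma, the trailing process and
# the blur tail.
scene_start_x <- function(cfg) {
  cfg$start_x_um %||% (max(cfg$soma_radius_um, cfg$trailing_length_um) +
                         4 * cfg$psf_sigma_xy_um + 2 * cfg$voxel_xy_um)
}

#' @export
print.scene_config <- function(x, ...) {
  cat("Synthetic scene configuration\n")
  cat(sprintf("  grid: %d frames x %d z x %d y x %d x (voxel %.3g x %.3g x %.3g um)\n",
              x$n_frames, x$n_z, x$n_y, x$n_x,
              x$voxel_xy_um, x$voxel_xy_um, x$voxel_z_um))
  cat(sprintf("  frame interval: %g s; nucleus speed: %g um/s; cycle: %g s\n",
              x$frame_interval_s, x$nucleus_speed_um_s, x$cycle_period_s))
  if (!is.null(x$drug_time_s))
    cat(sprintf("  drug at %g s, post-drug speed factor %g\n",
                x$drug_time_s, x$post_drug_factor))
  cat(sprintf("  noise: gaussian sd %g, poisson %s; seed %d\n",
              x$gaussian_noise_sd, x$poisson_noise, x$seed))
  invisible(x)
}
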