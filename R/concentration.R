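#' Mean local marker intensity around a point
#'
#' The region is the intersection of the segmented cell with a cylinder of
#' the given radius: masked voxels whose center lies within `radius_um` of
#' the point in the x-y plane, at every z (the cylinder axis is taken
#' parallel to z, so the neighborhood is a disk extruded through the
#' anisotropically sampled axial dimension). Distances are physical
#' (micrometres), voxel-center to point.
#'
#' @param stack an [image_stack()].
#' @param channel channel label or 0-based index of the marker (e.g.
#'   actin).
#' @param mask logical `(z, y, x)` cell mask for the frame.
#' @param point_um object position `c(x, y, z)` in micrometres (z is
#'   ignored by the region definition but kept for interface symmetry).
#' @param radius_um cylinder radius, `> 0`.
#' @param frame 0-based frame index.
#' @return List with `mean` (NA when the region is empty), `n_voxels` and
#'   `flagged` (TRUE for an empty region; never a silent zero).
#' @export
local_mean <- function(stack, channel, mask, point_um, radius_um,
                       frame = 0) {
  check_scalar(radius_um, "radius_um", positive = TRUE)
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx))
    return(list(mean = NA_real_, n_voxels = 0L, flagged = TRUE))
  pts <- ind_to_um(arrayInd(idx, d), stack$voxel_size_um)
  inplane <- sqrt((pts[, 1] - point_um[1])^2 + (pts[, 2] - point_um[2])^2)
  sel <- inplane <= radius_um
  if (!any(sel))
    return(list(mean = NA_real_, n_voxels = 0L, flagged = TRUE))
  vol <- stack_volume(stack, frame, channel)
  list(mean = mean(vol[idx[sel]]), n_voxels = sum(sel), flagged = FALSE)
}

#' Local concentration profile along a track
#'
#' For every present frame of the track, computes the mean marker intensity
#' within cylinders of the given radii around the tracked position, plus the
#' whole-cell baseline (mean over the full 3D mask) for comparison.
#'
#' @param stack an [image_stack()].
#' @param channel marker channel label or 0-based index.
#' @param seg a `segmentation` aligned with the stack.
#' @param track a [track()]; frames must exist in the stack.
#' @param radii_um strictly increasing radii (default `c(1, 2, 4)` um, the
#'   scales used to probe actin around the Golgi/cilium).
#' @return A data frame of class `concentration_profile` with columns
#'   `frame`, `time_s`, `radius_um` (the string `"baseline"` for the
#'   whole-cell mean), `mean_intensity`, `voxel_count`, `flagged`.
#' @export
concentration_profile <- function(stack, channel, seg, track,
                                  radii_um = c(1, 2, 4)) {
  if (length(radii_um) < 1L || any(diff(radii_um) <= 0) ||
      any(radii_um <= 0))
    stop_config("'radii_um' must be strictly increasing and positive")
  d <- dim(stack$data)
  if (any(track$frames < 0 | track$frames > d[1] - 1L))
    stop_dimension("track frames outside the stack")
  rows <- list()
  for (i in seq_along(track$frames)) {
    fr <- track$frames[i]
    mask <- seg$masks[[fr + 1L]]
    vol <- stack_volume(stack, fr, channel)
    base_n <- sum(mask)
    base <- if (base_n) mean(vol[mask]) else NA_real_
    tt <- fr * stack$frame_interval_s
    for (r in radii_um) {
      lm <- local_mean(stack, channel, mask, track$pos[i, ], r, frame = fr)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fr, time_s = tt, radius_um = as.character(r),
        mean_intensity = lm$mean, voxel_count = lm$n_voxels,
        flagged = lm$flagged, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      frame = fr, time_s = tt, radius_um = "baseline",
      mean_intensity = base, voxel_count = base_n,
      flagged = base_n == 0L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("concentration_profile", "data.frame")
  out
}
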