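#' Multi-channel 3D time-lapse image stack
#'
#' Container for voxel intensities indexed `(t, c, z, y, x)` with physical
#' calibration. Conventions used throughout the package: voxel indices are
#' 0-based in all on-disk formats and user-facing coordinates, the physical
#' coordinate of a voxel is `index * voxel size` (voxel-center convention),
#' and ranges are half-open.
#'
#' @param data 5-dimensional numeric array, dimensions `(t, c, z, y, x)`,
#'   non-negative intensities.
#' @param voxel_size_um named numeric vector `c(x=, y=, z=)`, micrometres.
#' @param frame_interval_s time between frames, seconds.
#' @param channels optional character vector of channel labels.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size_um, frame_interval_s,
                        channels = NULL) {
  if (!is.array(data) || length(dim(data)) != 5L)
    stop_dimension("'data' must be a 5-D array (t, c, z, y, x); got %s dims",
                   length(dim(data)))
  if (any(dim(data) < 1L)) stop_dimension("all five extents must be >= 1")
  vs <- voxel_size_um
  if (length(vs) != 3L) stop_metadata("'voxel_size_um' must have 3 entries")
  if (is.null(names(vs))) names(vs) <- c("x", "y", "z")
  vs <- vs[c("x", "y", "z")]
  if (any(!is.finite(vs)) || any(vs <= 0))
    stop_metadata("voxel sizes must be positive (got %s)",
                  paste(signif(vs, 4), collapse = ", "))
  check_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  if (is.null(channels))
    channels <- paste0("ch", seq_len(dim(data)[2]) - 1L)
  if (length(channels) != dim(data)[2])
    stop_metadata("%d channel labels for %d channels",
                  length(channels), dim(data)[2])
  if (min(data) < 0)
    stop_data("intensities must be non-negative (min = %g)", min(data))
  structure(list(data = data, voxel_size_um = vs,
                 frame_interval_s = frame_interval_s,
                 channels = as.character(channels)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d frames x %d channels x %d z x %d y x %d x\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  voxel %.4g x %.4g x %.4g um; frame interval %g s\n",
              x$voxel_size_um["x"], x$voxel_size_um["y"],
              x$voxel_size_um["z"], x$frame_interval_s))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

# One (z, y, x) volume.
stack_volume <- function(stack, frame, channel) {
  ch <- resolve_channel(stack, channel)
  d <- dim(stack$data)
  if (frame < 0 || frame >= d[1])
    stop_dimension("frame %d outside [0, %d]", frame, d[1] - 1L)
  array(stack$data[frame + 1L, ch, , , ], d[3:5])
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    ch <- match(channel, stack$channels)
    if (is.na(ch)) stop_metadata("unknown channel '%s' (have: %s)", channel,
                                 paste(stack$channels, collapse = ", "))
    ch
  } else {
    ch <- as.integer(channel) + 1L  # 0-based for callers
    if (ch < 1L || ch > dim(stack$data)[2])
      stop_dimension("channel index %d outside [0, %d]",
                     channel, dim(stack$data)[2] - 1L)
    ch
  }
}

# Voxel-center physical coordinates (um) for a (z, y, x) volume.
volume_coords <- function(dim_zyx, voxel_size_um) {
  list(x = (seq_len(dim_zyx[3]) - 1) * voxel_size_um[["x"]],
       y = (seq_len(dim_zyx[2]) - 1) * voxel_size_um[["y"]],
       z = (seq_len(dim_zyx[1]) - 1) * voxel_size_um[["z"]])
}

# Physical (x, y, z) um coordinates of voxels given by arrayInd rows (z,y,x).
ind_to_um <- function(ind, voxel_size_um) {
  cbind(x = (ind[, 3] - 1) * voxel_size_um[["x"]],
        y = (ind[, 2] - 1) * voxel_size_um[["y"]],
        z = (ind[, 1] - 1) * voxel_size_um[["z"]])
}
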