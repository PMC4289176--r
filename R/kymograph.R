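#' Migration axis of a cell
#'
#' The migration axis is fixed from the first frame: it points from the
#' soma centroid toward the tip of the leading process and approximates the
#' direction of migration. The origin stays anchored at the frame-0
#' centroid for the whole sequence. When `tip_um` is omitted, the tip is
#' auto-selected as the frame-0 mask voxel farthest from the centroid.
#'
#' @param origin_um soma centroid at frame 0, `c(x, y, z)` micrometres.
#' @param tip_um leading-process tip, `c(x, y, z)` micrometres; optional if
#'   `mask` is given.
#' @param mask optional logical `(z, y, x)` frame-0 mask for tip
#'   auto-selection.
#' @param voxel_size_um named voxel sizes, required with `mask`.
#' @return An object of class `migration_axis` with unit `direction` and
#'   `origin_um`.
#' @export
migration_axis <- function(origin_um, tip_um = NULL, mask = NULL,
                           voxel_size_um = NULL) {
  origin_um <- as.numeric(origin_um)
  if (length(origin_um) != 3L) stop_geometry("'origin_um' must be length 3")
  if (is.null(tip_um)) {
    if (is.null(mask) || is.null(voxel_size_um))
      stop_geometry("supply 'tip_um' or both 'mask' and 'voxel_size_um'")
    idx <- which(mask)
    if (!length(idx)) stop_geometry("empty mask; cannot auto-select a tip")
    pts <- ind_to_um(arrayInd(idx, dim(mask)), voxel_size_um)
    d2 <- rowSums(sweep(pts, 2, origin_um)^2)
    tip_um <- pts[which.max(d2), ]
  }
  tip_um <- as.numeric(tip_um)
  v <- tip_um - origin_um
  nv <- sqrt(sum(v^2))
  if (nv == 0)
    stop_geometry("tip coincides with the soma centroid; axis undefined")
  structure(list(origin_um = origin_um, direction = v / nv,
                 tip_um = tip_um), class = "migration_axis")
}

#' @export
print.migration_axis <- function(x, ...) {
  cat(sprintf("migration_axis: origin (%s) um, direction (%s)\n",
              paste(signif(x$origin_um, 4), collapse = ", "),
              paste(signif(x$direction, 4), collapse = ", ")))
  invisible(x)
}

# Projected coordinate s (um) of physical points onto the axis.
project_onto_axis <- function(points_um, axis) {
  pts <- matrix(as.numeric(points_um), ncol = 3)
  as.vector(sweep(pts, 2, axis$origin_um) %*% axis$direction)
}

#' Project a track onto the migration axis
#'
#' @param track a [track()].
#' @param axis a [migration_axis()].
#' @return Data frame `frame`, `s_um` (projected coordinate per present
#'   frame; absent frames yield no row).
#' @export
project_track <- function(track, axis) {
  data.frame(frame = track$frames,
             s_um = project_onto_axis(track$pos, axis))
}

#' Adaptive volumetric kymograph
#'
#' Accumulates the masked fluorescence of a channel in cross-sections one
#' x-y pixel apart along the migration axis. Each masked voxel is assigned
#' to the half-open bin `floor(s / delta)` of its projected coordinate
#' `s = (center - origin) . direction`, with `delta` the x-y voxel size;
#' the column for frame t holds the `sum` or `max` of the intensities in
#' each bin. Bins span the full projected extent of the mask over the whole
#' sequence (negative `s` is kept via the bin-0 offset); empty bins are 0,
#' with an emptiness flag for the max statistic. With the sum statistic
#' each column total equals the total masked fluorescence of its frame.
#'
#' @param stack an [image_stack()].
#' @param channel channel label or 0-based index.
#' @param seg a `segmentation` (from [segment_sequence()]), aligned with
#'   `stack`.
#' @param axis a [migration_axis()].
#' @param statistic `"sum"` or `"max"`.
#' @return An object of class `vol_kymograph`: `matrix` (bins x frames),
#'   `s_um` (bin-center coordinates), `bin_width_um`, `bin0_offset_um`,
#'   `statistic`, `empty` (logical matrix), `time_s`.
#' @export
volumetric_kymograph <- function(stack, channel, seg, axis,
                                 statistic = c("sum", "max")) {
  statistic <- match.arg(statistic)
  d <- dim(stack$data)
  if (length(seg$masks) != d[1] ||
      !identical(dim(seg$masks[[1]]), d[3:5]))
    stop_dimension("segmentation does not align with the stack")
  delta <- stack$voxel_size_um[["x"]]
  if (abs(stack$voxel_size_um[["x"]] - stack$voxel_size_um[["y"]]) >
      1e-9 * delta)
    warning("anisotropic x-y voxels; using the x size as bin width")

  per_frame <- lapply(seq_len(d[1]), function(t) {
    idx <- which(seg$masks[[t]])
    if (!length(idx))
      return(list(bin = integer(0), val = numeric(0)))
    pts <- ind_to_um(arrayInd(idx, d[3:5]), stack$voxel_size_um)
    s <- project_onto_axis(pts, axis)
    vol <- stack_volume(stack, t - 1L, channel)
    list(bin = as.integer(floor(s / delta)), val = vol[idx])
  })
  all_bins <- unlist(lapply(per_frame, `[[`, "bin"))
  if (!length(all_bins))
    stop_data("all masks are empty; nothing to accumulate")
  b0 <- min(all_bins); b1 <- max(all_bins)
  nb <- b1 - b0 + 1L
  K <- matrix(0, nb, d[1])
  empty <- matrix(TRUE, nb, d[1])
  for (t in seq_len(d[1])) {
    pf <- per_frame[[t]]
    if (!length(pf$bin)) next
    i <- pf$bin - b0 + 1L
    if (statistic == "sum") {
      acc <- rowsum(pf$val, i)
      K[as.integer(rownames(acc)), t] <- acc[, 1]
    } else {
      acc <- tapply(pf$val, i, max)
      K[as.integer(names(acc)), t] <- as.vector(acc)
    }
    empty[unique(i), t] <- FALSE
  }
  structure(list(matrix = K,
                 s_um = (seq.int(b0, b1) + 0.5) * delta,
                 bin_width_um = delta,
                 bin0_offset_um = b0 * delta,
                 statistic = statistic,
                 empty = empty,
                 time_s = (seq_len(d[1]) - 1) * stack$frame_interval_s,
                 channel = channel),
            class = "vol_kymograph")
}

#' @export
print.vol_kymograph <- function(x, ...) {
  cat(sprintf("volumetric kymograph (%s): %d bins x %d frames, bin %g um\n",
              x$statistic, nrow(x$matrix), ncol(x$matrix), x$bin_width_um))
  invisible(x)
}

#' Write a kymograph as CSV
#'
#' Rows are distance bins with the physical bin-center coordinate in the
#' first column; columns are frames.
#'
#' @param kymo a `vol_kymograph`.
#' @param path CSV path.
#' @export
write_kymograph <- function(kymo, path) {
  df <- data.frame(s_um = kymo$s_um, kymo$matrix)
  names(df)[-1] <- sprintf("t%03d", seq_len(ncol(kymo$matrix)) - 1L)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Soma overlay along the migration axis
#'
#' Locates the soma in every frame from the nucleus channel: the largest
#' 6-connected component of above-threshold nucleus signal inside the cell
#' mask, projected onto the axis. Reports the projected extremes (dilated
#' by a margin) and the intensity-weighted projected center. Frames without
#' nucleus signal in the mask are flagged with undefined overlay values.
#'
#' @param stack an [image_stack()].
#' @param nucleus_channel channel label or 0-based index of the nuclear
#'   marker.
#' @param seg a `segmentation`.
#' @param axis a [migration_axis()].
#' @param margin_um dilation margin applied to the extremes (default 1 um).
#' @param threshold nucleus threshold; default half of the frame's maximum
#'   nucleus intensity inside the mask.
#' @return Data frame `frame`, `s_min_um`, `s_center_um`, `s_max_um`,
#'   `flagged`.
#' @export
soma_overlay <- function(stack, nucleus_channel, seg, axis, margin_um = 1,
                         threshold = NULL) {
  d <- dim(stack$data)
  rows <- lapply(seq_len(d[1]), function(t) {
    vol <- stack_volume(stack, t - 1L, nucleus_channel)
    mask <- seg$masks[[t]]
    vals <- vol[mask]
    if (!length(vals) || max(vals) <= 0)
      return(data.frame(frame = t - 1L, s_min_um = NA_real_,
                        s_center_um = NA_real_, s_max_um = NA_real_,
                        flagged = TRUE))
    thr <- threshold %||% (0.5 * max(vals))
    region <- mask & vol >= thr
    idx <- which(region)
    if (!length(idx))
      return(data.frame(frame = t - 1L, s_min_um = NA_real_,
                        s_center_um = NA_real_, s_max_um = NA_real_,
                        flagged = TRUE))
    # largest connected component of the nucleus region
    comp <- largest_component(region)
    idx <- which(comp)
    pts <- ind_to_um(arrayInd(idx, d[3:5]), stack$voxel_size_um)
    s <- project_onto_axis(pts, axis)
    w <- vol[idx]
    data.frame(frame = t - 1L,
               s_min_um = min(s) - margin_um,
               s_center_um = sum(s * w) / sum(w),
               s_max_um = max(s) + margin_um,
               flagged = FALSE)
  })
  do.call(rbind, rows)
}

# Largest 6-connected component of a logical (z, y, x) array.
largest_component <- function(region) {
  idx <- which(region)
  if (!length(idx)) return(region)
  # reuse the seeded machinery: components over the region graph
  d <- dim(region)
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)
  ind <- arrayInd(idx, d)
  edges <- list()
  strides <- c(1L, d[1], d[1] * d[2])
  for (k in 1:3) {
    ok <- ind[, k] < d[k]
    nb <- idx[ok] + strides[k]
    ok2 <- region[nb]
    if (any(ok2))
      edges[[length(edges) + 1L]] <- rbind(pos[idx[ok][ok2]], pos[nb[ok2]])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  comp <- igraph::components(g)
  keep <- comp$membership == which.max(comp$csize)
  out <- array(FALSE, d)
  out[idx[keep]] <- TRUE
  out
}
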