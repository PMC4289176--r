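#' Zero out exclusion walls in a volume
#'
#' Walls are user-supplied polylines in x-y pixel coordinates, rasterized
#' 8-connected (Bresenham) and extruded through every z-section as lines of
#' zero intensity. Because segmentation uses 6-connectivity (in-plane 4 plus
#' the two z-neighbors), a one-pixel 8-connected wall is a guaranteed
#' separator: no 6-connected path can cross it.
#'
#' @param volume numeric array `(z, y, x)`.
#' @param walls list of [wall()] objects.
#' @param frame 0-based frame index used to honor per-wall frame ranges.
#' @return The volume with wall voxels set to zero.
#' @export
apply_walls <- function(volume, walls, frame = 0) {
  if (length(walls) == 0L) return(volume)
  d <- dim(volume)
  for (w in walls) {
    if (!wall_applies(w, frame)) next
    px <- rasterize_wall(w)
    if (any(px[, 1] < 0 | px[, 1] >= d[3] | px[, 2] < 0 | px[, 2] >= d[2]))
      stop_geometry("wall extends outside the %d x %d grid", d[3], d[2])
    for (i in seq_len(nrow(px)))
      volume[, px[i, 2] + 1L, px[i, 1] + 1L] <- 0
  }
  volume
}

# 8-connected raster of a wall polyline; returns unique 0-based (x, y) rows.
rasterize_wall <- function(w) {
  v <- round(w$vertices)
  segs <- lapply(seq_len(nrow(v) - 1L), function(i)
    bresenham(v[i, 1], v[i, 2], v[i + 1L, 1], v[i + 1L, 2]))
  px <- unique(do.call(rbind, segs))
  colnames(px) <- c("x", "y")
  px
}

# Integer Bresenham line; output pixels are 8-connected.
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  out <- matrix(0L, dx - dy + 1L, 2L)
  n <- 0L
  repeat {
    n <- n + 1L
    out[n, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  out[seq_len(n), , drop = FALSE]
}

# Connected component (6-connectivity) of {volume >= threshold} containing
# the seed; returns a logical array. Built on igraph components over the
# voxel adjacency graph.
seeded_component <- function(above, seed_lin) {
  d <- dim(above)
  idx <- which(above)
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)
  ind <- arrayInd(idx, d)
  edges <- list()
  offs <- list(c(1L, 1L, 0L, 0L, 0L),      # +z: stride 1, need z < nz
               c(d[1], 0L, 1L, 0L, 0L),    # +y
               c(d[1] * d[2], 0L, 0L, 1L, 0L))  # +x
  lim <- c(z = d[1], y = d[2], x = d[3])
  for (k in 1:3) {
    stride <- offs[[k]][1]
    ok <- ind[, k] < lim[k]
    nb <- idx[ok] + stride
    ok2 <- above[nb]
    from <- pos[idx[ok][ok2]]
    to <- pos[nb[ok2]]
    if (length(from)) edges[[length(edges) + 1L]] <- rbind(from, to)
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  comp <- igraph::components(g)
  keep <- comp$membership == comp$membership[pos[seed_lin]]
  mask <- array(FALSE, d)
  mask[idx[keep]] <- TRUE
  mask
}

#' Segment one frame by seeded thresholding
#'
#' The cell mask is the 6-connected component of voxels with intensity at or
#' above `threshold` (after wall zeroing) that contains the soma seed.
#'
#' @param volume numeric array `(z, y, x)`.
#' @param threshold intensity threshold (inclusive).
#' @param seed_voxel integer vector `c(x, y, z)` of 0-based voxel indices
#'   inside the soma.
#' @param walls list of [wall()] objects.
#' @param frame 0-based frame index (for per-wall frame ranges).
#' @return List with `mask` (logical `(z, y, x)` array), `threshold`,
#'   `seed_voxel` and `n_voxels`.
#' @export
segment_frame <- function(volume, threshold, seed_voxel, walls = list(),
                          frame = 0) {
  d <- dim(volume)
  if (length(d) != 3L) stop_dimension("'volume' must be (z, y, x)")
  sv <- as.integer(round(seed_voxel))
  if (length(sv) != 3L || any(sv < 0L) || any(sv >= d[c(3, 2, 1)]))
    stop_geometry("seed voxel (%s) outside the grid",
                  paste(seed_voxel, collapse = ", "))
  if (threshold <= 0 && all(volume > 0))
    warning("threshold <= 0 on an all-positive volume; the mask will span the frame")
  vol <- apply_walls(volume, walls, frame)
  seed_lin <- 1L + sv[3] + d[1] * (sv[2] + d[2] * sv[1])  # (z,y,x) col-major
  if (vol[seed_lin] < threshold)
    stop_data("seed intensity %g below threshold %g (frame %d)",
              vol[seed_lin], threshold, frame)
  mask <- seeded_component(vol >= threshold, seed_lin)
  list(mask = mask, threshold = threshold, seed_voxel = sv,
       n_voxels = sum(mask))
}

#' Segment an image sequence with one per-cell threshold
#'
#' Applies [segment_frame()] to every frame of a channel with a single,
#' constant threshold (one threshold per cell, as in the interactive
#' protocol this reproduces). The frame-0 seed must be supplied; later
#' seeds default to the intensity-weighted centroid of the previous frame's
#' mask. A frame whose propagated seed falls below threshold is flagged and
#' recorded with an empty mask; processing continues.
#'
#' @param stack an [image_stack()].
#' @param channel channel label or 0-based index to segment.
#' @param threshold intensity threshold, constant over the sequence.
#' @param seed_voxel frame-0 seed, 0-based `c(x, y, z)`; or a matrix with
#'   one row per frame to pin every seed.
#' @param walls list of [wall()] objects.
#' @return An object of class `segmentation`: per-frame masks, the
#'   threshold, applied walls and a QC table (`frame`, `mask_voxels`,
#'   `flagged`).
#' @export
segment_sequence <- function(stack, channel, threshold, seed_voxel,
                             walls = list()) {
  d <- dim(stack$data)
  nt <- d[1]
  seeds <- if (is.matrix(seed_voxel)) seed_voxel else
    matrix(seed_voxel, nrow = 1)
  masks <- vector("list", nt)
  qc <- data.frame(frame = seq_len(nt) - 1L, mask_voxels = 0L,
                   flagged = FALSE)
  cur_seed <- seeds[1, ]
  for (t in seq_len(nt)) {
    if (nrow(seeds) >= t) cur_seed <- seeds[t, ]
    vol <- stack_volume(stack, t - 1L, channel)
    res <- tryCatch(
      segment_frame(vol, threshold, cur_seed, walls, frame = t - 1L),
      neurokym_data_error = function(e) e,
      neurokym_geometry_error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("frame %d flagged: %s", t - 1L, conditionMessage(res)))
      masks[[t]] <- array(FALSE, d[3:5])
      qc$flagged[t] <- TRUE
      next  # keep the previous seed candidate for the next frame
    }
    masks[[t]] <- res$mask
    qc$mask_voxels[t] <- res$n_voxels
    if (nrow(seeds) < t + 1L) {
      ctr <- mask_centroid_vox(res$mask, vol)
      if (!any(is.na(ctr))) cur_seed <- ctr
    }
  }
  structure(list(masks = masks, threshold = threshold, walls = walls,
                 qc = qc, voxel_size_um = stack$voxel_size_um),
            class = "segmentation")
}

# Intensity-weighted centroid of a mask, 0-based (x, y, z) voxel indices.
mask_centroid_vox <- function(mask, vol) {
  idx <- which(mask)
  if (!length(idx)) return(rep(NA_real_, 3))
  ind <- arrayInd(idx, dim(mask))
  wts <- vol[idx]
  if (sum(wts) <= 0) wts <- rep(1, length(idx))
  ctr <- colSums(ind * wts) / sum(wts)  # (z, y, x), 1-based
  round(rev(ctr) - 1)
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d frames, threshold %g, %d flagged\n",
              length(x$masks), x$threshold, sum(x$qc$flagged)))
  invisible(x)
}

#' Write/read segmentation masks as 8-bit TIFF plus QC sidecar
#'
#' @param seg a `segmentation`.
#' @param path TIFF path; the QC table goes to `<path>.qc.csv` and the
#'   threshold/shape metadata to `<path>.json`.
#' @return `read_segmentation()` returns a `segmentation`.
#' @export
write_segmentation <- function(seg, path) {
  d3 <- dim(seg$masks[[1]])
  pages <- unlist(lapply(seg$masks, function(m)
    lapply(seq_len(d3[1]), function(z) matrix(as.numeric(m[z, , ]),
                                              d3[2], d3[3]))),
    recursive = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "deflate")
  jsonlite::write_json(list(n_frames = length(seg$masks),
                            dim_zyx = as.integer(d3),
                            threshold = seg$threshold,
                            voxel_size_um = as.list(seg$voxel_size_um)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(seg$qc, paste0(path, ".qc.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d3 <- as.integer(meta$dim_zyx)
  masks <- lapply(seq_len(meta$n_frames), function(t) {
    m <- array(FALSE, d3)
    for (z in seq_len(d3[1]))
      m[z, , ] <- pages[[(t - 1L) * d3[1] + z]] > 0.5
    m
  })
  qc <- utils::read.csv(paste0(path, ".qc.csv"))
  structure(list(masks = masks, threshold = meta$threshold, walls = list(),
                 qc = qc,
                 voxel_size_um = unlist(meta$voxel_size_um)[c("x", "y", "z")]),
            class = "segmentation")
}
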