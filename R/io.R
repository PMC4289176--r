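#' Read and write image stacks as multi-page TIFF with a JSON sidecar
#'
#' `write_stack()` writes an [image_stack()] as a multi-page TIFF (32-bit
#' samples, page order t-major, then channel, then z) together with a JSON
#' metadata sidecar (`<path>.json`) holding the axis order `"TCZYX"`, the
#' five extents, voxel sizes, frame interval, channel labels and the
#' intensity scale. `read_stack()` reverses it.
#'
#' Baseline TIFF stores 32-bit samples as integers on a fixed scale, so
#' non-negative integer-valued intensities (camera counts) up to `2^32 - 1`
#' round-trip bit-exactly; other data are quantized to `2^-32` relative
#' precision with the scale recorded in the sidecar. Metadata round-trips to
#' better than 1e-9.
#'
#' Files lacking a sidecar can be read by supplying `axes`, a named integer
#' vector `c(t=, c=, z=)` factorizing the page count; otherwise a dimension
#' error reports what was found.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @param axes optional named integer vector `c(t=, c=, z=)` used when no
#'   sidecar is present.
#' @param voxel_size_um,frame_interval_s,channels metadata overrides used
#'   when no sidecar is present (sizes default to 1 with a warning).
#' @return `read_stack()` returns an [image_stack()]; `write_stack()`
#'   invisibly returns `path`.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) stop_format("not an image_stack")
  d <- dim(stack$data)
  v <- stack$data
  M <- 2^32 - 1
  vmax <- max(v)
  integerish <- vmax <= M && isTRUE(all(v == round(v)))
  if (integerish || vmax == 0) {
    q <- v
    scale <- 1
  } else {
    q <- round(v / vmax * M)
    scale <- vmax / M
  }
  enc <- pmin((q + 0.5) / M, 1)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    pages[[i]] <- matrix(enc[t, ch, z, , ], d[4], d[5])
    i <- i + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "deflate")
  meta <- list(axes = "TCZYX", dim = as.integer(d),
               voxel_size_um = as.list(stack$voxel_size_um),
               frame_interval_s = stack$frame_interval_s,
               channels = stack$channels,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, axes = NULL, voxel_size_um = NULL,
                       frame_interval_s = NULL, channels = NULL) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  npage <- length(pages)
  py <- nrow(pages[[1]]); px <- ncol(pages[[1]])

  sidecar <- paste0(path, ".json")
  scale <- 1
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(meta$axes, "TCZYX"))
      stop_dimension("unsupported axis order '%s' in sidecar", meta$axes)
    d <- as.integer(meta$dim)
    vs <- unlist(meta$voxel_size_um)[c("x", "y", "z")]
    if (any(vs <= 0))
      stop_metadata("negative or zero voxel size in sidecar: %s",
                    paste(signif(vs, 4), collapse = ", "))
    frame_interval_s <- meta$frame_interval_s
    channels <- meta$channels
    scale <- meta$intensity_scale %||% 1
    voxel_size_um <- vs
  } else if (!is.null(axes)) {
    need <- c("t", "c", "z")
    if (!all(need %in% names(axes)))
      stop_dimension("'axes' must name t, c and z page counts")
    d <- c(as.integer(axes[need]), py, px)
    if (prod(d[1:3]) != npage)
      stop_dimension("axes t*c*z = %d pages but file has %d",
                     prod(d[1:3]), npage)
    if (is.null(voxel_size_um)) {
      warning("no sidecar metadata; assuming 1 um voxels")
      voxel_size_um <- c(x = 1, y = 1, z = 1)
    }
    frame_interval_s <- frame_interval_s %||% 1
  } else {
    stop_dimension(paste0(
      "cannot resolve axes: found %d page(s) of %d x %d with no sidecar; ",
      "supply axes = c(t=, c=, z=)"), npage, py, px)
  }

  data <- array(0, d)
  i <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    data[t, ch, z, , ] <- pages[[i]] * 2^32
    i <- i + 1L
  }
  if (scale != 1) data <- data * scale
  image_stack(data, voxel_size_um = voxel_size_um,
              frame_interval_s = frame_interval_s, channels = channels)
}

#' Read organelle tracks from CSV
#'
#' Expects columns `track_id`, `frame`, `channel`, `x_um`, `y_um`, `z_um`.
#' Frame gaps are preserved (never interpolated); duplicate
#' `(track_id, frame)` rows and non-numeric coordinates are format errors.
#' An empty file yields an empty list with a warning.
#'
#' @param path CSV file path.
#' @return List of [track()] objects.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) {
    warning("no track rows in ", path)
    return(list())
  }
  need <- c("track_id", "frame", "channel", "x_um", "y_um", "z_um")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_format("missing track columns: %s", paste(missing, collapse = ", "))
  for (cc in c("frame", "x_um", "y_um", "z_um")) {
    val <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad))
      stop_format("non-numeric '%s' at row(s) %s", cc,
                  paste(utils::head(bad, 5), collapse = ", "))
    df[[cc]] <- val
  }
  key <- paste(df$track_id, df$frame)
  dup <- which(duplicated(key))
  if (length(dup))
    stop_format("duplicate (track_id, frame) at row(s) %s",
                paste(dup, collapse = ", "))
  lapply(split(df, df$track_id), function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    track(g$track_id[1], g$frame,
          cbind(g$x_um, g$y_um, g$z_um), channel = g$channel[1])
  })
}

#' @rdname read_tracks
#' @param tracks list of [track()] objects.
#' @export
write_tracks <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(track_id = tr$id, frame = tr$frames, channel = tr$channel,
               x_um = tr$pos[, 1], y_um = tr$pos[, 2], z_um = tr$pos[, 3],
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read segmentation walls from JSON
#'
#' Walls are polylines in x-y pixel coordinates (0-based) extruded through
#' all z, rasterized to zero intensity before segmentation. Each JSON entry
#' has a `vertices` list of `[x, y]` pairs and an optional `frames = [first,
#' last]` range (0-based, inclusive; absent = all frames).
#'
#' @param path JSON file path.
#' @return List of `wall` objects.
#' @export
read_walls <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  raw <- jsonlite::read_json(path)
  if (length(raw) == 0L) {
    warning("no walls in ", path)
    return(list())
  }
  lapply(raw, function(w) {
    vv <- do.call(rbind, lapply(w$vertices, function(p) as.numeric(unlist(p))))
    fr <- if (!is.null(w$frames)) as.numeric(unlist(w$frames)) else NULL
    wall(vv, frames = fr)
  })
}

#' @rdname read_walls
#' @param walls list of `wall` objects.
#' @export
write_walls <- function(walls, path) {
  out <- lapply(walls, function(w) {
    e <- list(vertices = lapply(seq_len(nrow(w$vertices)),
                                function(i) as.numeric(w$vertices[i, ])))
    if (!is.null(w$frames)) e$frames <- w$frames
    e
  })
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Construct a wall (exclusion polyline)
#'
#' @param vertices numeric matrix with columns x, y (0-based pixel
#'   coordinates); at least two vertices.
#' @param frames optional inclusive 0-based frame range `c(first, last)`.
#' @return An object of class `wall`.
#' @export
wall <- function(vertices, frames = NULL) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L)
    stop_format("a wall needs at least 2 vertices (got %d)", nrow(vertices))
  if (!is.numeric(vertices) || any(!is.finite(vertices)) ||
      ncol(vertices) != 2L)
    stop_format("wall vertices must be a numeric matrix with columns x, y")
  if (!is.null(frames) && (length(frames) != 2L || frames[1] > frames[2]))
    stop_format("wall 'frames' must be c(first, last)")
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, frames = frames), class = "wall")
}

wall_applies <- function(w, frame) {
  is.null(w$frames) || (frame >= w$frames[1] && frame <= w$frames[2])
}
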