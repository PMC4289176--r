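# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed errors so callers can distinguish contract violations.
stop_classed <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "neurokym_error")))
}

stop_config <- function(msg, ...)
  stop_classed("neurokym_config_error", msg, ...)

stop_geometry <- function(msg, ...)
  stop_classed("neurokym_geometry_error", msg, ...)

stop_format <- function(msg, ...)
  stop_classed("neurokym_format_error", msg, ...)

stop_dimension <- function(msg, ...)
  stop_classed("neurokym_dimension_error", msg, ...)

stop_metadata <- function(msg, ...)
  stop_classed("neurokym_metadata_error", msg, ...)

stop_data <- function(msg, ...)
  stop_classed("neurokym_data_error", msg, ...)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config("'%s' must be a single finite number", name)
  if (positive && x <= 0) stop_config("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stop_config("'%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}

# 1D Gaussian kernel, truncated at `half` sigmas, renormalized.
gauss_kernel <- function(sigma_vox, half = 4) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(half * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable Gaussian blur of a (z, y, x) array, sigma per axis in voxels.
# Zero padding at the borders; mass is conserved for support away from edges.
gauss_blur3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  blur_axis <- function(arr, axis, sigma) {
    if (sigma <= 0) return(arr)
    k <- gauss_kernel(sigma)
    n <- dim(arr)[axis]
    r <- (length(k) - 1L) %/% 2L
    # band matrix: column j receives kernel centered at j
    K <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n)
      keep <- idx + off >= 1L & idx + off <= n
      K[cbind(idx[keep] + off, idx[keep])] <- k[off + r + 1L]
    }
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    da <- dim(a)
    m <- matrix(a, nrow = da[1])
    out <- crossprod(K, m)  # t(K) %*% m: row i of out = sum_j k[i-j] m[j,]
    dim(out) <- da
    aperm(out, order(perm))
  }
  vol <- blur_axis(vol, 1L, sigma_vox[1])
  vol <- blur_axis(vol, 2L, sigma_vox[2])
  vol <- blur_axis(vol, 3L, sigma_vox[3])
  vol
}

# Shift a (z, y, x) array by a (possibly fractional) number of voxels along x,
# using linear interpolation (mass-conserving away from the borders).
shift_x <- function(vol, shift_vox) {
  d <- dim(vol)
  i0 <- floor(shift_vox)
  f <- shift_vox - i0
  out <- array(0, d)
  place <- function(arr, s, w) {
    if (w == 0) return()
    src <- seq_len(d[3]) - s
    keep <- src >= 1L & src <= d[3]
    if (any(keep))
      out[, , which(keep)] <<- out[, , which(keep), drop = FALSE] +
        w * arr[, , src[keep], drop = FALSE]
  }
  place(vol, i0, 1 - f)
  place(vol, i0 + 1L, f)
  out
}

# Sampled 3D Gaussian blob on the voxel grid (separable outer product).
# xs/ys/zs are voxel-center coordinates in micrometres.
gauss_blob <- function(xs, ys, zs, center, sigma, amplitude = 1) {
  gx <- exp(-(xs - center[1])^2 / (2 * sigma[1]^2))
  gy <- exp(-(ys - center[2])^2 / (2 * sigma[2]^2))
  gz <- exp(-(zs - center[3])^2 / (2 * sigma[3]^2))
  amplitude * (gz %o% gy %o% gx)
}

fmt_um <- function(x) sprintf("%.3g um", x)
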