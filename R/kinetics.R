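#' Construct an organelle track
#'
#' A time-indexed set of 3D physical positions for one labeled object.
#' Frames are 0-based and strictly increasing; gaps mark frames where the
#' object was not localized and contribute no velocity step.
#'
#' @param id track identifier.
#' @param frames integer vector of 0-based frame indices, strictly
#'   increasing.
#' @param pos numeric matrix `length(frames) x 3` of positions in
#'   micrometres (columns x, y, z).
#' @param channel channel label the object was tracked in.
#' @return An object of class `track`.
#' @export
track <- function(id, frames, pos, channel = NA_character_) {
  frames <- as.numeric(frames)
  pos <- matrix(as.numeric(pos), ncol = 3)
  if (length(frames) != nrow(pos))
    stop_format("track '%s': %d frames but %d positions", id,
                length(frames), nrow(pos))
  if (length(frames) > 1L && any(diff(frames) <= 0))
    stop_format("track '%s': frames must be strictly increasing", id)
  if (length(pos) && any(!is.finite(pos)))
    stop_format("track '%s': non-finite positions", id)
  colnames(pos) <- c("x", "y", "z")
  structure(list(id = as.character(id), frames = frames, pos = pos,
                 channel = as.character(channel)), class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("track '%s' (%s): %d frames", x$id, x$channel,
              length(x$frames)))
  if (length(x$frames))
    cat(sprintf(" [%g..%g]", min(x$frames), max(x$frames)))
  cat("\n")
  invisible(x)
}

#' Mean step velocity of a track
#'
#' The average velocity is the mean over consecutive-frame pairs of the 3D
#' Euclidean step length divided by the frame interval. Frame gaps
#' contribute no step (the convention of per-frame manual tracking tools).
#'
#' @param track a [track()].
#' @param frame_interval_s frame interval in seconds.
#' @return Mean velocity in micrometres per second.
#' @export
mean_velocity <- function(track, frame_interval_s) {
  check_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  sp <- step_speeds(track, frame_interval_s)
  if (length(sp) == 0L)
    stop_data("track '%s': needs >= 2 consecutive present frames", track$id)
  mean(sp)
}

# Per-step instantaneous speeds (consecutive frames only).
step_speeds <- function(track, frame_interval_s) {
  n <- length(track$frames)
  if (n < 2L) return(numeric(0))
  consec <- which(diff(track$frames) == 1)
  if (!length(consec)) return(numeric(0))
  d <- track$pos[consec + 1L, , drop = FALSE] -
    track$pos[consec, , drop = FALSE]
  sqrt(rowSums(d^2)) / frame_interval_s
}

#' Inclusion rule: visible over enough consecutive frames
#'
#' @param track a [track()].
#' @param min_consecutive minimum run of consecutive present frames
#'   (default 5, the assay's inclusion rule).
#' @return `TRUE` if some run of at least `min_consecutive` consecutive
#'   frames exists.
#' @export
valid_track <- function(track, min_consecutive = 5) {
  n <- length(track$frames)
  if (n == 0L) return(FALSE)
  d <- diff(track$frames) == 1
  runs <- rle(d)
  # a maximal run of k consecutive unit steps spans k + 1 frames
  best <- if (any(runs$values)) max(runs$lengths[runs$values]) + 1L else 1L
  best >= min_consecutive
}

#' Classify a track as migrating
#'
#' A neuron is considered migrating when its net displacement (first to last
#' present position, straight-line) exceeds two cell body lengths. The
#' comparison is strict.
#'
#' @param track a [track()].
#' @param cell_body_length_um cell body length; a natural default is the
#'   frame-0 soma extent along the migration axis from [soma_overlay()].
#' @return Logical.
#' @export
classify_migrating <- function(track, cell_body_length_um) {
  check_scalar(cell_body_length_um, "cell_body_length_um", positive = TRUE)
  if (length(track$frames) < 2L) return(FALSE)
  net <- sqrt(sum((track$pos[nrow(track$pos), ] - track$pos[1, ])^2))
  net > 2 * cell_body_length_um
}

#' Split a track around a drug addition
#'
#' Partitions the frames of a track into pre-treatment (`t <= drug_time_s`),
#' an excluded settling window (`drug_time_s < t <= exclude_until_s`,
#' discarded to avoid focus loss and bath-addition motion), and
#' post-treatment (`t > exclude_until_s`). Defaults follow the acute
#' migration assay: drug at 24 min of a 60-min movie sampled every 2 min,
#' with the 26-32 min time points excluded.
#'
#' @param track a [track()].
#' @param frame_interval_s frame interval in seconds.
#' @param drug_time_s time of drug addition (s).
#' @param exclude_until_s end of the excluded window (s); must not precede
#'   `drug_time_s`. Equal to `drug_time_s` gives a clean two-way split.
#' @return List with `pre` and `post` sub-tracks (possibly with zero
#'   frames).
#' @export
split_pre_post <- function(track, frame_interval_s,
                           drug_time_s = 24 * 60,
                           exclude_until_s = 32 * 60) {
  check_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  check_scalar(drug_time_s, "drug_time_s", nonneg = TRUE)
  check_scalar(exclude_until_s, "exclude_until_s", nonneg = TRUE)
  if (exclude_until_s < drug_time_s) {
    warning("excluded window ends before drug addition; using drug_time_s")
    exclude_until_s <- drug_time_s
  }
  tt <- track$frames * frame_interval_s
  pre_i <- which(tt <= drug_time_s)
  post_i <- which(tt > exclude_until_s)
  if (!length(post_i) && max(c(tt, -Inf)) <= drug_time_s)
    warning("drug_time_s is at or after the last frame; post split is empty")
  sub <- function(i) track(track$id, track$frames[i],
                           track$pos[i, , drop = FALSE],
                           channel = track$channel)
  list(pre = sub(pre_i), post = sub(post_i))
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom, as used for the drug-effect velocity and FRAP half-life
#' comparisons. The degenerate case (both groups constant) is reported
#' rather than an error: equal means give `t = 0, p = 1`, unequal means
#' `p = 0`, both flagged.
#'
#' @param a,b numeric vectors, each with at least two values.
#' @return An object of class `welch_test` with fields `t`, `df`, `p`,
#'   per-group mean/sd/n and a `degenerate` flag.
#' @export
welch_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop_data("each group needs n >= 2 (got %d and %d)", length(a), length(b))
  degenerate <- stats::var(a) == 0 && stats::var(b) == 0
  if (degenerate) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                df = NA_real_, p = if (eq) 1 else 0)
  } else {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  structure(c(res, list(
    mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
    degenerate = degenerate)), class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t-test: t = %.4g, df = %.4g, p = %.4g%s\n",
              x$t, x$df, x$p, if (x$degenerate) " (degenerate)" else ""))
  cat(sprintf("  a: %.4g +/- %.4g (n = %d);  b: %.4g +/- %.4g (n = %d)\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}

#' Group velocity statistics
#'
#' Applies the consecutive-frame inclusion rule, computes per-track mean
#' velocities and summarizes the group.
#'
#' @param tracks list of [track()] objects.
#' @param frame_interval_s frame interval in seconds.
#' @param min_consecutive inclusion rule passed to [valid_track()].
#' @return An object of class `velocity_stats`: per-track table plus group
#'   `mean`, `sd` and `n` (included tracks only).
#' @export
velocity_stats <- function(tracks, frame_interval_s, min_consecutive = 5) {
  rows <- lapply(tracks, function(tr) {
    ok <- valid_track(tr, min_consecutive)
    v <- if (ok) tryCatch(mean_velocity(tr, frame_interval_s),
                          error = function(e) NA_real_) else NA_real_
    data.frame(track_id = tr$id,
               mean_velocity_um_s = v,
               included = ok && !is.na(v),
               reason = if (!ok) "too few consecutive frames"
                        else if (is.na(v)) "no consecutive steps" else "",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  inc <- tab$mean_velocity_um_s[tab$included]
  structure(list(tracks = tab, mean = mean(inc), sd = stats::sd(inc),
                 n = length(inc)), class = "velocity_stats")
}

#' @export
print.velocity_stats <- function(x, ...) {
  cat(sprintf("velocity: %.4g +/- %.4g um/sec (SD), n = %d of %d tracks\n",
              x$mean, x$sd, x$n, nrow(x$tracks)))
  invisible(x)
}

#' Basal motility time course
#'
#' Summarizes per-timepoint velocity for the basal assay (5-minute movies at
#' 15-second intervals, repeated every 10 minutes after drug addition). Each
#' element of `blocks` is the list of tracks from one acquisition block.
#'
#' @param blocks named list of track lists (e.g. `pre`, `t10`, `t20`, ...).
#' @param frame_interval_s frame interval within a block (default 15 s).
#' @param min_consecutive inclusion rule passed to [valid_track()].
#' @return Data frame `block`, `mean_velocity_um_s`, `sd`, `n`; empty blocks
#'   are reported as absent (`NA` with `n = 0`), never as zero.
#' @export
basal_motility_series <- function(blocks, frame_interval_s = 15,
                                  min_consecutive = 5) {
  nm <- names(blocks) %||% as.character(seq_along(blocks))
  rows <- lapply(seq_along(blocks), function(i) {
    trs <- blocks[[i]]
    if (length(trs) == 0L)
      return(data.frame(block = nm[i], mean_velocity_um_s = NA_real_,
                        sd = NA_real_, n = 0L, stringsAsFactors = FALSE))
    st <- velocity_stats(trs, frame_interval_s, min_consecutive)
    data.frame(block = nm[i], mean_velocity_um_s = st$mean, sd = st$sd,
               n = st$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate localization-noisy tracks with known speed
#'
#' Generates in-plane constant-speed or fixed-step random-walk tracks for
#' estimator-recovery experiments. `mode = "linear"` moves along +x at
#' `speed_um_s`; `mode = "random_walk"` takes steps of fixed length
#' `speed_um_s * frame_interval_s` in uniformly random in-plane directions
#' (the basal-motility regime of a stationary cell). Gaussian localization
#' noise of `noise_sd_um` is then added independently to each in-plane
#' coordinate of every position; z is constant (trajectories lie in the
#' imaging plane and the axial coordinate carries no modeled noise).
#'
#' @param n number of tracks.
#' @param speed_um_s true mean speed.
#' @param frame_interval_s frame interval (s).
#' @param duration_s track duration (s); frames at `0, dt, ..., duration`.
#' @param noise_sd_um localization noise sigma per in-plane coordinate.
#' @param mode `"linear"` or `"random_walk"`.
#' @param seed optional RNG seed.
#' @return List of [track()] objects.
#' @export
simulate_tracks <- function(n, speed_um_s, frame_interval_s, duration_s,
                            noise_sd_um = 0, mode = c("linear", "random_walk"),
                            seed = NULL) {
  mode <- match.arg(mode)
  check_scalar(speed_um_s, "speed_um_s", nonneg = TRUE)
  check_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  nf <- floor(duration_s / frame_interval_s) + 1L
  step <- speed_um_s * frame_interval_s
  with_seed(seed, lapply(seq_len(n), function(i) {
    if (mode == "linear") {
      xy <- cbind((seq_len(nf) - 1) * step, 0)
    } else {
      th <- stats::runif(nf - 1L, 0, 2 * pi)
      xy <- rbind(c(0, 0),
                  cbind(cumsum(step * cos(th)), cumsum(step * sin(th))))
    }
    if (noise_sd_um > 0)
      xy <- xy + matrix(stats::rnorm(2 * nf, sd = noise_sd_um), ncol = 2)
    track(sprintf("sim%03d", i), seq_len(nf) - 1L,
          cbind(xy, 0), channel = "sim")
  }))
}
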