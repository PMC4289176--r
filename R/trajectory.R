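#' Two-stroke nucleus/organelle trajectory along the migration axis
#'
#' Generates paired axial positions (micrometres) for the nucleus and a
#' leading organelle under a square-wave two-stroke phase model: during the
#' first half of each cycle the organelle advances into the leading process
#' (its lead over the nucleus rises from 0 to `lead_amplitude_um` along a
#' triangular wave) while the nucleus is stationary; during the second half
#' the nucleus advances at twice its mean speed and catches up. Per cycle the
#' nucleus advances exactly `nucleus_speed_um_s * cycle_period_s`. Setting
#' `lead_amplitude_um = 0` selects the constant-speed degenerate mode (both
#' objects advance together at `nucleus_speed_um_s`), which makes mean step
#' lengths analytically exact for estimator-recovery tests.
#'
#' If `drug_time_s` is set, every displacement step taken after that time is
#' scaled by `post_drug_factor`, emulating acute inhibition of motility.
#'
#' @param config a [scene_config()].
#' @return A data frame with columns `frame` (0-based), `time_s`,
#'   `nucleus_um` and `organelle_um` (axial positions; the organelle leads or
#'   coincides with the nucleus at all times).
#' @export
two_stroke_trajectory <- function(config) {
  if (!inherits(config, "scene_config"))
    stop_config("'config' must be a scene_config object")
  tt <- (seq_len(config$n_frames) - 1) * config$frame_interval_s
  v <- config$nucleus_speed_um_s
  P <- config$cycle_period_s
  A <- config$lead_amplitude_um

  if (A == 0) {
    nuc <- v * tt
    org <- nuc
  } else {
    phase <- (tt %% P) / P
    cycles <- floor(tt / P)
    nuc <- cycles * v * P + pmax(0, phase - 0.5) * 2 * v * P
    lead <- A * (1 - abs(2 * phase - 1))
    org <- nuc + lead
  }

  if (!is.null(config$drug_time_s)) {
    fac <- ifelse(tt[-1] > config$drug_time_s, config$post_drug_factor, 1)
    nuc <- nuc[1] + c(0, cumsum(diff(nuc) * fac))
    org <- org[1] + c(0, cumsum(diff(org) * fac))
  }

  x0 <- scene_start_x(config)
  data.frame(frame = seq_len(config$n_frames) - 1L, time_s = tt,
             nucleus_um = x0 + nuc, organelle_um = x0 + org)
}
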