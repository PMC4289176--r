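#' Compartment signal fractions along the migration axis
#'
#' Partitions each frame's masked voxels into leading process
#' (`s > s_max`), soma (`s_min <= s <= s_max`, closed interval so boundary
#' voxels count as soma) and trailing process (`s < s_min`), where `s` is
#' the voxel center's projected coordinate on the migration axis, and
#' reports the intensity-weighted fraction of the channel's masked
#' fluorescence in each compartment. Fractions are normalized per frame and
#' sum to one whenever the total masked signal is positive; frames with
#' zero total signal are flagged with undefined fractions.
#'
#' @param stack an [image_stack()].
#' @param channel channel label or 0-based index (e.g. an adhesion
#'   reporter).
#' @param seg a `segmentation` aligned with the stack.
#' @param axis a [migration_axis()].
#' @param soma_intervals data frame with columns `frame`, `s_min_um`,
#'   `s_max_um` (typically from [soma_overlay()]).
#' @return A data frame of class `compartment_fractions`: `frame`,
#'   `time_s`, `f_leading`, `f_soma`, `f_trailing`, `s_min_um`, `s_max_um`,
#'   `flagged`.
#' @export
compartment_fractions <- function(stack, channel, seg, axis,
                                  soma_intervals) {
  d <- dim(stack$data)
  need <- c("frame", "s_min_um", "s_max_um")
  if (!all(need %in% names(soma_intervals)))
    stop_format("'soma_intervals' needs columns %s",
                paste(need, collapse = ", "))
  rows <- lapply(seq_len(d[1]), function(t) {
    fr <- t - 1L
    si <- soma_intervals[soma_intervals$frame == fr, , drop = FALSE]
    tt <- fr * stack$frame_interval_s
    blank <- data.frame(frame = fr, time_s = tt, f_leading = NA_real_,
                        f_soma = NA_real_, f_trailing = NA_real_,
                        s_min_um = NA_real_, s_max_um = NA_real_,
                        flagged = TRUE)
    if (nrow(si) != 1L || !is.finite(si$s_min_um) || !is.finite(si$s_max_um))
      return(blank)
    mask <- seg$masks[[t]]
    idx <- which(mask)
    if (!length(idx)) return(blank)
    vol <- stack_volume(stack, fr, channel)
    s <- project_onto_axis(ind_to_um(arrayInd(idx, d[3:5]),
                                     stack$voxel_size_um), axis)
    w <- vol[idx]
    total <- sum(w)
    if (total <= 0) return(blank)
    lead <- sum(w[s > si$s_max_um])
    trail <- sum(w[s < si$s_min_um])
    data.frame(frame = fr, time_s = tt,
               f_leading = lead / total,
               f_soma = (total - lead - trail) / total,
               f_trailing = trail / total,
               s_min_um = si$s_min_um, s_max_um = si$s_max_um,
               flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("compartment_fractions", "data.frame")
  out
}
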