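#' Simulate a FRAP recovery trace with known kinetics
#'
#' Generates a post-bleach intensity time series from the single-exponential
#' recovery model
#' \deqn{I(t) = I_{post} + (I_{plateau} - I_{post})(1 - e^{-kt})}
#' where \eqn{I_{plateau} - I_{post} = m (I_{pre} - I_{post})} for mobile
#' fraction \eqn{m}. The first sample (t = 0, the bleach moment) equals the
#' post-bleach floor exactly when noise is off.
#'
#' @param k recovery rate constant (1/sec), `> 0`. The half-life is
#'   `log(2)/k`.
#' @param mobile_fraction fraction of the bleached signal that recovers, in
#'   `[0, 1]`.
#' @param pre_level pre-bleach intensity.
#' @param bleach_depth fraction of `pre_level` removed by the bleach, in
#'   `(0, 1]`; the post-bleach floor is `pre_level * (1 - bleach_depth)`.
#' @param interval_s sampling interval after bleaching (2 s in the assays
#'   this emulates).
#' @param duration_s length of the post-bleach acquisition.
#' @param noise_sd additive Gaussian noise sigma (intensity units).
#' @param n_pre number of pre-bleach samples to prepend (at `pre_level`).
#' @param seed optional RNG seed.
#' @return List with `trace` (data frame `time_s`, `intensity`, `phase`) and
#'   `truth` (class `frap_truth`: `k`, `t_half_s = log(2)/k`,
#'   `mobile_fraction`, `pre_level`, `post_level`, `plateau`).
#' @export
generate_frap_trace <- function(k, mobile_fraction, pre_level = 100,
                                bleach_depth = 0.8, interval_s = 2,
                                duration_s = 60, noise_sd = 0,
                                n_pre = 0, seed = NULL) {
  check_scalar(k, "k", positive = TRUE)
  check_scalar(mobile_fraction, "mobile_fraction", nonneg = TRUE)
  if (mobile_fraction > 1)
    stop_config("'mobile_fraction' must be in [0, 1] (got %g)", mobile_fraction)
  check_scalar(interval_s, "interval_s", positive = TRUE)
  check_scalar(bleach_depth, "bleach_depth")
  if (bleach_depth <= 0)
    stop_config("'bleach_depth' must be > 0 (got %g)", bleach_depth)

  post <- pre_level * (1 - bleach_depth)
  plateau <- post + mobile_fraction * (pre_level - post)
  tt <- seq(0, duration_s, by = interval_s)
  ii <- post + (plateau - post) * (1 - exp(-k * tt))
  trace <- data.frame(time_s = tt, intensity = ii, phase = "post",
                      stringsAsFactors = FALSE)
  if (n_pre > 0) {
    pre <- data.frame(time_s = seq(-n_pre, -1) * interval_s,
                      intensity = rep(pre_level, n_pre), phase = "pre",
                      stringsAsFactors = FALSE)
    trace <- rbind(pre, trace)
  }
  if (noise_sd > 0)
    trace$intensity <- with_seed(seed,
      trace$intensity + rnorm(nrow(trace), sd = noise_sd))

  truth <- structure(list(k = k, t_half_s = log(2) / k,
                          mobile_fraction = mobile_fraction,
                          pre_level = pre_level, post_level = post,
                          plateau = plateau),
                     class = "frap_truth")
  list(trace = trace, truth = truth)
}
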