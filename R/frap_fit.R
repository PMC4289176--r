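#' Fit a single-exponential FRAP recovery model
#'
#' Least-squares fit of the standard minimal fluorescence-recovery model
#' \deqn{I(t) = I_{post} + (I_{plateau} - I_{post})(1 - e^{-kt})}
#' to a post-bleach intensity trace. The bleach floor \eqn{I_{post}} is
#' fixed to the first post-bleach sample; the plateau and the rate `k` are
#' free. The half-life is `t_half = log(2)/k` and the mobile fraction is
#' `(plateau - post) / (pre - post)` (clipped into `[0, 1]` with a flag
#' when the fit overshoots). `k` is initialized from a log-linear fit of
#' the normalized recovery deficit and refined with Levenberg-Marquardt
#' (`minpack.lm::nlsLM`) under a positivity bound.
#'
#' A trace with no increasing trend is reported as non-converged with a
#' diagnostic rather than fitted.
#'
#' @param times_s post-bleach sample times, seconds, starting at 0 (the
#'   bleach moment); at least 6 samples.
#' @param intensities intensities matching `times_s`.
#' @param pre_bleach_level scalar pre-bleach intensity; required unless
#'   `pre_intensities` is given, in which case their mean is used. Must
#'   exceed the first post-bleach sample.
#' @param pre_intensities optional vector of pre-bleach samples.
#' @return An object of class `frap_fit` with components `k`, `t_half_s`,
#'   `mobile_fraction`, `plateau`, `post_level`, `pre_level`, `r_squared`,
#'   `converged`, `clipped`, `diagnostic` and the data. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @export
fit_recovery <- function(times_s, intensities, pre_bleach_level = NULL,
                         pre_intensities = NULL) {
  if (is.null(pre_bleach_level)) {
    if (is.null(pre_intensities))
      stop_config("supply 'pre_bleach_level' or 'pre_intensities'")
    pre_bleach_level <- mean(pre_intensities)
  }
  tt <- as.numeric(times_s); ii <- as.numeric(intensities)
  if (length(tt) != length(ii)) stop_format("times and intensities differ")
  if (length(tt) < 6L)
    stop_data("need at least 6 post-bleach samples (got %d)", length(tt))
  if (abs(tt[1]) > 1e-9)
    stop_config("post-bleach times must start at 0 (got %g)", tt[1])
  i0 <- ii[1]
  if (pre_bleach_level <= i0)
    stop_config("pre-bleach level (%g) must exceed the first post-bleach sample (%g)",
                pre_bleach_level, i0)

  out <- structure(list(k = NA_real_, t_half_s = NA_real_,
                        mobile_fraction = NA_real_, plateau = NA_real_,
                        post_level = i0, pre_level = pre_bleach_level,
                        r_squared = NA_real_, converged = FALSE,
                        clipped = FALSE, diagnostic = "",
                        data = data.frame(time_s = tt, intensity = ii)),
                   class = "frap_fit")

  trend <- stats::coef(stats::lm(ii ~ tt))[2]
  if (!is.finite(trend) || trend <= 1e-12 * max(abs(ii), 1)) {
    out$diagnostic <- "no recovery: intensity trend is non-increasing"
    return(out)
  }

  # initial values: plateau from the trace tail, k from the log deficit
  ip0 <- mean(utils::tail(ii, max(3L, length(ii) %/% 5L)))
  if (ip0 <= i0) ip0 <- i0 + max(diff(range(ii)), .Machine$double.eps)
  deficit <- (ip0 - ii) / (ip0 - i0)
  use <- which(deficit > 0.02 & tt > 0)
  k0 <- if (length(use) >= 2L)
    max(1e-4, -stats::coef(stats::lm(log(deficit[use]) ~ 0 + tt[use]))[1])
  else log(2) / max(tt[2], 1e-6)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      ii ~ i0 + (ip - i0) * (1 - exp(-k * tt)),
      start = list(ip = ip0, k = k0),
      lower = c(ip = i0, k = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out$diagnostic <- paste("fit failed:", conditionMessage(fit))
    return(out)
  }
  cf <- stats::coef(fit)
  out$k <- unname(cf["k"])
  out$plateau <- unname(cf["ip"])
  out$t_half_s <- log(2) / out$k
  mf <- (out$plateau - i0) / (pre_bleach_level - i0)
  out$clipped <- mf < 0 || mf > 1
  out$mobile_fraction <- min(max(mf, 0), 1)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((ii - mean(ii))^2)
  out$r_squared <- if (tss > 0) 1 - rss / tss else NA_real_
  out$converged <- TRUE
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  if (!x$converged) {
    cat("FRAP fit: NOT converged -", x$diagnostic, "\n")
    return(invisible(x))
  }
  cat(sprintf("FRAP fit: k = %.4g /s, t1/2 = %.4g s, mobile fraction = %.3g%s\n",
              x$k, x$t_half_s, x$mobile_fraction,
              if (x$clipped) " (clipped)" else ""))
  cat(sprintf("  plateau %.4g, post %.4g, pre %.4g; R^2 = %.4f\n",
              x$plateau, x$post_level, x$pre_level, x$r_squared))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(k = object$k, t_half_s = object$t_half_s,
    mobile_fraction = object$mobile_fraction,
    plateau = object$plateau, post_level = object$post_level)
}

#' @export
fitted.frap_fit <- function(object, ...) {
  predict(object, object$data$time_s)
}

#' @export
residuals.frap_fit <- function(object, ...) {
  object$data$intensity - fitted(object)
}

#' @export
predict.frap_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$data$time_s
        else if (is.data.frame(newdata)) newdata$time_s
        else as.numeric(newdata)
  if (!object$converged) return(rep(NA_real_, length(tt)))
  object$post_level +
    (object$plateau - object$post_level) * (1 - exp(-object$k * tt))
}

#' @export
summary.frap_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.frap_fit")
}

#' @export
print.summary.frap_fit <- function(x, ...) {
  print(x$fit)
  if (x$fit$converged) {
    r <- residuals(x$fit)
    cat(sprintf("  residual sd %.4g over %d samples\n",
                stats::sd(r), length(r)))
  }
  invisible(x)
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$data$time_s, x$data$intensity, xlab = "time (s)",
                 ylab = "intensity", main = "FRAP recovery", ...)
  if (x$converged) {
    tt <- seq(0, max(x$data$time_s), length.out = 200)
    graphics::lines(tt, predict(x, tt), col = "red")
    graphics::abline(h = x$pre_level, lty = 2)
  }
  invisible(x)
}

#' Summarize FRAP fits by condition
#'
#' Per-condition mean and SD of the fitted half-life over converged fits,
#' with Welch tests of every condition against the designated control.
#' Conditions with fewer than two converged fits are dropped with a
#' warning.
#'
#' @param fits list of [fit_recovery()] results.
#' @param condition character vector assigning each fit to a condition.
#' @param control name of the control condition.
#' @return An object of class `frap_summary`: `summary` data frame
#'   (`condition`, `mean_t_half_s`, `sd_t_half_s`, `n`) and `tests` (list
#'   of [welch_t_test()] results vs control, named by condition).
#' @export
summarize_frap <- function(fits, condition, control = condition[1]) {
  if (length(fits) != length(condition))
    stop_format("%d fits but %d condition labels", length(fits),
                length(condition))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  th <- vapply(fits, function(f) f$t_half_s, numeric(1))
  groups <- split(th[conv], condition[conv])
  small <- names(groups)[vapply(groups, length, integer(1)) < 2L]
  if (length(small)) {
    warning("dropping condition(s) with < 2 converged fits: ",
            paste(small, collapse = ", "))
    groups <- groups[!names(groups) %in% small]
  }
  if (!control %in% names(groups))
    stop_data("control condition '%s' absent after filtering", control)
  summ <- data.frame(condition = names(groups),
                     mean_t_half_s = vapply(groups, mean, numeric(1)),
                     sd_t_half_s = vapply(groups, stats::sd, numeric(1)),
                     n = vapply(groups, length, integer(1)),
                     row.names = NULL, stringsAsFactors = FALSE)
  others <- setdiff(names(groups), control)
  tests <- stats::setNames(lapply(others, function(g)
    welch_t_test(groups[[g]], groups[[control]])), others)
  structure(list(summary = summ, tests = tests, control = control),
            class = "frap_summary")
}

#' @export
print.frap_summary <- function(x, ...) {
  cat("FRAP half-life by condition (control:", x$control, ")\n")
  print(x$summary, row.names = FALSE)
  for (g in names(x$tests))
    cat(sprintf("  %s vs %s: t = %.3g, p = %.3g\n", g, x$control,
                x$tests[[g]]$t, x$tests[[g]]$p))
  invisible(x)
}
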