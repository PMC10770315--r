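#' TEG amplitude trace
#'
#' Container for a thromboelastography clot-strength trace: amplitude in
#' millimeters on a strictly increasing time grid in minutes. This is the
#' universal currency of the package — simulation produces it, fitting
#' consumes it, feature extraction summarises it.
#'
#' @param time Numeric vector of times in minutes, strictly increasing,
#'   starting at or after 0.
#' @param amplitude Numeric vector of clot-strength amplitudes in mm, one per
#'   time point, all finite and non-negative.
#' @return An object of class `teg_curve` with components `time` and
#'   `amplitude`.
#' @examples
#' tc <- teg_curve(0:60, pmax(0, 0:60 - 10))
#' @export
teg_curve <- function(time, amplitude) {
  check_time_grid(time)
  amplitude <- as.numeric(amplitude)
  if (length(amplitude) != length(time))
    stop("`time` and `amplitude` must have the same length", call. = FALSE)
  if (length(time) < 2L)
    stop("a TEG curve needs at least 2 points", call. = FALSE)
  if (!all(is.finite(amplitude)))
    stop("`amplitude` must be finite", call. = FALSE)
  if (any(amplitude < 0))
    stop("`amplitude` must be >= 0 everywhere (clamp numerical residue before construction)",
         call. = FALSE)
  structure(list(time = as.numeric(time), amplitude = amplitude),
            class = "teg_curve")
}

#' Thrombin generation trace
#'
#' A Calibrated Automated Thrombogram (CAT) style record of thrombin
#' concentration (nM) over time (minutes), used as the input of the plasma
#' viscoelastic model. A warning is raised when the trace has not decayed
#' below 1\% of its peak by the final time point, because the convolution
#' horizon would then truncate the input.
#'
#' @param time Numeric vector of times in minutes, strictly increasing.
#' @param thrombin Numeric vector of thrombin concentrations in nM, >= 0.
#' @return An object of class `thrombin_curve`.
#' @export
thrombin_curve <- function(time, thrombin) {
  check_time_grid(time)
  thrombin <- as.numeric(thrombin)
  if (length(thrombin) != length(time))
    stop("`time` and `thrombin` must have the same length", call. = FALSE)
  if (length(time) < 2L)
    stop("a thrombin curve needs at least 2 points", call. = FALSE)
  if (!all(is.finite(thrombin)))
    stop("`thrombin` must be finite", call. = FALSE)
  if (any(thrombin < 0))
    stop("`thrombin` must be >= 0 everywhere", call. = FALSE)
  pk <- max(thrombin)
  if (pk > 0 && thrombin[length(thrombin)] > 0.01 * pk)
    warning("thrombin trace ends above 1% of its peak; ",
            "convolution against it will truncate the input tail",
            call. = FALSE)
  structure(list(time = as.numeric(time), thrombin = thrombin),
            class = "thrombin_curve")
}

check_time_grid <- function(time) {
  time <- as.numeric(time)
  if (!all(is.finite(time)))
    stop("`time` must be finite", call. = FALSE)
  if (length(time) >= 1L && time[1L] < 0)
    stop("`time` must start at >= 0", call. = FALSE)
  if (length(time) >= 2L && any(diff(time) <= 0))
    stop("`time` must be strictly increasing", call. = FALSE)
  invisible(time)
}

#' @export
print.teg_curve <- function(x, ...) {
  cat(sprintf("TEG curve: %d points, t = [%.3g, %.3g] min, max amplitude %.3g mm\n",
              length(x$time), x$time[1L], x$time[length(x$time)],
              max(x$amplitude)))
  invisible(x)
}

#' @export
print.thrombin_curve <- function(x, ...) {
  cat(sprintf("Thrombin curve: %d points, t = [%.3g, %.3g] min, peak %.3g nM\n",
              length(x$time), x$time[1L], x$time[length(x$time)],
              max(x$thrombin)))
  invisible(x)
}

#' Linear interpolation of a curve at arbitrary times
#'
#' @param curve A `teg_curve` or `thrombin_curve`.
#' @param at Times (minutes) at which to evaluate; values outside the curve's
#'   support evaluate to 0 (curves are zero outside their recorded window).
#' @return Numeric vector of interpolated values.
#' @keywords internal
curve_value_at <- function(curve, at) {
  y <- if (inherits(curve, "thrombin_curve")) curve$thrombin else curve$amplitude
  out <- stats::approx(curve$time, y, xout = at, rule = 2)$y
  out[at < curve$time[1L] | at > curve$time[length(curve$time)]] <- 0
  out
}

#' Default uniform simulation grid
#'
#' Uniform grid with spacing `dt` minutes from 0 to `horizon`, the typical
#' 5-second TEG sampling cadence by default.
#'
#' @param horizon End of the grid in minutes.
#' @param dt Grid spacing in minutes (default 1/12 min = 5 s).
#' @return Numeric vector of times.
#' @export
teg_grid <- function(horizon = 90, dt = 1 / 12) {
  if (horizon <= 0 || dt <= 0) stop("`horizon` and `dt` must be positive", call. = FALSE)
  seq(0, horizon, by = dt)
}
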