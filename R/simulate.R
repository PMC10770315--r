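#' Simulate a plasma TEG curve for an impulsive input
#'
#' Evaluates the closed-form impulse response of the delayed second-order
#' plasma model on the requested grid:
#' \deqn{A(t) = \mathrm{area} \cdot K_{np} (1 - e^{-(t - K_{dp})/K_p})}
#' for `t >= K_dp`, 0 before. The curve is monotone non-decreasing with
#' supremum `area * K_np`.
#'
#' @param params A [plasma_params()] object.
#' @param grid Strictly increasing time grid, minutes.
#' @param area Input impulse area (default 1).
#' @return A [teg_curve()].
#' @examples
#' p <- plasma_params(60, 8, 10)
#' plasma_impulse_curve(p, teg_grid(60))
#' @export
plasma_impulse_curve <- function(params, grid, area = 1) {
  if (!inherits(params, "plasma_params"))
    stop("`params` must be plasma_params", call. = FALSE)
  stop_on_violations(params)
  grid <- check_time_grid(grid)
  if (length(grid) < 2L) stop("`grid` must have at least 2 points", call. = FALSE)
  if (!is.finite(area) || area < 0) stop("`area` must be >= 0", call. = FALSE)
  amp <- area * params$K_np * sat_exp(grid, params$K_p, params$K_dp)
  teg_curve(grid, clamp_amplitude(amp, scale = area * params$K_np))
}

#' Simulate the plasma TEG response to a thrombin trace
#'
#' Convolves a thrombin-generation input with the impulse response of the
#' plasma model. The input is linearly resampled onto a uniform grid, delayed
#' by `K_dp`, and convolved with the delay-free closed-form impulse response
#' using the trapezoid rule; the result is interpolated back onto the
#' requested output grid. The underlying system is linear and time-invariant,
#' so superposition and time-shift identities hold to numerical precision.
#'
#' @param params A [plasma_params()] object.
#' @param input A [thrombin_curve()]. If the requested grid extends far past
#'   the input's support while the input has not decayed, a warning is
#'   raised by the input constructor's 1\%-of-peak rule.
#' @param grid Strictly increasing output time grid, minutes.
#' @param dt Internal convolution step, minutes (default 1/96 min; the
#'   output is interpolated from this finer grid).
#' @return A [teg_curve()].
#' @export
plasma_response_to_thrombin <- function(params, input, grid, dt = 1 / 96) {
  if (!inherits(params, "plasma_params"))
    stop("`params` must be plasma_params", call. = FALSE)
  if (!inherits(input, "thrombin_curve"))
    stop("`input` must be a thrombin_curve", call. = FALSE)
  stop_on_violations(params)
  grid <- check_time_grid(grid)
  if (length(grid) < 2L) stop("`grid` must have at least 2 points", call. = FALSE)

  t_end <- max(grid)
  tt <- seq(0, t_end, by = dt)
  if (tt[length(tt)] < t_end) tt <- c(tt, t_end)
  # delay the input rather than the kernel: y_d(t) = y(t - K_dp)
  yd <- curve_value_at(input, tt - params$K_dp)
  h <- params$K_np * (1 - exp(-tt / params$K_p))
  amp_u <- trapezoid_convolve(h, yd, dt)
  amp <- stats::approx(tt, amp_u, xout = grid, rule = 2)$y
  teg_curve(grid, clamp_amplitude(amp, scale = max(abs(amp), 1)))
}

# discrete convolution r[k] = dt * sum_{j=1}^{k} h[k-j+1] y[j] with trapezoid
# end-point weights, computed via FFT (stats::convolve, open type)
trapezoid_convolve <- function(h, y, dt) {
  n <- length(h)
  full <- stats::convolve(h, rev(y), type = "open")[seq_len(n)]
  # trapezoid rule halves the j = 1 and j = k terms
  r <- full - 0.5 * h * y[1L] - 0.5 * h[1L] * y
  r * dt
}

#' Simulate a whole-blood TEG curve
#'
#' Evaluates the closed form of the two-term whole-blood model driven by a
#' tissue-factor impulse:
#' \deqn{A(t) = \mathrm{area} [K_{n1} f(t; K_{p1}, K_{d1}) -
#'              K_{n2} f(t; K_{p2}, K_{d2})]}
#' with \eqn{f(t; K_p, K_d) = (1 - e^{-(t-K_d)/K_p}) 1\{t \ge K_d\}}. The
#' first term captures clot formation (platelet-scaled), the second
#' fibrinolysis. Negative excursions beyond numerical residue trigger a
#' model-validity warning; amplitudes are then clamped at 0.
#'
#' @param params A [whole_blood_params()] object.
#' @param grid Strictly increasing time grid, minutes.
#' @param tf A [tf_impulse()] (default area 5).
#' @return A [teg_curve()].
#' @examples
#' wb <- whole_blood_params(60, 8, 10, 20, 15, 30)
#' whole_blood_curve(wb, teg_grid(90), tf_impulse(1))
#' @export
whole_blood_curve <- function(params, grid, tf = tf_impulse()) {
  if (!inherits(params, "whole_blood_params"))
    stop("`params` must be whole_blood_params", call. = FALSE)
  if (!inherits(tf, "tf_impulse")) stop("`tf` must be a tf_impulse", call. = FALSE)
  stop_on_violations(params)
  grid <- check_time_grid(grid)
  if (length(grid) < 2L) stop("`grid` must have at least 2 points", call. = FALSE)
  amp <- wb_closed_form(params, grid, tf$area)
  teg_curve(grid, clamp_amplitude(amp, scale = tf$area * params$K_n1))
}

# clamp tiny negative numerical residue silently; warn on real negativity
clamp_amplitude <- function(amp, scale) {
  tol <- 1e-9 * max(scale, 1)
  if (min(amp) < -tol)
    warning(sprintf(
      "simulated amplitude goes negative (min %.4g mm); clamping to 0 - check parameter orderings",
      min(amp)), call. = FALSE)
  pmax(amp, 0)
}
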