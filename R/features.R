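#' Clinical TEG scalar parameters
#'
#' Bundle of the standard scalar summaries of a TEG trace: `R` (minutes to
#' 2 mm amplitude), `K` (minutes from R to 20 mm), `alpha` (degrees, slope
#' proxy), `MA` (maximum amplitude, mm), `t_MA` (minutes at which MA is
#' attained) and `Ly30` (percent lysis 30 min after t_MA). Any field may be
#' `NA` with an entry in `reasons` explaining why it is undefined.
#'
#' @param R,K,alpha,MA,t_MA,Ly30 Numeric scalars or `NA`.
#' @param reasons Named list of strings for the `NA` fields.
#' @return An object of class `teg_scalar_params`.
#' @export
teg_scalar_params <- function(R = NA_real_, K = NA_real_, alpha = NA_real_,
                              MA = NA_real_, t_MA = NA_real_,
                              Ly30 = NA_real_, reasons = list()) {
  chk <- function(v, lo, hi, name) {
    if (!is.na(v) && (v < lo || v > hi))
      stop(sprintf("%s = %g outside [%g, %g]", name, v, lo, hi), call. = FALSE)
  }
  chk(R, 0, Inf, "R"); chk(K, 0, Inf, "K"); chk(MA, 0, Inf, "MA")
  chk(Ly30, 0, 100, "Ly30")
  if (!is.na(alpha) && (alpha < 0 || alpha >= 90))
    stop("alpha must be in [0, 90) degrees", call. = FALSE)
  if (!is.na(t_MA) && !is.na(R) && t_MA < R - 1e-9)
    stop("t_MA cannot precede R", call. = FALSE)
  structure(list(R = R, K = K, alpha = alpha, MA = MA, t_MA = t_MA,
                 Ly30 = Ly30, reasons = reasons),
            class = "teg_scalar_params")
}

#' @export
print.teg_scalar_params <- function(x, ...) {
  fmt <- function(v, unit) if (is.na(v)) "undefined" else sprintf("%.4g %s", v, unit)
  cat("TEG parameters:\n",
      sprintf("  R    = %s\n", fmt(x$R, "min")),
      sprintf("  K    = %s\n", fmt(x$K, "min")),
      sprintf("  alpha= %s\n", fmt(x$alpha, "deg")),
      sprintf("  MA   = %s at t_MA = %s\n", fmt(x$MA, "mm"), fmt(x$t_MA, "min")),
      sprintf("  Ly30 = %s\n", fmt(x$Ly30, "%")), sep = "")
  for (nm in names(x$reasons))
    cat(sprintf("  [%s undefined: %s]\n", nm, x$reasons[[nm]]))
  invisible(x)
}

# first time the curve crosses `level` going upward, linear interpolation
first_crossing <- function(curve, level) {
  a <- curve$amplitude; t <- curve$time
  if (max(a) < level) return(NA_real_)
  i <- which(a >= level)[1L]
  if (i == 1L) return(t[1L])
  t[i - 1L] + (level - a[i - 1L]) / (a[i] - a[i - 1L]) * (t[i] - t[i - 1L])
}

#' Extract R and K times from a TEG curve
#'
#' `R` is the first time the amplitude crosses 2 mm (clot initiation) and
#' `K` the additional time until 20 mm is reached (clot kinetics), both by
#' linear interpolation between bracketing samples. Either is `NA`, with a
#' reason, when the threshold is never reached.
#'
#' @param curve A [teg_curve()].
#' @return List with `R`, `K` (minutes, possibly `NA`) and `reasons`.
#' @export
extract_r_k <- function(curve) {
  stopifnot(inherits(curve, "teg_curve"))
  reasons <- list()
  R <- first_crossing(curve, 2)
  if (is.na(R))
    reasons$R <- sprintf("max amplitude %.3g mm < 2 mm", max(curve$amplitude))
  t20 <- first_crossing(curve, 20)
  K <- if (is.na(t20) || is.na(R)) NA_real_ else t20 - R
  if (is.na(t20))
    reasons$K <- sprintf("max amplitude %.3g mm < 20 mm", max(curve$amplitude))
  list(R = R, K = K, reasons = reasons)
}

#' Extract the alpha angle from a TEG curve
#'
#' The alpha angle proxies the initial rate of clot formation. Default
#' convention: `alpha = atan(max forward-difference slope in mm/min)` in
#' degrees, which on model-generated curves equals
#' `atan(area * K_n1 / K_p1)` at the clot-initiation instant and is strictly
#' decreasing in `K_p1`. The alternative clinical secant convention (slope
#' of the chord from the 2 mm to the 20 mm crossing) is available via
#' `method = "secant"`.
#'
#' @param curve A [teg_curve()] with at least 3 points.
#' @param method `"max_slope"` (default) or `"secant"`.
#' @return Angle in degrees; 0 with a warning for a flat curve.
#' @export
extract_alpha <- function(curve, method = c("max_slope", "secant")) {
  stopifnot(inherits(curve, "teg_curve"))
  method <- match.arg(method)
  if (length(curve$time) < 3L)
    stop("alpha extraction needs at least 3 points", call. = FALSE)
  if (method == "secant") {
    t2 <- first_crossing(curve, 2); t20 <- first_crossing(curve, 20)
    if (is.na(t2) || is.na(t20) || t20 <= t2) {
      warning("secant alpha undefined (thresholds not bracketed); falling back to max slope",
              call. = FALSE)
      return(extract_alpha(curve, "max_slope"))
    }
    return(atan2(18, t20 - t2) * 180 / pi)
  }
  slopes <- diff(curve$amplitude) / diff(curve$time)
  m <- max(slopes)
  if (m <= 0) {
    warning("flat curve: alpha = 0", call. = FALSE)
    return(0)
  }
  atan(m) * 180 / pi
}

#' Extract MA, its time, and Ly30 from a TEG curve
#'
#' `MA` is the maximum amplitude; `t_MA` the earliest time attaining it
#' (within 1e-9 mm tolerance); `Ly30` the percent amplitude loss 30 min
#' after `t_MA`, `100 * (MA - A(t_MA + 30)) / MA` clamped to \[0, 100\].
#' `Ly30` is `NA` with a reason when the curve does not extend 30 min past
#' `t_MA`, or when `MA = 0`.
#'
#' @param curve A [teg_curve()].
#' @return List with `MA` (mm), `t_MA` (min), `Ly30` (percent, possibly
#'   `NA`) and `reasons`.
#' @export
extract_ma_ly30 <- function(curve) {
  stopifnot(inherits(curve, "teg_curve"))
  reasons <- list()
  MA <- max(curve$amplitude)
  t_MA <- curve$time[which(curve$amplitude >= MA - 1e-9)[1L]]
  horizon <- curve$time[length(curve$time)]
  if (MA <= 0) {
    reasons$Ly30 <- "MA = 0: lysis fraction undefined"
    return(list(MA = 0, t_MA = t_MA, Ly30 = NA_real_, reasons = reasons))
  }
  if (horizon < t_MA + 30) {
    # a trace still at its maximum when recording ends shows no lysis at
    # all, so its observed Ly30 is 0; a trace caught mid-decay is genuinely
    # undefined because the 30-minute mark lies beyond the record
    if (curve$amplitude[length(curve$amplitude)] >= MA - 1e-9)
      return(list(MA = MA, t_MA = t_MA, Ly30 = 0, reasons = reasons))
    reasons$Ly30 <- sprintf(
      "curve ends %.3g min after t_MA; 30 min required", horizon - t_MA)
    return(list(MA = MA, t_MA = t_MA, Ly30 = NA_real_, reasons = reasons))
  }
  a30 <- curve_value_at(curve, t_MA + 30)
  Ly30 <- min(max(100 * (MA - a30) / MA, 0), 100)
  list(MA = MA, t_MA = t_MA, Ly30 = Ly30, reasons = reasons)
}

#' All scalar TEG parameters of a curve
#'
#' Convenience wrapper running [extract_r_k()], [extract_alpha()] and
#' [extract_ma_ly30()] and assembling a [teg_scalar_params()] object.
#'
#' @param curve A [teg_curve()].
#' @param alpha_method Passed to [extract_alpha()].
#' @return A `teg_scalar_params` object.
#' @export
teg_features <- function(curve, alpha_method = "max_slope") {
  rk <- extract_r_k(curve)
  alpha <- suppressWarnings(extract_alpha(curve, alpha_method))
  ml <- extract_ma_ly30(curve)
  teg_scalar_params(R = rk$R, K = rk$K, alpha = alpha, MA = ml$MA,
                    t_MA = ml$t_MA, Ly30 = ml$Ly30,
                    reasons = c(rk$reasons, ml$reasons))
}

#' Fibrinolytic AUC reduction of a whole-blood model
#'
#' The ratio of the area under the lysis term to the area under the
#' formation term over `[0, horizon]`, computed from the analytic
#' antiderivative of \eqn{f(t; K_p, K_d)}. This model-side lysis index is
#' directly related to Ly30 and increases monotonically with `K_n2`.
#'
#' @param params A [whole_blood_params()] object.
#' @param tf A [tf_impulse()].
#' @param horizon Integration end, minutes; must exceed `K_d2` for lysis to
#'   be observed (otherwise 0 with a warning).
#' @return Fraction in \[0, 1\] (can exceed 1 only if the lysis term
#'   dominates, which the parameter warnings flag).
#' @export
auc_reduction <- function(params, tf = tf_impulse(), horizon = 90) {
  stopifnot(inherits(params, "whole_blood_params"))
  stop_on_violations(params)
  if (horizon <= params$K_d2) {
    warning("horizon <= K_d2: no lysis observed, AUC reduction = 0", call. = FALSE)
    return(0)
  }
  num <- params$K_n2 * sat_exp_integral(horizon, params$K_p2, params$K_d2)
  den <- params$K_n1 * sat_exp_integral(horizon, params$K_p1, params$K_d1)
  if (den <= 0) return(0)
  num / den
}

# \int_0^H f(t; K_p, K_d) dt  with f = (1 - e^{-(t-K_d)/K_p}) 1{t >= K_d}
sat_exp_integral <- function(H, K_p, K_d) {
  if (H <= K_d) return(0)
  s <- H - K_d
  s - K_p * (1 - exp(-s / K_p))
}

#' Shear elasticity from maximum amplitude
#'
#' The standard transform of a TEG MA value to shear elasticity,
#' \eqn{G_f = 5000 \cdot MA / (100 - MA)} in dynes/cm^2 (0.1 Pa).
#' Strictly increasing on \[0, 100).
#'
#' @param MA Maximum amplitude in mm, `0 <= MA < 100`.
#' @return Shear elasticity, dynes/cm^2.
#' @examples
#' shear_elasticity(50)  # 5000
#' @export
shear_elasticity <- function(MA) {
  if (any(!is.finite(MA)) || any(MA < 0) || any(MA >= 100))
    stop("MA must satisfy 0 <= MA < 100", call. = FALSE)
  5000 * MA / (100 - MA)
}

#' Inverse of the shear-elasticity transform
#'
#' @param G_f Shear elasticity, dynes/cm^2, >= 0.
#' @return MA in mm; round-trips with [shear_elasticity()] to 1e-12.
#' @export
ma_from_shear_elasticity <- function(G_f) {
  if (any(!is.finite(G_f)) || any(G_f < 0))
    stop("G_f must be finite and >= 0", call. = FALSE)
  100 * G_f / (5000 + G_f)
}
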