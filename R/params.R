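#' Plasma viscoelastic model parameters
#'
#' Parameters of the delayed second-order transfer function that maps a
#' thrombin-generation input to a platelet-poor-plasma TEG output,
#' \deqn{G(s) = K_{np} / (s (K_p s + 1)) \, e^{-K_{dp} s}.}
#' `K_np` sets the maximum amplitude (clot firmness) per unit input area,
#' `K_p` is the time constant of clot-formation kinetics (minutes) and
#' `K_dp` the clot-initiation delay (minutes). All three must be strictly
#' positive.
#'
#' @param K_np Gain, mm per unit input area.
#' @param K_p Time constant, minutes.
#' @param K_dp Delay, minutes.
#' @return An object of class `plasma_params`.
#' @examples
#' plasma_params(K_np = 60, K_p = 8, K_dp = 10)
#' @export
plasma_params <- function(K_np, K_p, K_dp) {
  p <- structure(list(K_np = as.numeric(K_np), K_p = as.numeric(K_p),
                      K_dp = as.numeric(K_dp)),
                 class = "plasma_params")
  stop_on_violations(p)
  p
}

#' Whole-blood viscoelastic model parameters
#'
#' Parameters of the two-term delayed second-order model of whole-blood clot
#' dynamics: a formation term (gain `K_n1`, time constant `K_p1`, delay
#' `K_d1`, the delay being the time to initial clot formation) minus a
#' fibrinolysis term (`K_n2`, `K_p2`, `K_d2`, the delay being the time to
#' lysis onset). All six parameters must be strictly positive. Orderings
#' `K_d2 >= K_d1` and `K_n2 <= K_n1` are expected on physical grounds
#' (lysis starts after formation; the trace should not go negative) but are
#' reported as warnings by [validate_params()], not hard errors.
#'
#' @param K_n1,K_n2 Gains, mm per unit tissue-factor impulse area.
#' @param K_p1,K_p2 Time constants, minutes.
#' @param K_d1,K_d2 Delays, minutes.
#' @return An object of class `whole_blood_params`.
#' @examples
#' whole_blood_params(60, 8, 10, 20, 15, 30)
#' @export
whole_blood_params <- function(K_n1, K_p1, K_d1, K_n2, K_p2, K_d2) {
  p <- structure(list(K_n1 = as.numeric(K_n1), K_p1 = as.numeric(K_p1),
                      K_d1 = as.numeric(K_d1), K_n2 = as.numeric(K_n2),
                      K_p2 = as.numeric(K_p2), K_d2 = as.numeric(K_d2)),
                 class = "whole_blood_params")
  stop_on_violations(p)
  p
}

#' Tissue-factor impulse input
#'
#' The whole-blood model is driven by an impulsive tissue-factor input,
#' represented as a Dirac impulse of the stated area (default 5, the typical
#' 5 pM TF trigger). Gains absorb unit conversion to mm, so only the product
#' of area and gain is observable.
#'
#' @param area Impulse magnitude (pM), > 0.
#' @return An object of class `tf_impulse`.
#' @export
tf_impulse <- function(area = 5) {
  if (!is.finite(area) || area <= 0)
    stop("TF impulse `area` must be a positive finite number", call. = FALSE)
  structure(list(area = as.numeric(area)), class = "tf_impulse")
}

param_names <- function(params) {
  if (inherits(params, "plasma_params")) c("K_np", "K_p", "K_dp")
  else c("K_n1", "K_p1", "K_d1", "K_n2", "K_p2", "K_d2")
}

positivity_violations <- function(params) {
  vals <- unlist(params, use.names = TRUE)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad))
    sprintf("parameter %s must be strictly positive (got %g)", bad,
            vals[bad])
  else character()
}

stop_on_violations <- function(params) {
  v <- positivity_violations(params)
  if (length(v)) stop(paste(v, collapse = "; "), call. = FALSE)
  invisible(params)
}

#' Diagnose a parameter set
#'
#' Returns a character vector of violated invariants and soft warnings:
#' positivity for either model, and for the whole-blood model the ordering
#' `K_d2 >= K_d1`, the gain ordering `K_n2 <= K_n1`, and non-negativity of
#' the implied curve on a probe grid. An empty vector means fully valid.
#'
#' @param params A `plasma_params` or `whole_blood_params` object (may be an
#'   unvalidated bare list with the right names and class, so diagnostics can
#'   run on candidates that constructors would reject).
#' @return Character vector of human-readable diagnostics; empty iff valid.
#' @examples
#' validate_params(whole_blood_params(60, 8, 10, 20, 15, 30))
#' @export
validate_params <- function(params) {
  if (!inherits(params, c("plasma_params", "whole_blood_params")))
    stop("`params` must be plasma_params or whole_blood_params", call. = FALSE)
  out <- positivity_violations(params)
  if (inherits(params, "whole_blood_params") && !length(out)) {
    if (params$K_d2 < params$K_d1)
      out <- c(out, sprintf(
        "warning: K_d2 (%g) < K_d1 (%g): lysis onset precedes clot formation",
        params$K_d2, params$K_d1))
    if (params$K_n2 > params$K_n1)
      out <- c(out, sprintf(
        "warning: K_n2 (%g) > K_n1 (%g): lysis gain exceeds formation gain",
        params$K_n2, params$K_n1))
    # probe the un-clamped closed form for negative excursions
    probe_end <- params$K_d2 + 20 * max(params$K_p1, params$K_p2)
    tt <- seq(0, probe_end, length.out = 2001L)
    amp <- wb_closed_form(params, tt, area = 1)
    if (min(amp) < -1e-9)
      out <- c(out, sprintf(
        "warning: implied curve goes negative (min %.3g mm on probe grid)",
        min(amp)))
  }
  out
}

# un-clamped two-term closed form, area-scaled
wb_closed_form <- function(params, t, area) {
  area * (params$K_n1 * sat_exp(t, params$K_p1, params$K_d1) -
          params$K_n2 * sat_exp(t, params$K_p2, params$K_d2))
}

# f(t; K_p, K_d) = (1 - exp(-(t - K_d)/K_p)) * 1{t >= K_d}
sat_exp <- function(t, K_p, K_d) {
  s <- pmax(t - K_d, 0)
  1 - exp(-s / K_p)
}

#' @export
print.plasma_params <- function(x, ...) {
  cat(sprintf("Plasma model: K_np = %.4g mm/area, K_p = %.4g min, K_dp = %.4g min\n",
              x$K_np, x$K_p, x$K_dp))
  invisible(x)
}

#' @export
print.whole_blood_params <- function(x, ...) {
  cat(sprintf(paste0(
    "Whole-blood model:\n",
    "  formation: K_n1 = %.4g, K_p1 = %.4g min, K_d1 = %.4g min\n",
    "  lysis:     K_n2 = %.4g, K_p2 = %.4g min, K_d2 = %.4g min\n"),
    x$K_n1, x$K_p1, x$K_d1, x$K_n2, x$K_p2, x$K_d2))
  invisible(x)
}
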