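#' Single Maxwell element
#'
#' A spring (Young's modulus `E`) and damper (viscosity `eta`) in series,
#' with relaxation time `tau = eta / E`. Provide any two of `E`, `eta`,
#' `tau`; `sigma0` (asymptotic stress) and `epsilon0` (reference strain) are
#' optional, with the consistency requirement `E = sigma0 / epsilon0` when
#' both are given.
#'
#' @param E Elastic modulus, stress units (> 0).
#' @param eta Viscosity, stress x time (> 0).
#' @param tau Relaxation time, time units (> 0); defaults to `eta / E`.
#' @param sigma0 Asymptotic stress (optional; defaults to `E * epsilon0` or
#'   `E`).
#' @param epsilon0 Reference strain (optional, default 1).
#' @return An object of class `maxwell_element`.
#' @examples
#' maxwell_element(E = 10, eta = 80)  # tau = 8
#' @export
maxwell_element <- function(E = NULL, eta = NULL, tau = NULL,
                            sigma0 = NULL, epsilon0 = 1) {
  n_given <- sum(!vapply(list(E, eta, tau), is.null, logical(1)))
  if (n_given < 2L)
    stop("provide at least two of E, eta, tau", call. = FALSE)
  if (is.null(tau)) tau <- eta / E
  if (is.null(E)) E <- eta / tau
  if (is.null(eta)) eta <- E * tau
  if (E <= 0 || eta <= 0 || tau <= 0)
    stop("E, eta, tau must be strictly positive", call. = FALSE)
  if (abs(tau - eta / E) > 1e-12 * tau)
    stop(sprintf("inconsistent inputs: tau = %g but eta/E = %g", tau, eta / E),
         call. = FALSE)
  if (is.null(sigma0)) sigma0 <- E * epsilon0
  if (abs(E - sigma0 / epsilon0) > 1e-9 * E)
    stop("sigma0 / epsilon0 must equal E", call. = FALSE)
  structure(list(E = E, eta = eta, tau = tau, sigma0 = sigma0,
                 epsilon0 = epsilon0),
            class = "maxwell_element")
}

#' Stress build-up of a Maxwell element
#'
#' Evaluates `sigma(t) = sigma0 * (1 - exp(-t / tau))`, the response of the
#' Maxwell material to a sustained driving force. This shares its functional
#' form with the delay-free plasma TEG model under the correspondence
#' `sigma0 <-> K_np`, `tau <-> K_p`, which is what gives the transfer-function
#' models their mechanistic viscoelastic interpretation.
#'
#' @param elem A [maxwell_element()].
#' @param t Times >= 0.
#' @return Stress values, monotone increasing and bounded by `sigma0`.
#' @export
relaxation_stress <- function(elem, t) {
  stopifnot(inherits(elem, "maxwell_element"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  elem$sigma0 * (1 - exp(-t / elem$tau))
}

#' Dimensionless dynamic moduli of a Maxwell element
#'
#' Storage and loss moduli as functions of the dimensionless frequency
#' `x = tau * omega`:
#' \deqn{E_1/E = x^2/(x^2+1), \quad E_2/E = x/(x^2+1),}
#' and the magnitude of the complex modulus
#' \eqn{|E^*|/E = \sqrt{(E_1/E)^2 + (E_2/E)^2}}. The storage modulus is
#' monotone increasing in `x`; the loss modulus peaks at exactly 0.5 at
#' `x = 1`.
#'
#' @param tau_omega Dimensionless frequency grid, values >= 0.
#' @return A data.frame of class `maxwell_spectrum` with columns
#'   `tau_omega`, `e1_over_e`, `e2_over_e`, `magnitude_over_e`.
#' @examples
#' dynamic_moduli(c(0, 1, 1e6))
#' @export
dynamic_moduli <- function(tau_omega) {
  if (any(!is.finite(tau_omega)) || any(tau_omega < 0))
    stop("tau_omega must be finite and >= 0", call. = FALSE)
  x <- as.numeric(tau_omega)
  e1 <- x^2 / (x^2 + 1)
  e2 <- x / (x^2 + 1)
  out <- data.frame(tau_omega = x, e1_over_e = e1, e2_over_e = e2,
                    magnitude_over_e = sqrt(e1^2 + e2^2))
  class(out) <- c("maxwell_spectrum", "data.frame")
  out
}

#' Interpret a whole-blood clot through the Maxwell lens
#'
#' Qualitative decomposition of clot strength into a storage-like channel
#' (fibrin mesh / secondary hemostasis, predicted by the plasma model), a
#' loss-like channel (platelet plug / primary hemostasis, the share of
#' whole-blood MA attributable to platelet amplification) and the magnitude
#' (whole-blood MA). The association of platelets with the loss modulus and
#' fibrin with the storage modulus is interpretive; the only numeric content
#' is the share identities below.
#'
#' @param params A [whole_blood_params()] object.
#' @param fibrin_params A [plasma_params()] object describing the fibrin-only
#'   (platelet-inhibited) clot.
#' @param tf A [tf_impulse()] driving the whole-blood model.
#' @param fibrin_area Input area scaling the fibrin model's MA (default 1).
#' @param horizon Simulation horizon, minutes.
#' @return List with `tau` (the formation time constant `K_p1`),
#'   `magnitude_ma` (whole-blood MA, mm), `storage_ma` (fibrin MA, mm),
#'   `platelet_gain` (`magnitude_ma / storage_ma`), `loss_share`
#'   (`1 - 1/gain`, the platelet fraction of whole-blood MA) and a `note`
#'   marking the output as interpretive.
#' @export
interpret_clot <- function(params, fibrin_params, tf = tf_impulse(),
                           fibrin_area = 1, horizon = 90) {
  stopifnot(inherits(params, "whole_blood_params"),
            inherits(fibrin_params, "plasma_params"))
  grid <- teg_grid(horizon)
  wb_ma <- extract_ma_ly30(whole_blood_curve(params, grid, tf))$MA
  fib_ma <- fibrin_area * fibrin_params$K_np  # supremum of the fibrin curve
  gain <- if (fib_ma > 0) wb_ma / fib_ma else NA_real_
  loss_share <- if (is.na(gain) || gain <= 0) NA_real_ else max(0, 1 - 1 / gain)
  list(tau = params$K_p1,
       magnitude_ma = wb_ma,
       storage_ma = fib_ma,
       platelet_gain = gain,
       loss_share = loss_share,
       note = paste("interpretive mapping: storage ~ fibrin/secondary",
                    "hemostasis, loss ~ platelet/primary hemostasis,",
                    "magnitude ~ whole blood"))
}
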