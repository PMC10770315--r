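#' Assay-conversion relations
#'
#' Configuration of the linear relations that connect TEG assay variants:
#' fibrin-only (Functional Fibrinogen, FF), whole blood (Citrated Native,
#' CN), Platelet Mapping (PLT) and Rapid TEG. Most slopes are calibration
#' values fitted on a user's own data (e.g. with [fit_line()]); the shipped
#' numbers are illustrative defaults and are flagged as such. Two defaults
#' are literature-stated: the Rapid-TEG R time is approximately a constant
#' 1.107 min regardless of the CN R time, and Rapid-TEG Ly30 maps
#' one-to-one to CN Ly30.
#'
#' @param flev_slope Machine-reported fibrinogen level (FLEV, mg/dL) per
#'   unit shear elasticity G_f (dynes/cm^2).
#' @param fibrinogen_slope Laboratory fibrinogen (mg/dL) per unit G_f.
#' @param plt_gain_slope Clot-strength amplification (MA_CN/MA_FF) per
#'   uninhibited platelet unit (10^3/uL), linear mode.
#' @param plt_gain_constant Amplification used in mid-range constant mode
#'   (platelet counts roughly 50-150).
#' @param ff_to_plt_slope MA_PLT per MA_FF (through-origin).
#' @param rapid_ma_slope,rapid_ma_intercept Rapid MA from CN MA.
#' @param rapid_alpha_slope,rapid_alpha_intercept Rapid alpha from CN alpha.
#' @param rapid_r_constant Rapid-TEG R time, minutes (default 1.107).
#' @param rapid_ly30_slope Rapid Ly30 per CN Ly30 (default 1, identity).
#' @return An object of class `assay_relations`; the `illustrative` field
#'   names the entries that are placeholders pending calibration.
#' @export
assay_relations <- function(flev_slope = 0.25,
                            fibrinogen_slope = 0.15,
                            plt_gain_slope = 0.02,
                            plt_gain_constant = 2.0,
                            ff_to_plt_slope = 2.0,
                            rapid_ma_slope = 1.0, rapid_ma_intercept = 2.0,
                            rapid_alpha_slope = 1.1,
                            rapid_alpha_intercept = 0.0,
                            rapid_r_constant = 1.107,
                            rapid_ly30_slope = 1.0) {
  slopes <- c(flev_slope = flev_slope, fibrinogen_slope = fibrinogen_slope,
              plt_gain_slope = plt_gain_slope,
              plt_gain_constant = plt_gain_constant,
              ff_to_plt_slope = ff_to_plt_slope,
              rapid_ma_slope = rapid_ma_slope,
              rapid_alpha_slope = rapid_alpha_slope,
              rapid_ly30_slope = rapid_ly30_slope)
  if (any(slopes < 0))
    stop("all slopes must be >= 0", call. = FALSE)
  if (rapid_r_constant <= 0)
    stop("rapid_r_constant must be positive", call. = FALSE)
  structure(list(flev_slope = flev_slope,
                 fibrinogen_slope = fibrinogen_slope,
                 plt_gain_slope = plt_gain_slope,
                 plt_gain_constant = plt_gain_constant,
                 ff_to_plt_slope = ff_to_plt_slope,
                 rapid_ma_slope = rapid_ma_slope,
                 rapid_ma_intercept = rapid_ma_intercept,
                 rapid_alpha_slope = rapid_alpha_slope,
                 rapid_alpha_intercept = rapid_alpha_intercept,
                 rapid_r_constant = rapid_r_constant,
                 rapid_ly30_slope = rapid_ly30_slope,
                 illustrative = c("flev_slope", "fibrinogen_slope",
                                  "plt_gain_slope", "plt_gain_constant",
                                  "ff_to_plt_slope", "rapid_ma_slope",
                                  "rapid_ma_intercept", "rapid_alpha_slope",
                                  "rapid_alpha_intercept")),
            class = "assay_relations")
}

#' Platelet clot-strength amplification factor
#'
#' The ratio MA_CN / MA_FF by which platelets amplify fibrin clot strength.
#' It is driven by the number of platelets left uninhibited by ADP,
#' `platelet_count * (1 - adp_inhibition/100)`. In `"linear"` mode the gain
#' is `plt_gain_slope * uninhibited`, floored at 1 with a warning
#' (whole-blood MA cannot fall below fibrin MA); in `"constant"` mode the
#' configured mid-range constant is returned regardless of count (valid for
#' platelet counts roughly 50-150).
#'
#' @param platelet_count Platelet count, 10^3/uL (>= 0).
#' @param adp_inhibition Percent ADP inhibition in \[0, 100\].
#' @param relations An [assay_relations()] configuration.
#' @param mode `"linear"` or `"constant"`.
#' @return Amplification factor >= 1.
#' @export
platelet_gain <- function(platelet_count, adp_inhibition,
                          relations = assay_relations(),
                          mode = c("linear", "constant")) {
  mode <- match.arg(mode)
  if (platelet_count < 0) stop("platelet_count must be >= 0", call. = FALSE)
  if (adp_inhibition < 0 || adp_inhibition > 100)
    stop("adp_inhibition must be in [0, 100]", call. = FALSE)
  if (mode == "constant") return(relations$plt_gain_constant)
  uninhibited <- platelet_count * (1 - adp_inhibition / 100)
  gain <- relations$plt_gain_slope * uninhibited
  if (gain < 1) {
    warning(sprintf(
      "raw platelet gain %.3g < 1; floored at 1 (whole-blood MA >= fibrin MA)",
      gain), call. = FALSE)
    gain <- 1
  }
  gain
}

#' Percent MA reduction by platelet inhibition
#'
#' `100 * (MA_CN - MA_FF) / MA_CN`, the share of whole-blood clot strength
#' contributed by platelets.
#'
#' @param MA_CN Whole-blood (CN) maximum amplitude, mm, > 0.
#' @param MA_FF Fibrin-only (FF) maximum amplitude, mm. Normally
#'   `<= MA_CN`; a violation warns (measurement noise can invert the pair)
#'   but still computes.
#' @return Percent reduction.
#' @export
ma_reduction <- function(MA_CN, MA_FF) {
  if (MA_CN <= 0) stop("MA_CN must be > 0", call. = FALSE)
  if (MA_FF < 0 || MA_FF > MA_CN)
    warning("MA_FF outside [0, MA_CN]; computing anyway", call. = FALSE)
  100 * (MA_CN - MA_FF) / MA_CN
}

#' Convert Citrated Native TEG parameters to Rapid TEG
#'
#' Rapid TEG triggers coagulation with a high tissue-factor dose, so MA and
#' alpha scale affinely from their CN counterparts, R time collapses to a
#' constant (default 1.107 min) independent of the CN value, and Ly30 maps
#' linearly (identity by default, since tissue factor does not act on
#' fibrinolysis). Undefined CN fields propagate as undefined.
#'
#' @param cn A [teg_scalar_params()] from the CN assay; `MA`, `alpha` and
#'   `Ly30` should be defined (R is optional and unused).
#' @param relations An [assay_relations()] configuration.
#' @return A `teg_scalar_params` for the Rapid assay (K and t_MA are not
#'   mapped and are returned undefined).
#' @export
cn_to_rapid <- function(cn, relations = assay_relations()) {
  stopifnot(inherits(cn, "teg_scalar_params"))
  reasons <- list(K = "not mapped by the CN-to-Rapid relations",
                  t_MA = "not mapped by the CN-to-Rapid relations")
  ma <- if (is.na(cn$MA)) NA_real_
        else relations$rapid_ma_slope * cn$MA + relations$rapid_ma_intercept
  if (is.na(ma)) reasons$MA <- "CN MA undefined"
  alpha <- if (is.na(cn$alpha)) NA_real_
           else min(relations$rapid_alpha_slope * cn$alpha +
                    relations$rapid_alpha_intercept, 89.999)
  if (is.na(alpha)) reasons$alpha <- "CN alpha undefined"
  ly30 <- if (is.na(cn$Ly30)) NA_real_
          else min(max(relations$rapid_ly30_slope * cn$Ly30, 0), 100)
  if (is.na(ly30)) reasons$Ly30 <- "CN Ly30 undefined"
  teg_scalar_params(R = relations$rapid_r_constant, K = NA_real_,
                    alpha = alpha, MA = ma, t_MA = NA_real_, Ly30 = ly30,
                    reasons = reasons)
}

#' Functional fibrinogen level from fibrin MA
#'
#' Composes the shear-elasticity transform with a configured linear slope:
#' `FLEV = flev_slope * G_f(MA_FF)`. Strictly increasing in MA_FF for a
#' positive slope. Use `relations$fibrinogen_slope` in place of
#' `flev_slope` (argument `what = "fibrinogen"`) for laboratory-measured
#' fibrinogen rather than the machine-reported level.
#'
#' @param MA_FF Fibrin (FF-assay) maximum amplitude, mm, `0 <= MA_FF < 100`.
#' @param relations An [assay_relations()] configuration.
#' @param what `"flev"` (machine-reported level) or `"fibrinogen"`
#'   (laboratory concentration).
#' @return Estimated level, mg/dL-equivalent.
#' @export
flev_from_ma <- function(MA_FF, relations = assay_relations(),
                         what = c("flev", "fibrinogen")) {
  what <- match.arg(what)
  slope <- if (what == "flev") relations$flev_slope
           else relations$fibrinogen_slope
  slope * shear_elasticity(MA_FF)
}
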