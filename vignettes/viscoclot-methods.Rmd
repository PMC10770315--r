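---
title: "Control-oriented viscoelastic models of clot strength: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-oriented viscoelastic models of clot strength: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscoclot)
```

## The models

Thromboelastography (TEG) records the strength of a forming blood clot as an
amplitude, in millimeters, over time. A full run takes on the order of an
hour, which is too slow to steer treatment in acute bleeding. `viscoclot`
implements phenomenological, control-oriented models that reduce a TEG trace
to a handful of interpretable parameters, so that a curve can be simulated in
milliseconds, fitted to data, and predicted from quickly measurable
coagulation-factor concentrations.

**Plasma (fibrin-only) model.** Clotting in platelet-poor plasma is treated
as a linear time-invariant system from thrombin generation $y(t)$ (the
Calibrated Automated Thrombogram readout, nM over minutes) to clot-strength
amplitude $p(t)$:

$$G(s) = \frac{P(s)}{Y(s)} = \frac{K_{np}}{s\,(K_p s + 1)}\,e^{-K_{dp} s}.$$

The integrator holds accumulated clot strength, the first-order lag sets the
formation kinetics, and the dead time shifts clot initiation. The impulse
response has the closed form
$a(t) = K_{np}\,(1 - e^{-(t - K_{dp})/K_p})$ for $t \ge K_{dp}$, zero
before. `K_np` (mm per unit input area) bounds the maximum amplitude, `K_p`
(min) is the formation time constant, `K_dp` (min) the initiation delay.
Linearity is a modeling assumption, adequate at the standard 5 pM
tissue-factor trigger; superposition and time invariance are asserted by the
test suite rather than taken on faith.

**Whole-blood model.** Whole blood adds platelet amplification and
fibrinolysis. Platelets are absorbed into the formation gain; lysis is a
second term of identical structure with a negative sign:

$$G(s) = \frac{K_{n1}}{s\,(K_{p1} s + 1)}\,e^{-K_{d1} s}
       - \frac{K_{n2}}{s\,(K_{p2} s + 1)}\,e^{-K_{d2} s},$$

driven by an impulsive tissue-factor input (default area 5, for the 5 pM
trigger; only the product of impulse area and gain is observable, so the
gains absorb unit conversions). `K_d1` is the time to initial clot
formation, `K_d2` the time to fibrinolysis onset. All six parameters are
constrained positive. Orderings such as `K_d2 >= K_d1` and `K_n2 <= K_n1`
are physically expected but not mathematically required, so
`validate_params()` reports violations as warnings (including a probe-grid
check for implied negative amplitudes) rather than refusing the object.

**Delay realization.** Delays are realized as exact time shifts of the
closed forms, never as rational (Pade) approximations: the closed forms
exist, are cheap, and are bit-reproducible. Frequency-domain reasoning
appears only in documentation; independent delayed-ODE integrations serve
as oracles in the tests.

## Simulation

Impulse-driven curves evaluate the closed form directly. For an arbitrary
thrombin input the response is computed by delaying the input by `K_dp`
(linear interpolation), convolving with the delay-free kernel by the
trapezoid rule on an internal uniform grid (default step 1/96 min, FFT
accelerated), and interpolating onto the requested grid; against a
stiff-tolerance delayed-ODE integration this path agrees to about `1e-7`
relative. The default output grid is `teg_grid(horizon = 90, dt = 1/12)` —
5-second sampling, matching common instrument cadence.

Negative amplitudes cannot occur physically; tiny negative numerical
residue (below `1e-9` of scale) is clamped silently, anything larger
triggers a model-validity warning before clamping, so fitting objectives
remain smooth while reported curves honor non-negativity. Traces are
modeled single-sided; the instrument's mirrored display is presentation
only.

## Scalar TEG parameters

* `R`: first crossing of 2 mm, by linear interpolation between samples.
* `K`: time from `R` to the 20 mm crossing. Either is undefined (with a
  recorded reason) when the threshold is never reached.
* `alpha`: there is no universally fixed formula, only the convention that
  it proxies the initial slope. The default here is
  $\alpha = \arctan(\max_t \Delta a/\Delta t)$ in degrees, which on
  model-generated curves equals $\arctan(\text{area}\cdot K_{n1}/K_{p1})$
  at clot initiation and is monotone in curve steepness (hence strictly
  decreasing in `K_p1`). The clinical secant convention (chord from the
  2 mm to the 20 mm point) is available via `method = "secant"`.
* `MA` and `t_MA`: the maximum amplitude and the earliest time attaining it
  within `1e-9` mm; ties break toward earlier times.
* `Ly30`: amplitude-based percent lysis,
  $100\,(MA - a(t_{MA}+30))/MA$, clamped to $[0, 100]$. When the record
  ends less than 30 min after `t_MA` there are two cases: a trace still at
  its maximum shows no lysis at all and reports `Ly30 = 0`; a trace caught
  mid-decay reports `Ly30` undefined, because the 30-minute mark lies
  beyond the data. The model-side lysis index `auc_reduction()` — the
  analytic area ratio of the lysis term to the formation term — is exposed
  separately, since instruments and models can disagree on whether lysis is
  an amplitude or an area quantity; both views are provided.
* `G_f = 5000 \cdot MA/(100 - MA)` (dynes/cm^2) is the standard shear
  elasticity transform, with `ma_from_shear_elasticity()` as its exact
  inverse.

## Fitting

`fit_plasma()` and `fit_whole_blood()` minimize unweighted squared error
under positivity bounds (`[1e-6, 1e4]` in model units — wide enough never
to constrain a realistic fit) with solver tolerance `1e-9`. Parameters are
optimized in log-space by bounded Levenberg–Marquardt (`minpack.lm::nls.lm`),
which makes positivity automatic and steps naturally multiplicative.

Initial guesses are data-driven: the delay from the first 2 mm (or
2 %-of-max) crossing, the gain from the maximum amplitude over the input
area, the time constant from the 63 %-of-max rise time, and the lysis term
from post-peak decay magnitude and onset. Seeded log-uniform random
restarts (8 total starts by default) guard against local minima, and the
best-RSS start wins; best-of-N is never worse than a single start.

The six-parameter model needs one extra device. When formation and lysis
overlap, the visible post-peak drop can understate the lysis gain by an
order of magnitude — a near-monotone curve can hide a large lysis term that
only trims the apparent gain — and the objective develops a narrow basin in
`K_d2`. The fitter therefore runs a variable-projection pre-search: candidate
lysis onsets are scanned (4-minute spacing, crossed with a few kinetic
starting pairs), with both gains profiled out by linear least squares at
every step, and the best few candidates seed the full six-parameter polish.
On noiseless model-generated curves this recovers all six parameters to
numerical precision across the tested parameter ranges; on curves with no
decay inside the horizon the lysis term is reported as weakly identified.

`aic_model_order()` compares candidate impulse-response structures — a
delayed ramp (2 parameters), the integrator-plus-lag model (3), and a
two-pole variant (4) — by the least-squares form
$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2k$, sorted ascending with ties
broken toward fewer parameters and an exact-zero RSS reported as
$-\infty$. On noisy data generated by the 3-parameter structure it selects
that structure in the large majority of replicates, which is the expected
behavior of AIC with one superfluous parameter.

## Sparse maps from factor panels

Factor panels carry activities of factors II, V, VII, VIII, IX, X, ATIII
and protein C (percent of normal), fibrinogen (mg/dL), platelet count
(10^3/uL), percent ADP inhibition, and D-dimer (ug/mL). Each model
parameter may only draw on a registered feature subset: the seven factors
for the plasma parameters; plus PC for the whole-blood formation kinetics;
plus fibrinogen and platelets for the formation gain (so it reflects both
primary and secondary hemostasis); plus D-dimer for the lysis term. The
registry is enforced at training time, not advisory.

Estimation uses orthogonal matching pursuit: greedy atom selection on
z-scored features with full least-squares re-solution at each step. OMP is
deterministic, exact on orthogonal designs, and equivalent to best-subset
search at the small sparsities used here, which the tests verify by
exhaustive enumeration. Features are standardized with training-fold
statistics so that atom selection is not driven by units; targets stay on
their natural scale. With `sparsity = "auto"` the support size minimizes
the leave-one-out error (computed exactly via the hat matrix) along the
greedy path, ties toward the smaller support. Missing panel fields are a
hard error — silent imputation could corrupt a clinical prediction.

`crossvalidate()` reproduces the standard fivefold protocol: maps trained
on four folds, held-out parameters predicted, curves simulated from them,
and the scalar TEG properties compared with those of the reference curves
(simulated from each sample's own fitted parameters), reported as mean
percent error per property per fold plus an overall row. On noiseless
model-consistent cohorts the pipeline must and does reach the optimizer
noise floor; noisy cohorts are refitted per sample so that measurement
noise actually propagates into the maps. Percent errors are skipped (NA)
for properties whose reference value is zero or undefined — plasma curves,
for instance, have no lysis to misestimate.

`fit_line()` provides the outlier-aware correlation utility used around
the models: OLS, optionally through the origin, with either an externally
studentized residual rule (default threshold 3; a non-finite
studentization, which arises when deleting the point leaves a perfect fit,
counts as a gross outlier) or an explicit index list for reproducing
published exclusions.

## Assay bridge

The four common TEG variants are connected by low-dimensional relations:

* Platelet amplification: whole-blood over fibrin MA, driven by the
  uninhibited platelet count `platelet_count * (1 - adp_inhibition/100)`.
  Linear mode multiplies a configured slope (floored at gain 1, since
  whole-blood MA cannot fall below fibrin MA); constant mode covers the
  mid-range plateau (counts of roughly 50-150) with a single gain.
* `ma_reduction()` is the complementary percent reduction
  `100 (MA_CN - MA_FF)/MA_CN`; gain and reduction compose exactly as
  `100 (1 - 1/gain)`.
* Citrated Native to Rapid TEG: affine maps for MA and alpha (alpha clamped
  below 90 degrees), a constant R time of 1.107 min — Rapid-TEG R times are
  reported to be nearly constant regardless of the native R time, and the
  shipped default carries that value with units of minutes implied by the
  R-time axis — and a one-to-one default for Ly30, since tissue factor does
  not act on fibrinolysis.
* `flev_from_ma()` composes the shear-elasticity transform with a
  configured slope to estimate machine-reported (FLEV) or
  laboratory-measured fibrinogen.

Most slopes in `assay_relations()` are calibration values: they come from
lines fitted on scatter data whose coefficients are instrument- and
cohort-specific, so the defaults are explicitly flagged `illustrative` and
a calibration path via `fit_line()` on the user's own data is the intended
use. Only the Rapid R constant and the Ly30 identity ship as
literature-grade defaults. The near one-to-one relation between CN and PLT
MA values is treated as identity rather than given its own operation.

## The Maxwell correspondence

A single Maxwell element (spring `E` and damper `eta` in series,
relaxation time `tau = eta/E`) builds stress as
$\sigma(t) = \sigma_0 (1 - e^{-t/\tau})$ — exactly the delay-free plasma
response under $\sigma_0 \leftrightarrow K_{np}$,
$\tau \leftrightarrow K_p$. This gives the phenomenological models a
mechanistic reading. The dimensionless dynamic moduli over
$x = \tau\omega$,

$$E_1/E = \frac{x^2}{x^2+1}, \qquad E_2/E = \frac{x}{x^2+1},$$

satisfy $E_1 + i E_2 \propto ix/(1+ix)$, with the loss modulus peaking at
exactly 0.5 at $x = 1$. `interpret_clot()` maps the storage channel to the
fibrin mesh (secondary hemostasis, the plasma-model MA), the loss channel
to the platelet plug (primary hemostasis, the share $1 - 1/\text{gain}$ of
whole-blood MA), and the modulus magnitude to whole-blood clot strength.
This association is a hypothesis, and the function labels its output as
interpretive; its only numeric content is those share identities. Only the
single-element model is implemented — multi-element Maxwell–Wiechert
superposition is out of scope, and the magnitude curve is reported as
$|E^*|/E$ without additional scaling.

## The synthetic cohort generator

Every module is testable without clinical data through seeded synthetic
cohorts, which emulate the *structure* of real panel-plus-TEG datasets, not
any particular cohort's marginals.

* **Panels.** Normal population: factor activities from a truncated normal
  centered at 100 % with about 95 % of mass inside the clinical normal
  range 60–140 % (sd 20.4, truncated at zero), exchangeable inter-factor
  correlation 0.3 through a shared latent factor; fibrinogen 300 ± 60
  mg/dL, platelets 250 ± 60 × 10^3/uL, ADP inhibition 20 ± 15 % (truncated
  to [0, 100]), D-dimer log-normal around 0.4 ug/mL. Trauma population:
  factors shifted down and widened (70 ± 25), fibrinogen reduced, platelet
  counts spanning 0–350, heavier ADP inhibition, and D-dimer elevated
  about an order of magnitude — values a trauma service would recognize as
  plausible admission chemistry, chosen once and not tuned.
* **Ground-truth maps** respect the feature registry, draw random sparse
  supports, and scale coefficients (4–8 % of the parameter's intercept per
  z-unit, with the lysis gain's D-dimer loading deliberately dominant) so
  parameters stay positive across both populations under a fixed, recorded
  standardization. Two links are wired in deterministically because they
  reflect known biology: the plasma and whole-blood gains load negatively
  on ATIII (the anticoagulant lowers attainable firmness), and the lysis
  gain loads positively on D-dimer (the degradation product marks active
  fibrinolysis). Whole-blood parameter intercepts (gain 12 under the
  area-5 impulse, formation 6/8 min, lysis 0.5/30/35 min) put MA near
  60 mm with a few percent Ly30 for normal panels — typical healthy values.
* **Thrombin surrogate.** `synth_thrombin()` is a parametric stand-in of
  this package's own design, not a mechanistic thrombin-generation model: a
  lagged difference of exponentials whose amplitude scales with prothrombin
  and whose decay shortens with ATIII, so the endogenous thrombin potential
  moves in the directions hemostasis predicts. Peak near 150 nM and area
  near 1800 nM·min at normal factor levels. Only these qualitative
  directions are biologically grounded; the functional form is a
  documented convenience.
* **Noise.** Additive Gaussian amplitude noise, truncated so amplitudes
  stay non-negative, homoscedastic by default with a proportional option;
  the realized noise vector is stored so every stored curve equals its
  model curve plus its recorded noise exactly, and the whole cohort is
  bit-reproducible from its seed.

What passing tests on such cohorts shows: the estimation machinery is
consistent — exact model recovery at zero noise, graceful degradation with
noise, exact support recovery where theory predicts it. What it does not
show: performance on real blood, where the model is only an approximation,
noise is structured, panels are incomplete, and the panel-to-parameter
relations are not exactly sparse-linear.

## Numerical choices and problem sizes

Defaults: output grid 1/12 min over 90 min; internal convolution step
1/96 min; solver tolerances 1e-9; parameter bounds [1e-6, 1e4]; 8 fit
starts; positivity floor 1e-6 on predicted parameters; fivefold CV. The
test suite exercises 50-set parameter-recovery sweeps, 100-curve
feature-extraction sweeps against 0.001-min brute-force grids, 100-seed
support-recovery runs at 20 dB SNR, and cohorts of 20-100 samples — sizes
chosen to pin the numerics tightly while keeping a full run in a few
minutes on one core.

## Known limitations

* The models are linear and time-invariant by construction; strongly
  nonlinear or time-varying coagulation dynamics (massive transfusion mid-
  run, hyperfibrinolysis with shutdown) are outside their regime.
* Whole-blood fits with no observable decay cannot identify the lysis
  term; they are flagged, not guessed.
* The assay-bridge slopes are placeholders until calibrated; predictions
  made with `illustrative` defaults are for pipeline exercise, not
  clinical use.
* `crossvalidate()` reports percent errors, which are undefined for
  zero-valued references; those cells are NA by design.
* The thrombin surrogate is qualitative; CAT-replacement modeling is a
  non-goal here.
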