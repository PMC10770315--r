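#' Sample synthetic coagulation-factor panels
#'
#' Draws factor panels with the statistical structure the pipeline assumes.
#' The `"normal"` population draws percent activities from a truncated
#' normal centered at 100 with about 95\% of its mass inside the clinical
#' normal range of 60-140\% activity, with mild exchangeable inter-factor
#' correlation (default 0.3). The `"trauma"` population is shifted and
#' widened: lower factor activities, reduced fibrinogen, a platelet range
#' spanning 0-350 x 10^3/uL, heavier ADP inhibition, and elevated D-dimer.
#' All values are non-negative.
#'
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; same seed and arguments reproduce the table
#'   bit-identically.
#' @param population `"normal"` or `"trauma"`.
#' @param rho Exchangeable correlation among the eight factor activities.
#' @return Data.frame with the columns of [factor_panel_columns()].
#' @export
sample_factor_panels <- function(n, seed = 1L, population = c("normal", "trauma"),
                                 rho = 0.3) {
  population <- match.arg(population)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  facs <- c("FII", "FV", "FVII", "FVIII", "FIX", "FX", "ATIII", "PC")
  if (population == "normal") {
    mu_f <- 100; sd_f <- 20.4  # ~95% mass in [60, 140]
    fib_mu <- 300; fib_sd <- 60
    plt_mu <- 250; plt_sd <- 60; plt_max <- Inf
    adp_mu <- 20; adp_sd <- 15
    dd_meanlog <- log(0.4); dd_sdlog <- 0.5
  } else {
    mu_f <- 70; sd_f <- 25
    fib_mu <- 200; fib_sd <- 70
    plt_mu <- 150; plt_sd <- 80; plt_max <- 350
    adp_mu <- 40; adp_sd <- 20
    dd_meanlog <- log(3); dd_sdlog <- 0.5
  }
  # exchangeable correlation through a shared latent factor
  z0 <- stats::rnorm(n)
  Z <- sqrt(rho) * z0 + sqrt(1 - rho) *
    matrix(stats::rnorm(n * length(facs)), n)
  panel <- as.data.frame(pmax(mu_f + sd_f * Z, 0))
  names(panel) <- facs
  panel$fibrinogen <- pmax(stats::rnorm(n, fib_mu, fib_sd), 0)
  panel$platelet_count <- pmin(pmax(stats::rnorm(n, plt_mu, plt_sd), 0),
                               plt_max)
  panel$adp_inhibition <- pmin(pmax(stats::rnorm(n, adp_mu, adp_sd), 0), 100)
  panel$d_dimer <- stats::rlnorm(n, dd_meanlog, dd_sdlog)
  panel
}

# fixed standardization used by ground-truth maps: chosen to span both
# populations so that z-scores stay moderate for either
truth_standardization <- function() {
  list(mean = c(FII = 85, FV = 85, FVII = 85, FVIII = 85, FIX = 85, FX = 85,
                ATIII = 85, PC = 85, fibrinogen = 250, platelet_count = 200,
                adp_inhibition = 30, d_dimer = 1),
       scale = c(FII = 25, FV = 25, FVII = 25, FVIII = 25, FIX = 25, FX = 25,
                 ATIII = 25, PC = 25, fibrinogen = 70, platelet_count = 80,
                 adp_inhibition = 20, d_dimer = 2))
}

# nominal parameter intercepts per model; whole-blood values assume the
# 5 pM TF impulse so that MA lands near 60 mm
truth_intercepts <- function(model) {
  if (model == "plasma")
    c(K_np = 0.0125, K_p = 6, K_dp = 8)
  else
    c(K_n1 = 12, K_p1 = 6, K_d1 = 8, K_n2 = 0.5, K_p2 = 30, K_d2 = 35)
}

make_truth_map <- function(target, support_names, coefs, intercept) {
  std <- truth_standardization()
  feats <- factor_feature_registry()[[target]]
  structure(list(target = target, feature_names = feats,
                 support = match(support_names, feats),
                 coefficients = coefs, intercept = intercept,
                 standardization = list(mean = std$mean[feats],
                                        scale = std$scale[feats])),
            class = "sparse_linear_map")
}

#' Construct ground-truth sparse maps for a synthetic cohort
#'
#' For each parameter of the chosen model, draws a `sparsity`-sized support
#' from its registered feature set and coefficients scaled so that generated
#' parameters stay positive over the panel distribution. Two dependencies
#' are built in deterministically: the plasma gain `K_np` (and the
#' whole-blood formation gain `K_n1`) always loads negatively on `ATIII`
#' (the anticoagulant lowers attainable clot firmness), and the lysis gain
#' `K_n2` always loads positively on `d_dimer` (the fibrin degradation
#' product marks active fibrinolysis).
#'
#' @param seed Integer seed.
#' @param sparsity Support size per parameter (0 allowed: intercept-only
#'   maps, with a warning).
#' @param model `"plasma"` or `"whole_blood"`.
#' @return Named list of `sparse_linear_map`s, one per model parameter.
#' @export
make_true_maps <- function(seed = 1L, sparsity = 3L,
                           model = c("whole_blood", "plasma")) {
  model <- match.arg(model)
  reg <- factor_feature_registry()
  ints <- truth_intercepts(model)
  sparsity <- as.integer(sparsity)
  if (sparsity < 0L) stop("sparsity must be >= 0", call. = FALSE)
  min_set <- min(lengths(reg[names(ints)]))
  if (sparsity > min_set)
    stop(sprintf("sparsity %d exceeds smallest registered feature set (%d)",
                 sparsity, min_set), call. = FALSE)
  if (sparsity == 0L)
    warning("sparsity 0: intercept-only ground-truth maps", call. = FALSE)
  set.seed(as.integer(seed))
  forced <- list(K_np = c(feature = "ATIII", sign = -1),
                 K_n1 = c(feature = "ATIII", sign = -1),
                 K_n2 = c(feature = "d_dimer", sign = 1))
  maps <- lapply(names(ints), function(pn) {
    feats <- reg[[pn]]
    b0 <- ints[[pn]]
    sup <- character(0)
    if (sparsity > 0L && pn %in% names(forced))
      sup <- forced[[pn]][["feature"]]
    extra <- sample(setdiff(feats, sup), sparsity - length(sup))
    sup <- c(sup, extra)
    if (!length(sup))
      return(make_truth_map(pn, character(0), numeric(0), b0))
    # coefficient budget keeps the parameter positive for |z| <= ~4
    mag <- stats::runif(length(sup), 0.04, 0.08) * b0
    sgn <- sample(c(-1, 1), length(sup), replace = TRUE)
    if (pn %in% names(forced))
      sgn[1L] <- as.numeric(forced[[pn]][["sign"]])
    if (pn == "K_n2") mag[1L] <- 0.45 * b0  # lysis gain driven hard by D-dimer
    make_truth_map(pn, sup, mag * sgn, b0)
  })
  names(maps) <- names(ints)
  maps
}

#' Synthetic thrombin-generation curve from a panel row
#'
#' A documented parametric surrogate for a CAT thrombin trace: a lagged
#' difference of exponentials
#' `c * (exp(-(t - lag)/tau_dec) - exp(-(t - lag)/tau_rise))` for
#' `t >= lag`. The amplitude scales with prothrombin (FII, more substrate
#' gives more thrombin) and the decay time shortens with ATIII (the
#' anticoagulant clears thrombin faster), so the endogenous thrombin
#' potential (curve area) decreases in ATIII and increases in FII. The
#' trace is non-negative and extends until it has decayed well below 1\% of
#' its peak. Generator constants are attached as the `"generator"`
#' attribute.
#'
#' @param panel One panel row with `FII` and `ATIII` present.
#' @param seed Integer seed for the mild lag jitter.
#' @param dt Sampling step, minutes.
#' @return A [thrombin_curve()].
#' @export
synth_thrombin <- function(panel, seed = 1L, dt = 0.25) {
  panel <- as.data.frame(panel)
  if (is.null(panel$FII) || is.null(panel$ATIII) ||
      is.na(panel$FII) || is.na(panel$ATIII))
    stop("panel must carry FII and ATIII", call. = FALSE)
  set.seed(as.integer(seed))
  lag <- max(stats::rnorm(1, 2, 0.3), 0.5)
  tau_rise <- 1.5
  tau_dec <- min(max(8 * 100 / max(panel$ATIII, 10), 2), 20)
  cc <- 271 * panel$FII / 100  # peak ~150 nM at FII = 100, tau_dec = 8
  horizon <- lag + 7 * tau_dec
  tt <- seq(0, horizon, by = dt)
  s <- pmax(tt - lag, 0)
  thr <- cc * (exp(-s / tau_dec) - exp(-s / tau_rise))
  thr[tt < lag] <- 0
  out <- thrombin_curve(tt, pmax(thr, 0))
  attr(out, "generator") <- list(lag = lag, tau_rise = tau_rise,
                                 tau_dec = tau_dec, c = cc)
  out
}

#' Generate a full seeded synthetic cohort
#'
#' Chains [sample_factor_panels()] -> [make_true_maps()] -> per-sample
#' parameters -> (for the plasma model, [synth_thrombin()] ->) curve
#' simulation -> additive Gaussian amplitude noise truncated so that
#' amplitudes stay non-negative. The realized noise is recorded, so each
#' stored curve equals its model curve plus its recorded noise exactly, and
#' regenerating with the same seed and configuration reproduces the cohort
#' bit-identically.
#'
#' @param n Cohort size (>= 1).
#' @param model `"plasma"` or `"whole_blood"`.
#' @param noise_sd Amplitude noise standard deviation, mm (>= 0).
#' @param seed Integer master seed (sub-seeds are derived from it).
#' @param population Passed to [sample_factor_panels()].
#' @param sparsity Passed to [make_true_maps()].
#' @param horizon,dt Simulation grid, minutes.
#' @param tf_area TF impulse area for the whole-blood model.
#' @param noise_model `"homoscedastic"` (default) or `"proportional"`
#'   (noise sd scales with amplitude/max amplitude).
#' @return An object of class `teg_cohort`: list with `panels`,
#'   `true_maps`, `true_params` (list of parameter objects),
#'   `thrombin_curves` (plasma only), `curves`, `noise` (list of realized
#'   noise vectors), `model`, `tf_area`, `noise_sd`, `seed` and
#'   `provenance` (the generation config).
#' @export
generate_cohort <- function(n, model = c("whole_blood", "plasma"),
                            noise_sd = 0.5, seed = 1L,
                            population = "normal", sparsity = 3L,
                            horizon = 90, dt = 1 / 12, tf_area = 5,
                            noise_model = c("homoscedastic", "proportional")) {
  model <- match.arg(model)
  noise_model <- match.arg(noise_model)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  seed <- as.integer(seed)

  panels <- sample_factor_panels(n, seed = seed, population = population)
  maps <- make_true_maps(seed = seed + 1L, sparsity = sparsity, model = model)
  true_params <- lapply(seq_len(n), function(i)
    suppressWarnings(predict_parameters(panels[i, , drop = FALSE], maps,
                                        model)))
  grid <- teg_grid(horizon, dt)
  thrombin_curves <- NULL
  clean <- vector("list", n)
  if (model == "plasma") {
    thrombin_curves <- lapply(seq_len(n), function(i)
      synth_thrombin(panels[i, , drop = FALSE], seed = seed + 100L + i))
    clean <- lapply(seq_len(n), function(i)
      plasma_response_to_thrombin(true_params[[i]], thrombin_curves[[i]],
                                  grid))
  } else {
    clean <- lapply(seq_len(n), function(i)
      suppressWarnings(whole_blood_curve(true_params[[i]], grid,
                                         tf_impulse(tf_area))))
  }
  set.seed(seed + 1000L)
  noise <- vector("list", n)
  curves <- vector("list", n)
  for (i in seq_len(n)) {
    amp <- clean[[i]]$amplitude
    if (noise_sd > 0) {
      sdv <- if (noise_model == "proportional")
        noise_sd * amp / max(max(amp), 1e-12) else noise_sd
      raw <- stats::rnorm(length(amp), 0, sdv)
      eff <- pmax(amp + raw, 0) - amp  # truncated so amplitude stays >= 0
    } else eff <- numeric(length(amp))
    noise[[i]] <- eff
    curves[[i]] <- teg_curve(grid, amp + eff)
  }
  structure(list(panels = panels, true_maps = maps, true_params = true_params,
                 thrombin_curves = thrombin_curves, curves = curves,
                 noise = noise, model = model, tf_area = tf_area,
                 noise_sd = noise_sd, seed = seed,
                 provenance = list(n = n, model = model, noise_sd = noise_sd,
                                   seed = seed, population = population,
                                   sparsity = sparsity, horizon = horizon,
                                   dt = dt, tf_area = tf_area,
                                   noise_model = noise_model)),
            class = "teg_cohort")
}

#' @export
print.teg_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TEG cohort: n = %d, model = %s, noise_sd = %g mm, seed = %d\n",
              nrow(x$panels), x$model, x$noise_sd, x$seed))
  invisible(x)
}
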