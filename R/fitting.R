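#' Fitting options
#'
#' Bundle of solver settings used by [fit_plasma()], [fit_whole_blood()] and
#' [aic_model_order()]. Parameters are optimized in log-space (positivity is
#' then automatic) by bounded Levenberg-Marquardt ([minpack.lm::nls.lm]) at
#' the stated tolerance, from a data-driven initial guess plus seeded
#' log-uniform random restarts; the best-RSS solution wins.
#'
#' @param tol Solver function/step tolerance (default 1e-9).
#' @param starts Total number of starts including the data-driven heuristic
#'   (default 8).
#' @param lower,upper Parameter bounds in model units (default 1e-6 and 1e4).
#' @param seed Seed for the random restarts.
#' @param maxiter Maximum solver iterations per start.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(tol = 1e-9, starts = 8L, lower = 1e-6, upper = 1e4,
                        seed = 1L, maxiter = 400L) {
  if (lower <= 0 || upper <= lower)
    stop("need 0 < lower < upper", call. = FALSE)
  if (starts < 1L) stop("`starts` must be >= 1", call. = FALSE)
  structure(list(tol = tol, starts = as.integer(starts), lower = lower,
                 upper = upper, seed = as.integer(seed),
                 maxiter = as.integer(maxiter)),
            class = "fit_options")
}

# bounded LM on log-parameters; returns list(theta, rss, converged)
lm_fit_once <- function(predict_fn, y, theta0, opts) {
  resid_fn <- function(lpar) predict_fn(exp(lpar)) - y
  fit <- try(minpack.lm::nls.lm(
    par = log(theta0), lower = rep(log(opts$lower), length(theta0)),
    upper = rep(log(opts$upper), length(theta0)), fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = opts$tol, ptol = opts$tol, gtol = 0,
      maxiter = opts$maxiter, maxfev = 100L * (length(theta0) + 1L) * 10L)),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(theta = theta0, rss = sum(resid_fn(log(theta0))^2),
                converged = FALSE))
  list(theta = exp(fit$par), rss = fit$deviance,
       converged = fit$info %in% 1:4)
}

# multi-start driver around a heuristic guess; `extra_starts` are structured
# alternatives tried before the random restarts
lm_fit_multistart <- function(predict_fn, y, theta0, opts,
                              extra_starts = list()) {
  clip <- function(th) pmin(pmax(th, opts$lower), opts$upper)
  theta0 <- clip(theta0)
  set.seed(opts$seed)
  # the heuristic and any structured alternatives always run; random
  # restarts fill the budget beyond them
  starts <- c(list(theta0), lapply(extra_starts, clip))
  while (length(starts) < opts$starts)
    starts[[length(starts) + 1L]] <- clip(
      theta0 * 10^stats::runif(length(theta0), -0.7, 0.7))
  best <- NULL
  for (s in starts) {
    res <- lm_fit_once(predict_fn, y, s, opts)
    if (is.null(best) || res$rss < best$rss) best <- res
  }
  best$n_starts_used <- length(starts)
  best
}

fit_result <- function(params, rss, y, converged, n_starts_used,
                       flags = character()) {
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  structure(list(params = params, rss = rss, r2 = r2, n_obs = length(y),
                 converged = converged, n_starts_used = n_starts_used,
                 flags = flags),
            class = "teg_fit")
}

#' @export
print.teg_fit <- function(x, ...) {
  cat(sprintf("Model fit: rss = %.4g, r2 = %.6g, n = %d, converged = %s (%d starts)\n",
              x$rss, x$r2, x$n_obs, x$converged, x$n_starts_used))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  print(x$params)
  invisible(x)
}

# input-area (ETP for a thrombin trace, impulse area for tf_impulse)
input_area <- function(input) {
  if (inherits(input, "tf_impulse")) return(input$area)
  sum(diff(input$time) * (utils::head(input$thrombin, -1) +
                          utils::tail(input$thrombin, -1)) / 2)
}

# predictor factory for the plasma model; theta = (K_np, K_p, K_dp)
plasma_predictor <- function(input, grid, dt = 1 / 48) {
  if (inherits(input, "tf_impulse")) {
    area <- input$area
    function(theta) area * theta[1L] * sat_exp(grid, theta[2L], theta[3L])
  } else {
    t_end <- max(grid)
    tt <- seq(0, t_end, by = dt)
    if (tt[length(tt)] < t_end) tt <- c(tt, t_end)
    function(theta) {
      yd <- curve_value_at(input, tt - theta[3L])
      h <- theta[1L] * (1 - exp(-tt / theta[2L]))
      stats::approx(tt, trapezoid_convolve(h, yd, dt), xout = grid,
                    rule = 2)$y
    }
  }
}

# data-driven heuristic start for the single-term model
plasma_start <- function(curve, area) {
  ma <- max(curve$amplitude)
  K_d0 <- first_crossing(curve, min(2, 0.1 * ma))
  if (is.na(K_d0) || K_d0 <= 0) K_d0 <- 1
  t63 <- first_crossing(curve, 0.632 * ma)
  K_p0 <- if (is.na(t63)) 5 else max(t63 - K_d0, 0.25)
  c(K_np = ma / max(area, 1e-12), K_p = K_p0, K_dp = K_d0)
}

#' Fit the plasma model to a TEG curve
#'
#' Estimates `(K_np, K_p, K_dp)` by minimizing the sum of squared
#' differences between the simulated and observed amplitude, with
#' positivity enforced through bounds, solver tolerance 1e-9, and
#' multi-start as configured in `opts`.
#'
#' @param curve Observed [teg_curve()].
#' @param input The model input: a [thrombin_curve()] or a [tf_impulse()]
#'   for an impulsive input.
#' @param opts A [fit_options()] bundle.
#' @return A `teg_fit` with a [plasma_params()] estimate, RSS, R-squared,
#'   convergence flag and number of starts used.
#' @examples
#' p <- plasma_params(60, 8, 10)
#' cv <- plasma_impulse_curve(p, teg_grid(60))
#' fit_plasma(cv, tf_impulse(1), fit_options(starts = 2))
#' @export
fit_plasma <- function(curve, input, opts = fit_options()) {
  stopifnot(inherits(curve, "teg_curve"),
            inherits(input, c("thrombin_curve", "tf_impulse")),
            inherits(opts, "fit_options"))
  y <- curve$amplitude
  if (!all(is.finite(y))) stop("non-finite amplitudes in `curve`", call. = FALSE)
  if (max(y) <= 0)
    return(fit_result(NULL, sum(y^2), y, converged = FALSE, 0L,
                      flags = "degenerate: curve is identically zero"))
  predict_fn <- plasma_predictor(input, curve$time)
  theta0 <- plasma_start(curve, input_area(input))
  best <- lm_fit_multistart(predict_fn, y, theta0, opts)
  fit_result(plasma_params(best$theta[1L], best$theta[2L], best$theta[3L]),
             best$rss, y, best$converged, best$n_starts_used)
}

#' Fit the whole-blood two-term model to a TEG curve
#'
#' Estimates the six parameters of the formation-minus-lysis model for an
#' impulsive tissue-factor input. When the observed curve shows no decay
#' within its horizon the lysis term carries no information; its parameters
#' are then flagged as weakly identified.
#'
#' @param curve Observed [teg_curve()]. A warning is raised when the curve
#'   does not extend past its maximum (lysis onset unidentifiable).
#' @param tf A [tf_impulse()].
#' @param opts A [fit_options()] bundle.
#' @return A `teg_fit` with a [whole_blood_params()] estimate.
#' @export
fit_whole_blood <- function(curve, tf = tf_impulse(), opts = fit_options()) {
  stopifnot(inherits(curve, "teg_curve"), inherits(tf, "tf_impulse"),
            inherits(opts, "fit_options"))
  y <- curve$amplitude
  if (!all(is.finite(y))) stop("non-finite amplitudes in `curve`", call. = FALSE)
  if (max(y) <= 0)
    return(fit_result(NULL, sum(y^2), y, converged = FALSE, 0L,
                      flags = "degenerate: curve is identically zero"))
  area <- tf$area
  grid <- curve$time
  horizon <- grid[length(grid)]
  ma <- max(y); t_ma <- grid[which.max(y)]; a_end <- y[length(y)]
  has_lysis <- a_end < 0.995 * ma
  flags <- character()
  if (!has_lysis) {
    flags <- "lysis term weakly identified: no decay within horizon"
    warning("curve shows no decay within its horizon; ",
            "lysis parameters are weakly identified", call. = FALSE)
  }

  th1 <- plasma_start(curve, area)
  theta0 <- c(K_n1 = unname(th1[1L]), K_p1 = unname(th1[2L]),
              K_d1 = unname(th1[3L]),
              K_n2 = if (has_lysis) max((ma - a_end) / area, 1e-3) else 1e-3,
              K_p2 = if (has_lysis) max((horizon - t_ma) / 2, 1) else 10,
              K_d2 = if (has_lysis) max(t_ma, th1[3L] + 1) else 0.9 * horizon)
  # when formation and lysis overlap, the visible post-peak drop badly
  # understates the lysis term (a monotone trace can still hide a large
  # lysis term that only trims the gain) and the objective has a narrow
  # basin in K_d2; a variable-projection scan over the lysis onset (gains
  # solved by linear least squares at each step) locates that basin before
  # the full six-parameter polish
  extras <- wb_varpro_starts(y / area, grid, th1, horizon)
  predict_fn <- function(theta)
    area * (theta[1L] * sat_exp(grid, theta[2L], theta[3L]) -
            theta[4L] * sat_exp(grid, theta[5L], theta[6L]))
  best <- lm_fit_multistart(predict_fn, y, theta0, opts, extras)
  fit_result(whole_blood_params(best$theta[1L], best$theta[2L], best$theta[3L],
                                best$theta[4L], best$theta[5L], best$theta[6L]),
             best$rss, y, best$converged, best$n_starts_used, flags)
}

# variable-projection pre-search for the whole-blood fit: scan candidate
# lysis onsets, run a short LM over the four kinetic parameters with both
# gains profiled out by linear least squares, and return the best few
# (gains, kinetics) combinations as structured starts for the full fit
wb_varpro_starts <- function(y, grid, th1, horizon) {
  gains_for <- function(kin) {
    X <- cbind(sat_exp(grid, kin[1L], kin[2L]),
               -sat_exp(grid, kin[3L], kin[4L]))
    g <- if (max(abs(X[, 2L])) < 1e-12) {
      c(sum(X[, 1L] * y) / max(sum(X[, 1L]^2), 1e-12), 1e-6)
    } else tryCatch(stats::lm.fit(X, y)$coefficients,
                    error = function(e) c(NA_real_, NA_real_))
    g[!is.finite(g) | g <= 0] <- 1e-6
    unname(g)
  }
  resid_fn <- function(lk) {
    kin <- exp(lk)
    g <- gains_for(kin)
    g[1L] * sat_exp(grid, kin[1L], kin[2L]) -
      g[2L] * sat_exp(grid, kin[3L], kin[4L]) - y
  }
  kd1 <- th1[[3L]]; kp1 <- th1[[2L]]
  kd2_grid <- seq(kd1 + 1, min(horizon - 5, kd1 + 70), by = 4)
  # the rise-time heuristic underestimates K_p1 when lysis eats into the
  # peak, and the two time constants trade off, so cross a few kinetic
  # starting pairs with every candidate onset
  combos <- list(c(kp1, 8), c(kp1, 22), c(1.8 * kp1, 8), c(1.8 * kp1, 22))
  cases <- expand.grid(kd2 = kd2_grid, cb = seq_along(combos))
  fits <- list()
  for (i in seq_len(nrow(cases))) {
    cb <- combos[[cases$cb[i]]]
    k0 <- pmin(pmax(c(cb[1L], kd1, cb[2L], cases$kd2[i]), 1e-6), 1e4)
    # a pre-search candidate that runs out of iterations is simply a worse
    # start; silence the solver's complaint
    r <- try(suppressWarnings(minpack.lm::nls.lm(
      par = log(k0), lower = rep(log(1e-6), 4L), upper = rep(log(1e4), 4L),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-9, ptol = 1e-9, gtol = 0, maxiter = 100L, maxfev = 2000L))),
      silent = TRUE)
    if (!inherits(r, "try-error")) {
      fits[[length(fits) + 1L]] <- list(dev = r$deviance, kin = exp(r$par))
      # an essentially exact candidate ends the search
      if (r$deviance <= 1e-12 * sum(y^2)) break
    }
  }
  fits <- fits[order(vapply(fits, `[[`, numeric(1), "dev"))]
  lapply(fits[seq_len(min(3L, length(fits)))], function(f) {
    g <- gains_for(f$kin)
    c(g[1L], f$kin[1L], f$kin[2L], g[2L], f$kin[3L], f$kin[4L])
  })
}

# impulse-response predictors for the candidate model orders used by AIC
order_predictor <- function(order, grid, area) {
  switch(order,
    first_order = function(theta)      # K_n/s e^{-K_d s}: delayed ramp, k = 2
      area * theta[1L] * pmax(grid - theta[2L], 0),
    second_order = function(theta)     # integrator + one pole, k = 3
      area * theta[1L] * sat_exp(grid, theta[2L], theta[3L]),
    third_order = function(theta) {    # integrator + two poles, k = 4
      s <- pmax(grid - theta[4L], 0)
      pa <- theta[2L]; pb <- theta[3L]
      if (abs(pa - pb) < 1e-8 * pa) {
        area * theta[1L] * (1 - exp(-s / pa) * (1 + s / pa))
      } else {
        area * theta[1L] *
          (1 - (pa * exp(-s / pa) - pb * exp(-s / pb)) / (pa - pb))
      }
    },
    stop(sprintf("unknown model order '%s'", order), call. = FALSE))
}

order_start <- function(order, curve, area) {
  th <- plasma_start(curve, area)
  switch(order,
    first_order = c(K_n = unname(th[1L] / max(th[2L], 1)), K_d = unname(th[3L])),
    second_order = unname(th),
    third_order = c(unname(th[1L]), unname(th[2L]), unname(th[2L]) * 0.5,
                    unname(th[3L])))
}

order_k <- c(first_order = 2L, second_order = 3L, third_order = 4L)

#' Model-order selection by AIC
#'
#' Fits each candidate impulse-response structure to the observed curve and
#' scores it with the least-squares Akaike Information Criterion
#' `AIC = n * log(RSS / n) + 2 k`, where `k` is the parameter count. The
#' table is sorted ascending, so the first row is the preferred structure.
#' An exact-zero RSS yields a `-Inf` sentinel.
#'
#' @param curve Observed [teg_curve()].
#' @param input A [tf_impulse()] (candidate structures are compared on their
#'   impulse responses) or a [thrombin_curve()], in which case the
#'   second-order candidate is fitted by convolution and the others on an
#'   equivalent-area impulse.
#' @param orders Character vector of candidates among `"first_order"`
#'   (delayed ramp, 2 parameters), `"second_order"` (the plasma model, 3)
#'   and `"third_order"` (an extra pole, 4). At least two.
#' @param opts A [fit_options()] bundle.
#' @return A data.frame with columns `order`, `k`, `rss`, `aic`, sorted by
#'   `aic`.
#' @export
aic_model_order <- function(curve, input = tf_impulse(1),
                            orders = c("first_order", "second_order",
                                       "third_order"),
                            opts = fit_options(starts = 4L)) {
  stopifnot(inherits(curve, "teg_curve"))
  orders <- match.arg(orders, c("first_order", "second_order", "third_order"),
                      several.ok = TRUE)
  if (length(orders) < 2L)
    stop("need at least 2 candidate structures", call. = FALSE)
  area <- input_area(input)
  y <- curve$amplitude
  n <- length(y)
  rows <- lapply(orders, function(ord) {
    if (ord == "second_order" && inherits(input, "thrombin_curve")) {
      fit <- fit_plasma(curve, input, opts)
      rss <- fit$rss
    } else {
      pf <- order_predictor(ord, curve$time, area)
      th0 <- order_start(ord, curve, area)
      rss <- lm_fit_multistart(pf, y, th0, opts)$rss
    }
    k <- order_k[[ord]]
    aic <- if (rss <= 0) -Inf else n * log(rss / n) + 2 * k
    data.frame(order = ord, k = k, rss = rss, aic = aic)
  })
  tab <- do.call(rbind, rows)
  # ascending AIC; ties broken toward fewer parameters
  tab[order(tab$aic, tab$k), , drop = FALSE]
}

#' Coefficient of determination between two curves
#'
#' `R^2 = 1 - sum((o - p)^2) / sum((o - mean(o))^2)` on a shared grid.
#'
#' @param observed,predicted [teg_curve()]s on the same time grid.
#' @return R-squared (<= 1; negative when the prediction is worse than the
#'   mean).
#' @export
goodness_of_fit <- function(observed, predicted) {
  stopifnot(inherits(observed, "teg_curve"), inherits(predicted, "teg_curve"))
  if (length(observed$time) != length(predicted$time) ||
      any(abs(observed$time - predicted$time) > 1e-9))
    stop("curves must share the same time grid", call. = FALSE)
  o <- observed$amplitude; p <- predicted$amplitude
  tss <- sum((o - mean(o))^2)
  if (tss <= 0)
    stop("R-squared undefined for a constant observed trace", call. = FALSE)
  1 - sum((o - p)^2) / tss
}
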