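test_that("noiseless plasma refits recover the generator parameters", {
  sets <- sample_plasma_params(10, seed = 41)
  for (p in sets) {
    cv <- plasma_impulse_curve(p, teg_grid(90))
    f <- fit_plasma(cv, tf_impulse(1), fit_options(starts = 2))
    rel <- abs(unlist(f$params) - unlist(p)) / unlist(p)
    expect_lt(max(rel), 0.001)
    expect_gt(f$r2, 0.9999)
    expect_true(f$converged)
  }
})

test_that("plasma fit through the thrombin-convolution path recovers parameters", {
  pan <- sample_factor_panels(2, seed = 43)
  for (i in 1:2) {
    thr <- synth_thrombin(pan[i, , drop = FALSE], seed = i)
    p <- plasma_params(0.012 + 0.002 * i, 5 + i, 7 + i)
    cv <- plasma_response_to_thrombin(p, thr, teg_grid(60))
    f <- fit_plasma(cv, thr, fit_options(starts = 1))
    rel <- abs(unlist(f$params) - unlist(p)) / unlist(p)
    expect_lt(max(rel), 0.001)
  }
})

test_that("refitting from a fitted solution is idempotent", {
  p <- plasma_params(60, 8, 10)
  cv <- plasma_impulse_curve(p, teg_grid(90))
  f1 <- fit_plasma(cv, tf_impulse(1), fit_options(starts = 1))
  cv_fit <- plasma_impulse_curve(f1$params, teg_grid(90))
  f2 <- fit_plasma(cv_fit, tf_impulse(1), fit_options(starts = 1))
  expect_equal(unlist(f2$params), unlist(f1$params), tolerance = 1e-7)
})

test_that("noisy plasma fits stay accurate in the median", {
  p <- plasma_params(60, 8, 10)
  clean <- plasma_impulse_curve(p, teg_grid(90))
  errs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    noisy <- teg_curve(clean$time,
                       pmax(clean$amplitude + stats::rnorm(length(clean$time),
                                                           0, 0.5), 0))
    f <- fit_plasma(noisy, tf_impulse(1), fit_options(starts = 2, seed = s))
    max(abs(unlist(f$params) - unlist(p)) / unlist(p))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("noiseless whole-blood refits recover all six parameters", {
  sets <- sample_wb_params(10, seed = 47)
  for (p in sets) {
    cv <- whole_blood_curve(p, teg_grid(120), tf_impulse(1))
    f <- fit_whole_blood(cv, tf_impulse(1), fit_options(starts = 2))
    rel <- abs(unlist(f$params) - unlist(p)) / unlist(p)
    expect_lt(max(rel), 0.005)
  }
})

test_that("a curve with no decay flags the lysis term as weakly identified", {
  p <- whole_blood_params(60, 8, 10, 20, 15, 150)   # lysis beyond horizon
  cv <- whole_blood_curve(p, teg_grid(90), tf_impulse(1))
  expect_warning(f <- fit_whole_blood(cv, tf_impulse(1),
                                      fit_options(starts = 2)),
                 "weakly identified")
  expect_match(f$flags, "weakly identified", all = FALSE)
  form <- unlist(f$params)[c("K_n1", "K_p1", "K_d1")]
  truth <- c(K_n1 = 60, K_p1 = 8, K_d1 = 10)
  expect_lt(max(abs(form - truth) / truth), 0.01)
})

test_that("degenerate all-zero curves do not crash the fitters", {
  z <- teg_curve(0:60, rep(0, 61))
  f <- fit_whole_blood(z, tf_impulse(1), fit_options(starts = 1))
  expect_false(f$converged)
  expect_match(f$flags, "degenerate", all = FALSE)
  fp <- fit_plasma(z, tf_impulse(1), fit_options(starts = 1))
  expect_false(fp$converged)
})

test_that("fits are invariant to uniform grid refinement", {
  p <- plasma_params(60, 8, 10)
  f1 <- fit_plasma(plasma_impulse_curve(p, teg_grid(90, 1 / 12)),
                   tf_impulse(1), fit_options(starts = 1))
  f2 <- fit_plasma(plasma_impulse_curve(p, teg_grid(90, 1 / 24)),
                   tf_impulse(1), fit_options(starts = 1))
  expect_lt(max(abs(unlist(f1$params) - unlist(f2$params)) /
                unlist(f1$params)), 1e-4)
})

test_that("multi-start never does worse than a single start", {
  p <- whole_blood_params(60, 8, 10, 20, 15, 30)
  set.seed(7)
  noisy <- teg_curve(teg_grid(90), pmax(
    whole_blood_curve(p, teg_grid(90), tf_impulse(1))$amplitude +
      stats::rnorm(length(teg_grid(90)), 0, 1), 0))
  f1 <- fit_whole_blood(noisy, tf_impulse(1), fit_options(starts = 1, seed = 3))
  f4 <- fit_whole_blood(noisy, tf_impulse(1), fit_options(starts = 4, seed = 3))
  expect_lte(f4$rss, f1$rss + 1e-9)
})

test_that("AIC prefers the generating second-order structure under noise", {
  p <- plasma_params(60, 8, 10)
  clean <- plasma_impulse_curve(p, teg_grid(60, 0.25))
  wins <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    noisy <- teg_curve(clean$time,
                       pmax(clean$amplitude +
                              stats::rnorm(length(clean$time), 0, 0.3), 0))
    tab <- aic_model_order(noisy, tf_impulse(1),
                           opts = fit_options(starts = 2, seed = s))
    tab$order[1L]
  }, character(1))
  expect_gte(mean(wins == "second_order"), 0.8)
})

test_that("AIC tie-breaks toward fewer parameters and flags zero RSS", {
  # first-order (ramp) data: the ramp fits exactly, RSS ~ 0 for it, and the
  # richer structures cannot beat its parameter count
  ramp <- teg_curve(seq(0, 30, 0.25), 1.5 * pmax(seq(0, 30, 0.25) - 4, 0))
  tab <- aic_model_order(ramp, tf_impulse(1), opts = fit_options(starts = 2))
  expect_equal(tab$order[1L], "first_order")
  expect_true(all(tab$aic[1L] <= tab$aic))
})

test_that("first-order-generated noisy data never selects third order", {
  ramp_amp <- function(t) 1.5 * pmax(t - 4, 0)
  tt <- seq(0, 30, 0.25)
  picks <- vapply(1:10, function(s) {
    set.seed(3000 + s)
    noisy <- teg_curve(tt, pmax(ramp_amp(tt) + stats::rnorm(length(tt), 0, 0.3), 0))
    aic_model_order(noisy, tf_impulse(1),
                    opts = fit_options(starts = 2, seed = s))$order[1L]
  }, character(1))
  expect_true(all(picks %in% c("first_order", "second_order")))
})

test_that("goodness of fit is the standard coefficient of determination", {
  o <- teg_curve(0:10, c(0, 1, 3, 6, 10, 14, 17, 19, 20, 20, 20))
  expect_equal(goodness_of_fit(o, o), 1)
  pred_mean <- teg_curve(0:10, rep(mean(o$amplitude), 11))
  expect_equal(goodness_of_fit(o, pred_mean), 0)
  # hand-computed with known residuals
  res <- c(0.5, -0.5, 0.2, 0, -0.2, 0.1, 0, 0.3, -0.3, 0, 0.1)
  pred <- teg_curve(0:10, o$amplitude + res)
  expect_equal(goodness_of_fit(o, pred),
               1 - sum(res^2) / sum((o$amplitude - mean(o$amplitude))^2))
  flat <- teg_curve(0:10, rep(5, 11))
  expect_error(goodness_of_fit(flat, o), "constant")
  expect_error(goodness_of_fit(o, teg_curve(0:9, rep(1, 10))), "grid")
})
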