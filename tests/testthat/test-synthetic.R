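test_that("normal panels match the designed truncation and determinism", {
  pan <- sample_factor_panels(1000, seed = 71)
  facs <- c("FII", "FV", "FVII", "FVIII", "FIX", "FX", "ATIII", "PC")
  for (f in facs) {
    expect_lt(abs(mean(pan[[f]]) - 100), 3)
    inside <- mean(pan[[f]] >= 60 & pan[[f]] <= 140)
    expect_gt(inside, 0.92); expect_lt(inside, 0.98)
  }
  expect_true(all(as.matrix(pan) >= 0))
  expect_identical(pan, sample_factor_panels(1000, seed = 71))
  expect_false(identical(pan, sample_factor_panels(1000, seed = 72)))
  expect_error(sample_factor_panels(0), ">= 1")
  expect_error(sample_factor_panels(5, population = "zebra"))
})

test_that("trauma panels are shifted: lower factors, higher D-dimer, wide platelets", {
  nor <- sample_factor_panels(500, seed = 73)
  tra <- sample_factor_panels(500, seed = 73, population = "trauma")
  expect_lt(mean(tra$FII), mean(nor$FII))
  expect_gt(mean(tra$d_dimer), mean(nor$d_dimer))
  expect_lte(max(tra$platelet_count), 350)
  expect_gt(stats::sd(tra$platelet_count), stats::sd(nor$platelet_count))
})

test_that("ground-truth maps respect the registry and keep parameters positive", {
  maps <- make_true_maps(seed = 74, sparsity = 3)
  reg <- factor_feature_registry()
  for (pn in names(maps)) {
    sel <- maps[[pn]]$feature_names[maps[[pn]]$support]
    expect_true(all(sel %in% reg[[pn]]))
    expect_length(maps[[pn]]$support, 3)
  }
  # built-in dependencies: anticoagulant lowers the gain, D-dimer drives lysis
  kn1 <- maps$K_n1
  expect_true("ATIII" %in% kn1$feature_names[kn1$support])
  kn2 <- maps$K_n2
  expect_true("d_dimer" %in% kn2$feature_names[kn2$support])
  expect_gt(kn2$coefficients[match("d_dimer",
                                   kn2$feature_names[kn2$support])], 0)
  # positivity over a large normal panel (and the trauma tail)
  for (pop in c("normal", "trauma")) {
    pan <- sample_factor_panels(1000, seed = 75, population = pop)
    for (pn in names(maps))
      expect_true(all(predict_map(maps[[pn]], pan) > 0))
  }
  expect_warning(m0 <- make_true_maps(seed = 74, sparsity = 0), "intercept-only")
  expect_length(m0$K_p1$support, 0)
  expect_error(make_true_maps(sparsity = 9), "exceeds")
})

test_that("plasma ground-truth maps exist and include the ATIII-gain link", {
  maps <- make_true_maps(seed = 76, sparsity = 3, model = "plasma")
  expect_setequal(names(maps), c("K_np", "K_p", "K_dp"))
  knp <- maps$K_np
  i <- match("ATIII", knp$feature_names[knp$support])
  expect_false(is.na(i))
  expect_lt(knp$coefficients[i], 0)
})

test_that("synthetic thrombin has the documented shape and factor dependence", {
  pan <- sample_factor_panels(1, seed = 77)
  thr <- synth_thrombin(pan, seed = 5)
  gen <- attr(thr, "generator")
  # analytic extremum of the difference of exponentials
  tstar <- gen$lag + log(gen$tau_dec / gen$tau_rise) /
    (1 / gen$tau_rise - 1 / gen$tau_dec)
  peak <- gen$c * (exp(-(tstar - gen$lag) / gen$tau_dec) -
                   exp(-(tstar - gen$lag) / gen$tau_rise))
  expect_equal(max(thr$thrombin), peak, tolerance = 1e-3)
  expect_equal(thr$time[which.max(thr$thrombin)], tstar, tolerance = 0.25)
  # ETP decreases when ATIII doubles, increases with FII
  area <- function(p) {
    tc <- synth_thrombin(p, seed = 5)
    sum(diff(tc$time) * (utils::head(tc$thrombin, -1) +
                         utils::tail(tc$thrombin, -1)) / 2)
  }
  p2 <- pan; p2$ATIII <- 2 * pan$ATIII
  expect_lt(area(p2), area(pan))
  p3 <- pan; p3$FII <- 1.5 * pan$FII
  expect_gt(area(p3), area(pan))
  # non-negative and decayed for a spread of panels
  pans <- sample_factor_panels(100, seed = 78)
  for (i in seq_len(20)) {
    tc <- synth_thrombin(pans[i, , drop = FALSE], seed = i)
    expect_true(all(tc$thrombin >= 0))
    expect_lt(tc$thrombin[length(tc$thrombin)], 0.01 * max(tc$thrombin))
  }
  expect_error(synth_thrombin(data.frame(FII = 100), seed = 1), "ATIII")
})

test_that("cohorts are reproducible and carry their exact noise realization", {
  c1 <- generate_cohort(8, "whole_blood", noise_sd = 0.5, seed = 79)
  c2 <- generate_cohort(8, "whole_blood", noise_sd = 0.5, seed = 79)
  expect_identical(c1$curves, c2$curves)
  expect_identical(c1$panels, c2$panels)
  c3 <- generate_cohort(8, "whole_blood", noise_sd = 0.5, seed = 80)
  expect_false(identical(c1$curves, c3$curves))
  # curve = clean model curve + recorded noise, and stays non-negative
  grid <- teg_grid(c1$provenance$horizon, c1$provenance$dt)
  for (i in c(1, 5)) {
    clean <- suppressWarnings(whole_blood_curve(c1$true_params[[i]], grid,
                                                tf_impulse(c1$tf_area)))
    expect_equal(c1$curves[[i]]$amplitude,
                 clean$amplitude + c1$noise[[i]], tolerance = 1e-12)
    expect_true(all(c1$curves[[i]]$amplitude >= 0))
  }
})

test_that("noiseless cohorts are exactly refittable", {
  coh <- generate_cohort(3, "whole_blood", noise_sd = 0, seed = 81)
  for (i in 1:3) {
    f <- fit_whole_blood(coh$curves[[i]], tf_impulse(coh$tf_area),
                         fit_options(starts = 1))
    truth <- unlist(coh$true_params[[i]])
    expect_lt(max(abs(unlist(f$params) - truth) / truth), 0.005)
  }
})

test_that("end-to-end identifiability: OMP recovers every true support", {
  coh <- generate_cohort(30, "whole_blood", noise_sd = 0, seed = 82)
  pmat <- do.call(rbind, lapply(coh$true_params, unlist))
  for (pn in colnames(pmat)) {
    m <- train_sparse_map(coh$panels, pmat[, pn], pn, sparsity = 3)
    true_sel <- coh$true_maps[[pn]]$feature_names[coh$true_maps[[pn]]$support]
    expect_setequal(m$feature_names[m$support], true_sel)
  }
})

test_that("trauma cohorts lyse more often than normal cohorts", {
  frac_lysed <- function(pop) {
    coh <- generate_cohort(40, "whole_blood", noise_sd = 0, seed = 83,
                           population = pop)
    ly <- vapply(coh$curves, function(cu) teg_features(cu)$Ly30, numeric(1))
    mean(ly > 3)
  }
  expect_gt(frac_lysed("trauma"), frac_lysed("normal"))
})

test_that("proportional noise scales with amplitude", {
  coh <- generate_cohort(5, "whole_blood", noise_sd = 1, seed = 84,
                         noise_model = "proportional")
  for (i in 1:5) {
    amp <- coh$curves[[i]]$amplitude
    lead_in <- amp[teg_grid(90) < coh$true_params[[i]]$K_d1]
    expect_true(all(lead_in == 0))   # zero amplitude leaves zero noise scale
  }
})
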