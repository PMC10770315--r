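# orthonormal-after-centering design: columns orthogonal, mean zero, then
# rescaled to unit variance so z-scoring leaves them orthogonal
orthogonal_panel <- function(n, seed) {
  set.seed(seed)
  M <- cbind(1, matrix(stats::rnorm(n * 7), n))
  Q <- qr.Q(qr(M))[, -1L]           # orthonormal, orthogonal to intercept
  X <- sweep(Q, 2, apply(Q, 2, stats::sd), "/")
  colnames(X) <- c("FII", "FV", "FVII", "FVIII", "FIX", "FX", "ATIII")
  as.data.frame(X)
}

test_that("the feature registry matches the per-parameter feature sets", {
  reg <- factor_feature_registry()
  f7 <- c("FII", "FV", "FVII", "FVIII", "FIX", "FX", "ATIII")
  expect_equal(reg$K_np, f7)
  expect_equal(reg$K_p, f7)
  expect_equal(reg$K_dp, f7)
  expect_setequal(reg$K_d1, c(f7, "PC"))
  expect_setequal(reg$K_p1, c(f7, "PC"))
  expect_setequal(reg$K_n1, c(f7, "PC", "fibrinogen", "platelet_count"))
  expect_setequal(reg$K_n2, c(f7, "PC", "fibrinogen", "platelet_count",
                              "d_dimer"))
  # plasma maps never see PC, fibrinogen, platelets; K_n1 never sees d_dimer
  expect_false("PC" %in% reg$K_np)
  expect_false("d_dimer" %in% reg$K_n1)
})

test_that("constant target yields an intercept-only map", {
  pan <- sample_factor_panels(10, seed = 51)
  m <- train_sparse_map(pan, rep(4.2, 10), "K_p", sparsity = "auto")
  expect_length(m$support, 0)
  expect_equal(m$intercept, 4.2)
  expect_equal(predict_map(m, pan), rep(4.2, 10))
})

test_that("OMP recovers an exact sparse representation on orthogonal designs", {
  pan <- orthogonal_panel(40, seed = 52)
  z <- scale(as.matrix(pan))
  y <- drop(3 * z[, "FV"] - 2 * z[, "ATIII"]) + 5
  m <- train_sparse_map(pan, y, "K_np", sparsity = 2)
  expect_setequal(m$feature_names[m$support], c("FV", "ATIII"))
  cf <- stats::setNames(m$coefficients, m$feature_names[m$support])
  expect_equal(unname(cf["FV"]), 3, tolerance = 1e-9)
  expect_equal(unname(cf["ATIII"]), -2, tolerance = 1e-9)
  expect_equal(m$intercept, 5, tolerance = 1e-9)
})

test_that("OMP equals exhaustive best-subset search on orthogonal designs", {
  for (seed in 53:57) {
    pan <- orthogonal_panel(30, seed = seed)
    z <- scale(as.matrix(pan))
    set.seed(seed)
    beta <- numeric(7); beta[sample(7, 2)] <- stats::runif(2, 1, 4)
    y <- drop(z %*% beta) + stats::rnorm(30, 0, 0.3)
    for (s in 1:2) {
      m <- train_sparse_map(pan, y, "K_np", sparsity = s)
      # brute-force oracle: all supports of size s, min RSS wins
      subsets <- utils::combn(7, s, simplify = FALSE)
      rss <- vapply(subsets, function(sub)
        sum(stats::lm.fit(cbind(1, z[, sub, drop = FALSE]), y)$residuals^2),
        numeric(1))
      best <- subsets[[which.min(rss)]]
      expect_setequal(m$support, best)
    }
  }
})

test_that("OMP support recovery holds at 20 dB SNR on correlated panels", {
  hits <- vapply(1:100, function(s) {
    pan <- sample_factor_panels(50, seed = 6000 + s)
    z <- scale(as.matrix(pan[, factor_feature_registry()$K_n2]))
    set.seed(6000 + s)
    sup <- sample(ncol(z), 3)
    beta <- numeric(ncol(z)); beta[sup] <- stats::runif(3, 1, 3) *
      sample(c(-1, 1), 3, replace = TRUE)
    signal <- drop(z %*% beta)
    noise_sd <- stats::sd(signal) / 10          # SNR = 20 dB
    y <- 10 + signal + stats::rnorm(50, 0, noise_sd)
    m <- train_sparse_map(pan, y, "K_n2", sparsity = 3)
    setequal(m$support, sup)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("auto sparsity settles near the true support on clean data", {
  pan <- sample_factor_panels(60, seed = 58)
  z <- scale(as.matrix(pan))
  y <- 8 + drop(2 * z[, "FII"] - 1.5 * z[, "FX"])
  m <- train_sparse_map(pan, y, "K_dp", sparsity = "auto")
  expect_setequal(m$feature_names[m$support], c("FII", "FX"))
})

test_that("training validates inputs: registry, missing values, tiny n", {
  pan <- sample_factor_panels(10, seed = 59)
  expect_error(train_sparse_map(pan, 1:10, "K_q"), "unknown target")
  pan2 <- pan; pan2$FV[3] <- NA
  expect_error(train_sparse_map(pan2, 1:10, "K_np"), "no imputation")
  expect_error(train_sparse_map(pan[1:2, ], 1:2, "K_np"), "at least 3")
  pan3 <- pan; pan3$FV <- 100
  expect_warning(m <- train_sparse_map(pan3, stats::rnorm(10) + 5, "K_np",
                                       sparsity = 2), "constant")
  expect_false("FV" %in% m$feature_names[m$support])
})

test_that("parameter prediction is the affine map, floored at epsilon", {
  pan <- sample_factor_panels(30, seed = 60)
  maps <- make_true_maps(seed = 61, sparsity = 3, model = "whole_blood")
  # training-mean panel returns intercepts
  mean_pan <- as.data.frame(as.list(colMeans(pan)))
  m <- train_sparse_map(pan, 5 + pan$FV / 50, "K_p", sparsity = 1)
  expect_equal(predict_map(m, mean_pan), m$intercept, tolerance = 1e-9)
  # matrix-arithmetic oracle on a training sample
  row <- pan[7, , drop = FALSE]
  sel <- m$feature_names[m$support]
  zval <- (as.numeric(row[, sel]) - m$standardization$mean[sel]) /
    m$standardization$scale[sel]
  expect_equal(predict_map(m, row),
               m$intercept + sum(zval * m$coefficients), tolerance = 1e-12)
  # positivity floor
  neg_map <- m; neg_map$intercept <- -0.2; neg_map$coefficients <- 0 * neg_map$coefficients
  expect_warning(p <- predict_parameters(
    row, list(K_np = neg_map, K_p = neg_map, K_dp = neg_map), "plasma"),
    "floored")
  expect_equal(p$K_p, 1e-6)
  # missing required feature is named
  expect_error(predict_map(m, row[, setdiff(names(row), sel), drop = FALSE]),
               sel[1])
})

test_that("cross-validation reaches the noise floor on model-consistent cohorts", {
  coh <- generate_cohort(40, "whole_blood", noise_sd = 0, seed = 62)
  tab <- crossvalidate(coh, k = 5, seed = 1, sparsity = 3)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$fold[6], "overall")
  num <- unlist(tab[6, c("R", "K", "alpha", "MA", "t_MA", "Ly30")])
  expect_true(all(num[!is.na(num)] < 0.5))
  # destroying the panel-parameter link inflates the error far above floor
  coh_perm <- coh
  set.seed(9)
  coh_perm$true_params <- coh$true_params[sample(40)]
  tab_perm <- crossvalidate(coh_perm, k = 5, seed = 1, sparsity = 3)
  expect_gt(tab_perm$mean[6], 100 * tab$mean[6])
})

test_that("plasma cohorts cross-validate through the thrombin path", {
  coh <- generate_cohort(20, "plasma", noise_sd = 0, seed = 63)
  tab <- crossvalidate(coh, k = 4, seed = 1, sparsity = 3, horizon = 60)
  num <- unlist(tab[nrow(tab), c("R", "K", "alpha", "MA")])
  expect_true(all(num[!is.na(num)] < 0.5))
  expect_true(is.na(tab$Ly30[nrow(tab)]))   # plasma clots do not lyse
})

test_that("cross-validation error shrinks as the cohort grows", {
  err <- vapply(c(50, 100), function(n) {
    coh <- generate_cohort(n, "whole_blood", noise_sd = 0.5, seed = 64)
    crossvalidate(coh, k = 5, seed = 2, sparsity = 3)$mean[6]
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("fold validation catches degenerate splits", {
  coh <- generate_cohort(6, "whole_blood", noise_sd = 0, seed = 65)
  expect_error(crossvalidate(coh, k = 7), "smaller")
  expect_error(crossvalidate(coh, k = 1), ">= 2")
})

test_that("fit_line handles outliers by rule or by explicit indices", {
  x <- 1:20
  y <- 2 * x
  f <- fit_line(x, y)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_length(f$excluded, 0)
  # one gross outlier, studentized rule: oracle is the manual-removal refit
  y2 <- y; y2[10] <- 90
  f2 <- fit_line(x, y2, outlier_rule = "studentized", threshold = 3)
  expect_equal(f2$excluded, 10L)
  manual <- stats::lm(y2[-10] ~ x[-10])
  expect_equal(f2$slope, unname(stats::coef(manual)[2]), tolerance = 1e-12)
  # explicit index list (the replication path for published exclusions)
  f3 <- fit_line(x, y2, outlier_rule = "indices", exclude = 10)
  expect_equal(f3$slope, 2, tolerance = 1e-12)
  # through-origin on a line through the origin matches the free fit
  f4 <- fit_line(x, y, through_origin = TRUE)
  expect_equal(f4$slope, f$slope, tolerance = 1e-12)
  expect_equal(f4$intercept, 0)
  expect_error(fit_line(1:4, c(2, 4, 6, 8), outlier_rule = "indices",
                        exclude = 1:2), "fewer than 3")
})
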