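#' Coagulation-factor panel column names
#'
#' A factor panel is a data.frame with one row per sample and (a subset of)
#' these columns: factor activities `FII, FV, FVII, FVIII, FIX, FX, ATIII,
#' PC` in percent of normal, `fibrinogen` in mg/dL, `platelet_count` in
#' 10^3/uL, `adp_inhibition` in percent and `d_dimer` in ug/mL.
#'
#' @return Character vector of the canonical column names.
#' @export
factor_panel_columns <- function() {
  c("FII", "FV", "FVII", "FVIII", "FIX", "FX", "ATIII", "PC",
    "fibrinogen", "platelet_count", "adp_inhibition", "d_dimer")
}

#' Validate a factor-panel table
#'
#' Errors on negative values; flags (as returned strings, not errors)
#' percent-activity values outside \[0, 300\]. The normal clinical range of
#' 60-140\% activity is a sampling/QC guide, never a hard bound.
#'
#' @param panels Data.frame of factor-panel rows.
#' @return Character vector of QC flags (empty if clean).
#' @export
validate_factor_panels <- function(panels) {
  cols <- intersect(factor_panel_columns(), names(panels))
  flags <- character()
  for (cn in cols) {
    v <- panels[[cn]]
    if (any(v < 0, na.rm = TRUE))
      stop(sprintf("column %s has negative values", cn), call. = FALSE)
    if (cn %in% c("FII", "FV", "FVII", "FVIII", "FIX", "FX", "ATIII", "PC") &&
        any(v > 300, na.rm = TRUE))
      flags <- c(flags, sprintf("%s has values above 300%% activity", cn))
  }
  flags
}

#' Per-parameter feature registry
#'
#' Which panel features are allowed to predict each model parameter:
#' the seven factors `FII...FX, ATIII` for the plasma parameters; those plus
#' `PC` for the whole-blood formation kinetics (`K_d1`, `K_p1`); plus
#' `fibrinogen` and `platelet_count` for the formation gain `K_n1` (so it
#' reflects both primary and secondary hemostasis); and additionally
#' `d_dimer` for the fibrinolysis-term parameters.
#'
#' @return Named list mapping each model parameter to its allowed features.
#' @export
factor_feature_registry <- function() {
  f7 <- c("FII", "FV", "FVII", "FVIII", "FIX", "FX", "ATIII")
  f8 <- c(f7, "PC")
  f10 <- c(f8, "fibrinogen", "platelet_count")
  f11 <- c(f10, "d_dimer")
  list(K_np = f7, K_p = f7, K_dp = f7,
       K_d1 = f8, K_p1 = f8,
       K_n1 = f10,
       K_n2 = f11, K_p2 = f11, K_d2 = f11)
}

# leave-one-out SSE of OLS on the given design (intercept included)
loo_sse <- function(X, y) {
  n <- length(y)
  Xi <- cbind(1, X)
  fit <- stats::lm.fit(Xi, y)
  h <- rowSums(qr.Q(fit$qr)[, seq_len(fit$rank), drop = FALSE]^2)
  e <- fit$residuals / pmax(1 - h, 1e-12)
  sum(e^2)
}

#' Train a sparse linear map by orthogonal matching pursuit
#'
#' Greedy OMP on z-scored features: at each step the feature most correlated
#' with the current residual joins the support, and all coefficients are
#' re-solved by least squares. Candidate features are restricted to the
#' registry entry for `target`. With `sparsity = "auto"` the support size is
#' chosen by the leave-one-out error minimum along the greedy path (ties
#' toward the smaller support). Deterministic given its inputs.
#'
#' @param panels Factor-panel data.frame (training rows).
#' @param y Numeric vector of the target parameter values, one per row.
#' @param target Parameter name (a key of [factor_feature_registry()]).
#' @param sparsity Number of features to select, or `"auto"`.
#' @return An object of class `sparse_linear_map` with fields `target`,
#'   `feature_names` (candidates, in registry order), `support` (selected
#'   indices), `coefficients` (per selected feature, on the z-score scale),
#'   `intercept`, and `standardization` (training means/scales).
#' @export
train_sparse_map <- function(panels, y, target, sparsity = "auto") {
  reg <- factor_feature_registry()
  if (!target %in% names(reg))
    stop(sprintf("unknown target parameter '%s'", target), call. = FALSE)
  feats <- reg[[target]]
  missing_cols <- setdiff(feats, names(panels))
  if (length(missing_cols))
    stop(sprintf("panel table lacks feature(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  X <- as.matrix(panels[, feats, drop = FALSE])
  if (anyNA(X) || anyNA(y))
    stop("missing values in features or target; no imputation is performed",
         call. = FALSE)
  n <- length(y)
  if (nrow(X) != n) stop("panels and y disagree in length", call. = FALSE)
  if (n < 3L) stop("need at least 3 training samples", call. = FALSE)

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(feats[!keep], collapse = ", ")), call. = FALSE)
    sdv[!keep] <- 1  # keep the map applicable; these atoms are never selected
  }
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  max_s <- if (identical(sparsity, "auto")) min(sum(keep), n - 2L)
           else min(as.integer(sparsity), sum(keep), n - 2L)
  if (!identical(sparsity, "auto") && as.integer(sparsity) > max_s)
    warning(sprintf("sparsity capped at %d by sample/feature count", max_s),
            call. = FALSE)

  # greedy path
  path <- integer(0)
  r <- y - mean(y)
  avail <- unname(which(keep))
  while (length(path) < max_s && length(avail)) {
    scores <- abs(crossprod(Z[, avail, drop = FALSE], r))
    j <- avail[which.max(scores)]   # which.max breaks ties by column order
    path <- c(path, j)
    cf <- stats::lm.fit(cbind(1, Z[, path, drop = FALSE]), y)$coefficients
    r <- y - cbind(1, Z[, path, drop = FALSE]) %*% cf
    avail <- setdiff(avail, j)
    if (sum(r^2) < 1e-24 * max(sum((y - mean(y))^2), 1)) break
  }

  n_sel <- if (identical(sparsity, "auto")) {
    sses <- vapply(0:length(path), function(s) {
      if (s == 0L) loo_sse(matrix(0, n, 0), y)
      else loo_sse(Z[, path[seq_len(s)], drop = FALSE], y)
    }, numeric(1))
    which.min(sses) - 1L  # which.min ties resolve toward smaller support
  } else min(as.integer(sparsity), length(path))

  support <- path[seq_len(n_sel)]
  if (n_sel > 0L) {
    cf <- stats::lm.fit(cbind(1, Z[, support, drop = FALSE]), y)$coefficients
    intercept <- unname(cf[1L])
    coefs <- unname(cf[-1L])
  } else {
    intercept <- mean(y)
    coefs <- numeric(0)
  }
  structure(list(target = target, feature_names = feats,
                 support = support, coefficients = coefs,
                 intercept = intercept,
                 standardization = list(mean = mu, scale = sdv)),
            class = "sparse_linear_map")
}

#' @export
print.sparse_linear_map <- function(x, ...) {
  cat(sprintf("Sparse map for %s: intercept %.4g", x$target, x$intercept))
  if (length(x$support)) {
    terms <- sprintf("%+.4g z(%s)", x$coefficients,
                     x$feature_names[x$support])
    cat(" ", paste(terms, collapse = " "))
  }
  cat("\n")
  invisible(x)
}

#' Evaluate a sparse linear map on panel rows
#'
#' @param map A `sparse_linear_map`.
#' @param panels Data.frame with the map's selected features present.
#' @return Numeric predictions, one per row.
#' @export
predict_map <- function(map, panels) {
  stopifnot(inherits(map, "sparse_linear_map"))
  if (!length(map$support)) return(rep(map$intercept, nrow(panels)))
  sel <- map$feature_names[map$support]
  miss <- setdiff(sel, names(panels))
  if (length(miss))
    stop(sprintf("panel lacks required feature(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  X <- as.matrix(panels[, sel, drop = FALSE])
  if (anyNA(X))
    stop(sprintf("missing values in required feature(s) of map for %s",
                 map$target), call. = FALSE)
  Z <- sweep(sweep(X, 2, map$standardization$mean[sel]), 2,
             map$standardization$scale[sel], "/")
  unname(drop(map$intercept + Z %*% map$coefficients))
}

#' Predict model parameters from a factor panel
#'
#' Applies one trained map per parameter and assembles a parameter object.
#' Non-positive predictions are floored at a small epsilon with a warning
#' (model parameters must stay strictly positive).
#'
#' @param panel One panel row (data.frame or named list).
#' @param maps Named list of `sparse_linear_map`s covering all parameters of
#'   the requested model.
#' @param model `"plasma"` or `"whole_blood"`.
#' @param floor_eps Positivity floor (default 1e-6).
#' @return A [plasma_params()] or [whole_blood_params()] object.
#' @export
predict_parameters <- function(panel, maps, model = c("plasma", "whole_blood"),
                               floor_eps = 1e-6) {
  model <- match.arg(model)
  panel <- as.data.frame(panel)
  need <- if (model == "plasma") c("K_np", "K_p", "K_dp")
          else c("K_n1", "K_p1", "K_d1", "K_n2", "K_p2", "K_d2")
  miss <- setdiff(need, names(maps))
  if (length(miss))
    stop(sprintf("maps missing for parameter(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  vals <- vapply(need, function(p) predict_map(maps[[p]], panel), numeric(1))
  if (any(vals <= 0)) {
    warning(sprintf("non-positive prediction floored at %g for: %s", floor_eps,
                    paste(need[vals <= 0], collapse = ", ")), call. = FALSE)
    vals[vals <= 0] <- floor_eps
  }
  if (model == "plasma") plasma_params(vals[1L], vals[2L], vals[3L])
  else whole_blood_params(vals[1L], vals[2L], vals[3L], vals[4L], vals[5L],
                          vals[6L])
}

#' Fivefold (k-fold) cross-validation of the panel-to-TEG pipeline
#'
#' For each fold: sparse maps are trained per model parameter on the other
#' folds' (panel, fitted-parameter) pairs, held-out parameters are
#' predicted, curves are simulated from them, and the TEG properties
#' (R, K, alpha, MA, t_MA, Ly30) of the predicted curves are compared with
#' those of the reference curves (simulated from each sample's own fitted
#' parameters). Reported as mean percent error per property per fold plus
#' an overall row, the standard layout of a cross-validated error table.
#'
#' @param cohort A `teg_cohort` from [generate_cohort()], or a list with
#'   components `panels` (data.frame), `params` (list of parameter objects,
#'   one per row), `model` (`"plasma"`/`"whole_blood"`), and for the plasma
#'   model `thrombin_curves` (list), for whole blood `tf_area`. If `params`
#'   is absent but `curves` is present, each curve is fitted first.
#' @param k Number of folds (>= 2).
#' @param seed Seed for the fold assignment.
#' @param sparsity Passed to [train_sparse_map()].
#' @param horizon Simulation horizon in minutes for property extraction.
#' @param opts [fit_options()] used only when curves must be fitted.
#' @return Data.frame with one row per fold plus `"overall"`, columns
#'   `R, K, alpha, MA, t_MA, Ly30` (mean percent errors; `NA` when the
#'   property is undefined throughout the fold) and `mean` across defined
#'   properties.
#' @export
crossvalidate <- function(cohort, k = 5L, seed = 1L, sparsity = "auto",
                          horizon = 90, opts = fit_options(starts = 2L)) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  panels <- cohort$panels
  n <- nrow(panels)
  if (n < k) stop("cohort smaller than number of folds", call. = FALSE)
  model <- cohort$model
  params <- cohort$params
  # noiseless synthetic cohorts are model-consistent, so their ground-truth
  # parameters coincide with what a per-sample fit would return; noisy
  # cohorts must be fitted so measurement noise propagates into the maps
  if (is.null(params) && !is.null(cohort$true_params) &&
      (cohort$noise_sd %||% 0) == 0)
    params <- cohort$true_params
  if (is.null(params)) {
    if (is.null(cohort$curves))
      stop("cohort must carry `params` or `curves`", call. = FALSE)
    params <- lapply(seq_len(n), function(i) {
      if (model == "plasma")
        fit_plasma(cohort$curves[[i]], cohort$thrombin_curves[[i]], opts)$params
      else
        fit_whole_blood(cohort$curves[[i]],
                        tf_impulse(cohort$tf_area %||% 5), opts)$params
    })
  }
  pnames <- param_names(params[[1L]])
  pmat <- do.call(rbind, lapply(params, function(p) unlist(p[pnames])))

  set.seed(seed)
  fold_id <- sample(rep(seq_len(k), length.out = n))
  grid <- teg_grid(horizon)
  props <- c("R", "K", "alpha", "MA", "t_MA", "Ly30")

  sim_curve <- function(p, i) {
    if (model == "plasma") {
      if (!is.null(cohort$thrombin_curves))
        plasma_response_to_thrombin(p, cohort$thrombin_curves[[i]], grid)
      else plasma_impulse_curve(p, grid, area = cohort$tf_area %||% 1)
    } else {
      suppressWarnings(
        whole_blood_curve(p, grid, tf_impulse(cohort$tf_area %||% 5)))
    }
  }
  feat_vec <- function(f) c(R = f$R, K = f$K, alpha = f$alpha, MA = f$MA,
                            t_MA = f$t_MA, Ly30 = f$Ly30)

  ref_feats <- t(vapply(seq_len(n), function(i)
    feat_vec(teg_features(sim_curve(params[[i]], i))), numeric(6)))

  fold_rows <- lapply(seq_len(k), function(f) {
    test <- which(fold_id == f); train <- which(fold_id != f)
    if (length(test) < 1L || length(train) < 2L)
      stop("fold with too few samples", call. = FALSE)
    maps <- lapply(pnames, function(pn)
      train_sparse_map(panels[train, , drop = FALSE], pmat[train, pn], pn,
                       sparsity))
    names(maps) <- pnames
    errs <- t(vapply(test, function(i) {
      est_p <- suppressWarnings(predict_parameters(
        panels[i, , drop = FALSE], maps, model))
      est <- feat_vec(teg_features(sim_curve(est_p, i)))
      ref <- ref_feats[i, ]
      e <- abs(est - ref) / abs(ref) * 100
      e[is.na(ref) | abs(ref) < 1e-9] <- NA_real_
      e
    }, numeric(6)))
    colMeans(errs, na.rm = TRUE)
  })
  tab <- do.call(rbind, fold_rows)
  tab <- rbind(tab, colMeans(tab, na.rm = TRUE))
  tab[is.nan(tab)] <- NA_real_
  out <- data.frame(fold = c(as.character(seq_len(k)), "overall"), tab,
                    row.names = NULL, check.names = FALSE)
  names(out) <- c("fold", props)
  out$mean <- rowMeans(out[, props], na.rm = TRUE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Outlier-aware line of best fit
#'
#' Ordinary least squares, optionally through the origin, with an optional
#' outlier-exclusion pass before the final fit: either an externally
#' studentized-residual threshold or an explicit index list. Reported
#' `r2 = 1 - RSS / TSS` about the mean of the retained `y`.
#'
#' @param x,y Numeric vectors.
#' @param through_origin Force a zero intercept.
#' @param outlier_rule `"none"`, `"studentized"` or `"indices"`.
#' @param threshold Studentized-residual cutoff (default 3).
#' @param exclude Integer indices to drop when `outlier_rule = "indices"`.
#' @return List with `slope`, `intercept`, `r2`, `excluded` (indices) and
#'   `n_used`.
#' @export
fit_line <- function(x, y, through_origin = FALSE,
                     outlier_rule = c("none", "studentized", "indices"),
                     threshold = 3, exclude = integer(0)) {
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(length(x) == length(y))
  idx <- seq_along(x)
  excluded <- integer(0)
  if (outlier_rule == "studentized") {
    f0 <- if (through_origin) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
    rs <- stats::rstudent(f0)
    raw <- stats::residuals(f0)
    # a non-finite external studentization means deleting the point leaves a
    # (near-)perfect fit: a gross outlier whenever its own residual is large
    gross <- !is.finite(rs) & abs(raw) > 1e-8 * max(abs(raw))
    excluded <- idx[gross | (is.finite(rs) & abs(rs) > threshold)]
  } else if (outlier_rule == "indices") {
    excluded <- intersect(as.integer(exclude), idx)
  }
  keep <- setdiff(idx, excluded)
  if (length(keep) < 3L)
    stop("fewer than 3 points remain after exclusion", call. = FALSE)
  xk <- x[keep]; yk <- y[keep]
  fit <- if (through_origin) stats::lm(yk ~ xk + 0) else stats::lm(yk ~ xk)
  cf <- stats::coef(fit)
  slope <- unname(if (through_origin) cf[1L] else cf[2L])
  intercept <- if (through_origin) 0 else unname(cf[1L])
  tss <- sum((yk - mean(yk))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  list(slope = slope, intercept = intercept, r2 = r2, excluded = excluded,
       n_used = length(keep))
}
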