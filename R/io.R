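#' Read a curve CSV
#'
#' Reads a two-column curve file and dispatches on its header:
#' `time_min,amplitude_mm` yields a [teg_curve()],
#' `time_min,thrombin_nM` a [thrombin_curve()]. Non-numeric cells,
#' duplicate or non-increasing times are reported with their row number.
#'
#' @param path Path to the CSV file.
#' @return A `teg_curve` or `thrombin_curve`.
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  hdr <- names(df)
  kind <- if (identical(hdr, c("time_min", "amplitude_mm"))) "teg"
          else if (identical(hdr, c("time_min", "thrombin_nM"))) "thrombin"
          else stop(sprintf(
            "unrecognized header '%s' (expected time_min,amplitude_mm or time_min,thrombin_nM)",
            paste(hdr, collapse = ",")), call. = FALSE)
  num <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !is.na(df[[j]]) & nzchar(df[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column %s, row %d of %s",
                   df[[j]][bad[1L]], hdr[j], bad[1L], path), call. = FALSE)
    if (anyNA(num[[j]]))
      stop(sprintf("empty cell in column %s of %s", hdr[j], path),
           call. = FALSE)
  }
  t <- num[[1L]]
  nonmono <- which(diff(t) <= 0)
  if (length(nonmono))
    stop(sprintf("time not strictly increasing at row %d of %s",
                 nonmono[1L] + 1L, path), call. = FALSE)
  if (kind == "teg") teg_curve(t, num[[2L]]) else thrombin_curve(t, num[[2L]])
}

#' Write a curve CSV
#'
#' Writes the standard two-column format read back by [read_curve_csv()]
#' (full-precision values; the round trip is exact).
#'
#' @param curve A `teg_curve` or `thrombin_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  if (inherits(curve, "teg_curve")) {
    df <- data.frame(time_min = curve$time, amplitude_mm = curve$amplitude)
  } else if (inherits(curve, "thrombin_curve")) {
    df <- data.frame(time_min = curve$time, thrombin_nM = curve$thrombin)
  } else stop("`curve` must be a teg_curve or thrombin_curve", call. = FALSE)
  # 17 significant digits per element keeps the round trip bit-exact
  df[] <- lapply(df, function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write model parameters to JSON
#'
#' Flat key-value document with a `model` tag (`"plasma"` or
#' `"whole_blood"`).
#'
#' @param params A [plasma_params()] or [whole_blood_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  model <- if (inherits(params, "plasma_params")) "plasma"
           else if (inherits(params, "whole_blood_params")) "whole_blood"
           else stop("unsupported params object", call. = FALSE)
  doc <- c(list(model = model), unclass(params))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path Path to a document written by [write_params_json()].
#' @return A [plasma_params()] or [whole_blood_params()] object.
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$model)) stop("parameter JSON lacks a `model` tag", call. = FALSE)
  if (doc$model == "plasma")
    plasma_params(doc$K_np, doc$K_p, doc$K_dp)
  else if (doc$model == "whole_blood")
    whole_blood_params(doc$K_n1, doc$K_p1, doc$K_d1, doc$K_n2, doc$K_p2,
                       doc$K_d2)
  else stop(sprintf("unknown model tag '%s'", doc$model), call. = FALSE)
}

#' Write trained sparse maps to JSON
#'
#' One entry per parameter with support, coefficients, intercept and the
#' training standardization.
#'
#' @param maps Named list of `sparse_linear_map`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maps_json <- function(maps, path) {
  doc <- lapply(maps, function(m) list(
    target = m$target, feature_names = m$feature_names,
    support = m$support, coefficients = m$coefficients,
    intercept = m$intercept,
    standardization = list(mean = as.list(m$standardization$mean),
                           scale = as.list(m$standardization$scale))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read trained sparse maps from JSON
#'
#' @param path Path to a document written by [write_maps_json()].
#' @return Named list of `sparse_linear_map`s.
#' @export
read_maps_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  maps <- lapply(doc, function(m) {
    structure(list(target = m$target,
                   feature_names = as.character(m$feature_names),
                   support = as.integer(m$support),
                   coefficients = as.numeric(m$coefficients),
                   intercept = as.numeric(m$intercept),
                   standardization = list(
                     mean = unlist(m$standardization$mean),
                     scale = unlist(m$standardization$scale))),
              class = "sparse_linear_map")
  })
  names(maps) <- vapply(maps, `[[`, "", "target")
  maps
}

#' Write assay relations to a flat key-value config file
#'
#' Lines of the form `key = value`; illustrative entries are marked with a
#' trailing comment.
#'
#' @param relations An [assay_relations()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_relations_config <- function(relations, path) {
  stopifnot(inherits(relations, "assay_relations"))
  keys <- setdiff(names(relations), "illustrative")
  lines <- vapply(keys, function(k) {
    mark <- if (k %in% relations$illustrative)
      "  # illustrative - calibrate on data" else ""
    sprintf("%s = %.17g%s", k, relations[[k]], mark)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read assay relations from a flat key-value config file
#'
#' @param path Path to a file written by [write_relations_config()] (or
#'   hand-edited in the same `key = value` format; `#` starts a comment).
#' @return An [assay_relations()] object.
#' @export
read_relations_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(
    lapply(kv, function(p) as.numeric(p[2L])),
    vapply(kv, `[[`, "", 1L))
  do.call(assay_relations, vals)
}

#' Write the scalar TEG parameters of a curve as a one-row CSV
#'
#' Columns `R_min, K_min, alpha_deg, MA_mm, tMA_min, Ly30_pct, Gf_dyn_cm2`;
#' undefined values are empty cells and their reasons are concatenated in a
#' trailing `undefined_reasons` column.
#'
#' @param feats A [teg_scalar_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(feats, path) {
  stopifnot(inherits(feats, "teg_scalar_params"))
  gf <- if (!is.na(feats$MA) && feats$MA < 100) shear_elasticity(feats$MA)
        else NA_real_
  df <- data.frame(R_min = feats$R, K_min = feats$K, alpha_deg = feats$alpha,
                   MA_mm = feats$MA, tMA_min = feats$t_MA,
                   Ly30_pct = feats$Ly30, Gf_dyn_cm2 = gf,
                   undefined_reasons = paste(
                     sprintf("%s: %s", names(feats$reasons),
                             unlist(feats$reasons)), collapse = "; "))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
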