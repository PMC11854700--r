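# End-to-end orchestration: image -> apex estimate -> signal-heterogeneity
# quality gate -> alpha angle -> DDH verdict. Stage failures become verdict
# statuses, never crashes; disqualified frames still report their iliac
# angle (useful feedback for the sonographer) but carry no diagnosis.

#' Pipeline configuration
#'
#' All tunables of the image-processing stages in one place. Defaults are
#' the package's stated analysis conditions.
#'
#' @param neighborhood_px max-filter window side (odd, >= 3).
#' @param k_min minimum ilium ridge support points.
#' @param gate inclusive iliac-angle quality gate, degrees.
#' @param roof_side side toward which the roof descends.
#' @param roof_extent_x,roof_extent_y roof search-rectangle extents, pixels.
#' @param roof_min_intensity_frac bone-intensity screen for roof maxima.
#' @param roof_min_points minimum roof sector points.
#' @param cutoff_deg,ddh_rule DDH decision rule (see [classify_ddh()]).
#' @param min_confidence no-apex-signal threshold on the heatmap peak.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(neighborhood_px = 5L, k_min = 10L,
                            gate = c(87, 93),
                            roof_side = c("right", "left"),
                            roof_extent_x = 40L, roof_extent_y = 40L,
                            roof_min_intensity_frac = 0.5,
                            roof_min_points = 2L,
                            cutoff_deg = 60,
                            ddh_rule = c("strict", "inclusive"),
                            min_confidence = 0.2) {
  structure(list(neighborhood_px = as.integer(neighborhood_px),
                 k_min = as.integer(k_min), gate = gate,
                 roof_side = match.arg(roof_side),
                 roof_extent_x = as.integer(roof_extent_x),
                 roof_extent_y = as.integer(roof_extent_y),
                 roof_min_intensity_frac = roof_min_intensity_frac,
                 roof_min_points = as.integer(roof_min_points),
                 cutoff_deg = cutoff_deg, ddh_rule = match.arg(ddh_rule),
                 min_confidence = min_confidence),
            class = "pipeline_config")
}

#' Load / save a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config `pipeline_config`.
#' @return `read_pipeline_config`: a `pipeline_config`;
#'   `write_pipeline_config`: `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  o <- yaml::read_yaml(path)
  do.call(pipeline_config, o)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis on one frame
#'
#' Stages run in order — apex estimation, ROI ridge extraction and quality
#' gate, roof/alpha measurement, DDH classification — and any stage failure
#' short-circuits into the corresponding status: `no_apex_signal`,
#' `insufficient_ridge_support`, `disqualified` (gate failure; iliac angle
#' still reported), `roof_not_found` (roof edge missing or too little roof
#' support). Only `status == "ok"` frames carry an alpha angle and a DDH
#' verdict.
#'
#' @param image numeric 256x256 matrix.
#' @param apex an `apex_estimator`, an `apex_oracle`, or a bare `(x, y)`
#'   ground-truth apex (oracle mode).
#' @param config [pipeline_config()].
#' @return object of class `frame_verdict`: list `status`, `eap`,
#'   `confidence`, `quality` (`quality_result` or NULL), `alpha`
#'   (`alpha_result` or NULL).
#' @export
run_pipeline <- function(image, apex, config = pipeline_config()) {
  verdict <- function(status, eap = NULL, confidence = NA_real_,
                      quality = NULL, alpha = NULL)
    structure(list(status = status, eap = eap, confidence = confidence,
                   quality = quality, alpha = alpha),
              class = "frame_verdict")

  if (is.numeric(apex) && !inherits(apex, "apex_estimator"))
    apex <- apex_oracle(apex)
  est <- tryCatch(
    estimate_apex(apex, image, min_confidence = config$min_confidence),
    ddh_no_apex_signal = function(e) NULL)
  if (is.null(est)) return(verdict("no_apex_signal"))

  iliac <- tryCatch(
    measure_iliac(image, est$eap, config$neighborhood_px, config$k_min,
                  config$gate),
    ddh_error = function(e) NULL)
  if (is.null(iliac))
    return(verdict("insufficient_ridge_support", est$eap, est$confidence))
  if (!iliac$quality$qualified)
    return(verdict("disqualified", est$eap, est$confidence, iliac$quality))

  alpha <- tryCatch(
    measure_alpha(image, est$eap, iliac$line, config$roof_side,
                  config$roof_extent_x, config$roof_extent_y,
                  config$neighborhood_px, config$roof_min_intensity_frac,
                  config$roof_min_points, config$cutoff_deg, config$ddh_rule),
    ddh_error = function(e) NULL)
  if (is.null(alpha))
    return(verdict("roof_not_found", est$eap, est$confidence, iliac$quality))

  verdict("ok", est$eap, est$confidence, iliac$quality, alpha)
}

#' @export
print.frame_verdict <- function(x, ...) {
  cat("frame verdict:", x$status, "\n")
  if (!is.null(x$eap))
    cat(sprintf("  eAP (%.2f, %.2f), confidence %.3f\n",
                x$eap[1], x$eap[2], x$confidence))
  if (!is.null(x$quality))
    cat(sprintf("  iliac angle %.2f deg (%s)\n", x$quality$iliac_angle_deg,
                if (x$quality$qualified) "qualified" else "disqualified"))
  if (!is.null(x$alpha))
    cat(sprintf("  alpha %.2f deg -> %s\n", x$alpha$alpha_deg,
                if (x$alpha$ddh) "DDH" else "normal"))
  invisible(x)
}

verdict_row <- function(v) {
  data.frame(status = v$status,
             eap_x = if (is.null(v$eap)) NA_real_ else v$eap[1],
             eap_y = if (is.null(v$eap)) NA_real_ else v$eap[2],
             iliac_angle_deg = if (is.null(v$quality)) NA_real_
                               else v$quality$iliac_angle_deg,
             qualified = if (is.null(v$quality)) NA else v$quality$qualified,
             alpha_deg = if (is.null(v$alpha)) NA_real_ else v$alpha$alpha_deg,
             ddh = if (is.null(v$alpha)) NA else v$alpha$ddh,
             stringsAsFactors = FALSE)
}

#' Run the pipeline over a cohort
#'
#' Frames are processed independently; batch results are identical to
#' per-frame invocation. Apex source: `"oracle"` uses the ground-truth apex
#' carried by each frame (or the manifest `apex_x/apex_y`), otherwise pass
#' a trained `apex_estimator`.
#'
#' @param frames list of frames (`generate_cohort()` output) or a manifest
#'   data.frame whose `path` column points at PNG images.
#' @param apex `"oracle"` or an `apex_estimator`.
#' @param config [pipeline_config()].
#' @param log optional connection or path: one JSON line per frame.
#' @return data.frame, one verdict row per frame.
#' @export
run_pipeline_batch <- function(frames, apex = "oracle",
                               config = pipeline_config(), log = NULL) {
  if (is.data.frame(frames)) {
    manifest <- frames
    frames <- lapply(seq_len(nrow(manifest)), function(i) {
      list(image = preprocess_image(read_image_png(manifest$path[i]))$image,
           truth = list(apex = c(manifest$apex_x[i], manifest$apex_y[i])))
    })
  }
  con <- NULL
  if (!is.null(log)) {
    con <- if (inherits(log, "connection")) log else file(log, "w")
    if (!inherits(log, "connection")) on.exit(close(con))
  }
  rows <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    ap <- if (identical(apex, "oracle")) f$truth$apex else apex
    t0 <- proc.time()[["elapsed"]]
    v <- run_pipeline(f$image, ap, config)
    row <- verdict_row(v)
    if (!is.null(con))
      writeLines(jsonlite::toJSON(
        c(list(frame = i, elapsed_s = round(proc.time()[["elapsed"]] - t0, 4)),
          as.list(row)), auto_unbox = TRUE, digits = NA), con)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
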