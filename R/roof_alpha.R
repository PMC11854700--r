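# Acetabular-roof analysis: locate the roof edge inside a search rectangle
# infero-medial to the apex, select roof maxima in the closed sector between
# the horizontal ray and the 45-degree-below-horizontal ray from that edge,
# fit the roof ridge line, form the alpha angle with the ilium line, and
# classify DDH.

#' Search rectangle for the acetabular-roof edge
#'
#' The roof begins infero-medial to the apex, so the rectangle extends from
#' the eAP `extent_x` pixels toward the roof side and `extent_y` pixels
#' deeper (+y). Half-open `[min, max)` bounds, clipped to the image.
#'
#' @param eap `(x, y)` estimated apex.
#' @param shape image `(width, height)`.
#' @param extent_x,extent_y rectangle extents in pixels.
#' @param roof_side `"right"` or `"left"`.
#' @return `roi_spec` for the rectangle.
#' @export
roof_search_rect <- function(eap, shape, extent_x = 40L, extent_y = 40L,
                             roof_side = c("right", "left")) {
  roof_side <- match.arg(roof_side)
  cx <- floor(eap[1] + 0.5); cy <- floor(eap[2] + 0.5)
  if (roof_side == "right")
    r <- roi_spec(cx, cx + extent_x, cy, cy + extent_y, shape)
  else
    r <- roi_spec(cx - extent_x + 1L, cx + 1L, cy, cy + extent_y, shape)
  if (r$x_max <= r$x_min || r$y_max <= r$y_min)
    stop(ddh_condition("ddh_roof_not_found",
                       "roof search rectangle is empty after clipping"))
  r
}

#' Locate the acetabular-roof edge
#'
#' The roof edge is the local maximum with the lowest numeric y-coordinate
#' (topmost on screen) inside the search rectangle; ties are broken toward
#' the point nearest the eAP in x.
#'
#' @param maxima data.frame of local maxima (from [detect_local_maxima()]
#'   over the search rectangle).
#' @param eap `(x, y)` estimated apex, used only for tie-breaking.
#' @return `(x, y)` of the edge point.
#' @export
find_roof_edge <- function(maxima, eap) {
  if (is.null(maxima) || nrow(maxima) == 0L)
    stop(ddh_condition("ddh_roof_not_found",
                       "no local maxima in the roof search rectangle"))
  o <- order(maxima$y, abs(maxima$x - eap[1]))
  unname(unlist(maxima[o[1], c("x", "y")]))
}

#' Select roof maxima in the horizontal-to-45-degree sector
#'
#' Keeps local maxima `p` lying strictly toward the roof side of the edge
#' `e` and inside the closed sector between the horizontal ray and the
#' 45-degree-below-horizontal ray from `e`:
#' `s (p_x - e_x) > 0` and `0 <= (p_y - e_y) <= s (p_x - e_x)`, with
#' `s = +1` for `roof_side = "right"` and `-1` for `"left"`.
#'
#' @param edge `(x, y)` roof edge.
#' @param maxima data.frame of local maxima.
#' @param roof_side `"right"` or `"left"`.
#' @param min_points minimum surviving points (< that is an
#'   "insufficient roof support" failure).
#' @return data.frame `(x, y, intensity)` of selected points.
#' @export
select_roof_points <- function(edge, maxima, roof_side = c("right", "left"),
                               min_points = 2L) {
  roof_side <- match.arg(roof_side)
  s <- if (roof_side == "right") 1 else -1
  dx <- s * (maxima$x - edge[1])
  dy <- maxima$y - edge[2]
  keep <- dx > 0 & dy >= 0 & dy <= dx
  out <- maxima[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) < min_points)
    stop(ddh_condition("ddh_insufficient_roof_support",
                       sprintf("insufficient roof support: %d points", nrow(out))))
  out
}

#' Thin roof maxima to the topmost point per image column
#'
#' The acetabular roof is the superior boundary of the bone in the sector;
#' reverberation echoes are displaced copies of the bone lying deeper, so
#' for each column only the topmost (minimum-y) candidate is a roof point
#' (ties broken toward the higher intensity). The mirror image of the
#' per-row thinning applied to the near-vertical ilium.
#'
#' @param points data.frame `(x, y, intensity)` of sector maxima.
#' @return thinned data.frame, one row per image column.
#' @export
thin_roof_points <- function(points) {
  if (is.null(points) || nrow(points) == 0L) return(points)
  o <- order(points$x, points$y, -points$intensity)
  out <- points[o, , drop = FALSE]
  out <- out[!duplicated(out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus selection of roof points anchored at the roof edge
#'
#' The roof ridge line passes close to its own edge point, while
#' reverberation echoes (displaced copies of the bone lying deeper) and
#' distractor streaks form separate alignments. Each candidate defines a
#' putative roof line through the edge; the candidate whose line collects
#' the most perpendicular inliers (within `tol_px`) wins, and its inliers
#' are returned. With at most a few dozen sector maxima the exhaustive
#' search is exact and deterministic.
#'
#' @param edge `(x, y)` roof edge.
#' @param points data.frame `(x, y, intensity)` of sector candidates.
#' @param tol_px inlier tolerance, perpendicular pixels.
#' @return inlier subset of `points`.
#' @export
consensus_roof_points <- function(edge, points, tol_px = 2.5) {
  n <- nrow(points)
  if (is.null(points) || n < 3L) return(points)
  dx <- points$x - edge[1]; dy <- points$y - edge[2]
  len <- sqrt(dx^2 + dy^2)
  best <- NULL; best_n <- -1L
  for (i in which(len >= 3)) {
    # unsigned perpendicular distance to the edge->candidate line
    d <- abs(dx * dy[i] - dy * dx[i]) / len[i]
    inl <- d <= tol_px
    if (sum(inl) > best_n) { best_n <- sum(inl); best <- inl }
  }
  if (is.null(best)) return(points)
  out <- points[best, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Alpha angle between the ilium and roof ridge lines
#'
#' The absolute difference of the two orientation angles, folded into
#' `[0, 90]` (a line has no preferred direction, so differences above 90
#' map to their supplement).
#'
#' @param ilium,roof `ridge_line` objects (or plain orientation angles in
#'   degrees).
#' @return alpha angle in degrees.
#' @export
compute_alpha <- function(ilium, roof) {
  a1 <- if (inherits(ilium, "ridge_line")) ilium$angle_deg else ilium
  a2 <- if (inherits(roof, "ridge_line")) roof$angle_deg else roof
  d <- abs(a1 - a2) %% 180
  min(d, 180 - d)
}

#' Classify DDH from the alpha angle
#'
#' DDH is a shallow bony roof: alpha below 60 degrees. The default rule is
#' the strict inequality `alpha < 60`; `rule = "inclusive"` uses
#' `alpha <= 60` (the screening cut-off reading).
#'
#' @param alpha_deg alpha angle in degrees.
#' @param cutoff_deg decision threshold (default 60).
#' @param rule `"strict"` (`<`) or `"inclusive"` (`<=`).
#' @return logical: TRUE if DDH.
#' @export
classify_ddh <- function(alpha_deg, cutoff_deg = 60,
                         rule = c("strict", "inclusive")) {
  rule <- match.arg(rule)
  if (rule == "strict") alpha_deg < cutoff_deg else alpha_deg <= cutoff_deg
}

#' Measure the alpha angle from a frame
#'
#' Full roof stage: local maxima in the search rectangle, intensity
#' screening (see Details), roof-edge detection, sector selection, roof
#' ridge-line fit, alpha angle and DDH classification.
#'
#' Speckle produces spurious low-intensity local maxima throughout the
#' rectangle; since the roof analysis targets the bright bone ridge, maxima
#' below `min_intensity_frac` times the brightest maximum in the rectangle
#' are screened out before edge detection and sector selection.
#'
#' @param image numeric matrix (preprocessed frame).
#' @param eap `(x, y)` estimated apex.
#' @param ilium `ridge_line` of the ilium (from [measure_iliac()]).
#' @param roof_side `"right"` or `"left"`.
#' @param extent_x,extent_y search-rectangle extents.
#' @param neighborhood_px max-filter window side.
#' @param min_intensity_frac bone-intensity screen as a fraction of the
#'   brightest maximum in the rectangle.
#' @param min_points minimum sector points for the roof fit.
#' @param cutoff_deg,rule DDH decision rule, see [classify_ddh()].
#' @return object of class `alpha_result`: list `roof_edge`, `roof_line`,
#'   `alpha_deg`, `ddh`, `n_roof_points`.
#' @export
measure_alpha <- function(image, eap, ilium, roof_side = c("right", "left"),
                          extent_x = 40L, extent_y = 40L,
                          neighborhood_px = 5L, min_intensity_frac = 0.5,
                          min_points = 2L, cutoff_deg = 60,
                          rule = c("strict", "inclusive")) {
  roof_side <- match.arg(roof_side)
  rule <- match.arg(rule)
  rect <- roof_search_rect(eap, c(ncol(image), nrow(image)),
                           extent_x, extent_y, roof_side)
  maxima <- detect_local_maxima(image, rect, neighborhood_px)
  if (nrow(maxima) == 0L)
    stop(ddh_condition("ddh_roof_not_found",
                       "no local maxima in the roof search rectangle"))
  bright <- maxima[maxima$intensity >= min_intensity_frac * max(maxima$intensity), ,
                   drop = FALSE]
  edge <- find_roof_edge(bright, eap)
  pts <- select_roof_points(edge, bright, roof_side, min_points)
  pts <- thin_roof_points(pts)
  pts <- consensus_roof_points(edge, pts)
  if (nrow(pts) < min_points)
    stop(ddh_condition("ddh_insufficient_roof_support",
                       sprintf("insufficient roof support: %d points", nrow(pts))))
  roof_line <- fit_line_robust(pts)
  kept <- attr(roof_line, "points")
  # leave a 3-px guard next to the apex column where the ilium band overlaps
  lo <- min(kept$x) + if (roof_side == "right") 3L else 0L
  hi <- max(kept$x) - if (roof_side == "left") 3L else 0L
  # +-3 window: a 45-degree band crossed vertically is ~sqrt(2) thicker
  # than the line profile, and echoes sit a reverberation period away
  if (hi - lo >= 2L)
    roof_line <- refine_line_centroid(image, rect, roof_line,
                                      span = lo:hi, halfwidth = 3L,
                                      along = "cols")
  roof_line$n_points <- nrow(kept)
  alpha <- compute_alpha(ilium, roof_line)
  structure(list(roof_edge = edge, roof_line = roof_line,
                 alpha_deg = alpha,
                 ddh = classify_ddh(alpha, cutoff_deg, rule),
                 n_roof_points = nrow(pts)),
            class = "alpha_result")
}

#' @export
print.alpha_result <- function(x, ...) {
  cat(sprintf("alpha %.2f deg (%s), roof edge (%.0f, %.0f), %d roof points\n",
              x$alpha_deg, if (x$ddh) "DDH" else "normal",
              x$roof_edge[1], x$roof_edge[2], x$n_roof_points))
  invisible(x)
}
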