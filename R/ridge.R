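# Signal-heterogeneity analysis of the bone region: a narrow ROI above the
# estimated apex point, local-maximum detection by max-filter + equality
# masking, per-row thinning, orthogonal least-squares ridge-line fitting and
# the iliac-verticality quality gate.

ddh_condition <- function(class, message) {
  structure(class = c(class, "ddh_error", "error", "condition"),
            list(message = message, call = sys.call(-1)))
}

#' Region of interest above the estimated apex
#'
#' The ROI is 10 pixels wide, centred in x on the estimated apex (eAP),
#' unbounded above (y starts at 0), and ends 5 pixels below the eAP's
#' y-coordinate, so it contains the ilium and the true apex even when the
#' estimate is a few pixels off. Intervals are half-open `[min, max)` in
#' 0-based integer pixel indices; the spec width of 10 means 10 columns.
#'
#' @param eap `(x, y)` estimated apex, 0-based continuous pixels.
#' @param shape image `(width, height)` in pixels.
#' @param width ROI width in columns.
#' @param below pixels of ROI below the eAP y-coordinate.
#' @return object of class `roi_spec`: list `x_min, x_max, y_min, y_max`
#'   (half-open bounds, clipped to the image).
#' @export
build_roi <- function(eap, shape, width = 10L, below = 5L) {
  w <- shape[1]; h <- shape[2]
  if (eap[1] < 0 || eap[1] > w - 1 || eap[2] < 0 || eap[2] > h - 1)
    stop("eAP lies outside the image")
  cx <- floor(eap[1] + 0.5)
  x_min <- max(0L, cx - width %/% 2L)
  x_max <- min(w, cx + width - width %/% 2L)
  y_max <- min(h, floor(eap[2] + 0.5) + below)
  structure(list(x_min = as.integer(x_min), x_max = as.integer(x_max),
                 y_min = 0L, y_max = as.integer(y_max)),
            class = "roi_spec")
}

roi_spec <- function(x_min, x_max, y_min, y_max, shape = NULL) {
  if (!is.null(shape)) {
    x_min <- max(0L, x_min); y_min <- max(0L, y_min)
    x_max <- min(shape[1], x_max); y_max <- min(shape[2], y_max)
  }
  structure(list(x_min = as.integer(x_min), x_max = as.integer(x_max),
                 y_min = as.integer(y_min), y_max = as.integer(y_max)),
            class = "roi_spec")
}

# Square max filter (side n) with -Inf padding, via shift-and-pmax.
max_filter <- function(img, n) {
  r <- (n - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  out <- matrix(-Inf, h, w)
  for (dy in -r:r) {
    ys <- seq_len(h) + dy
    ok_y <- ys >= 1L & ys <= h
    for (dx in -r:r) {
      xs <- seq_len(w) + dx
      ok_x <- xs >= 1L & xs <= w
      sub <- matrix(-Inf, h, w)
      sub[ok_y, ok_x] <- img[ys[ok_y], xs[ok_x]]
      out <- pmax(out, sub)
    }
  }
  out
}

#' Detect points of locally maximal intensity inside an ROI
#'
#' The classical max-filter construction: the image is filtered with a
#' square maximum filter of side `neighborhood_px` and masked against the
#' original — pixels whose value equals the filtered value (and is positive)
#' are local maxima. Plateaus are kept in full; the selection stages thin
#' them. The filter window sees the whole image, so maxima near the ROI
#' border are judged against their true neighborhoods.
#'
#' @param image numeric matrix.
#' @param roi `roi_spec` bounds.
#' @param neighborhood_px odd window side, >= 3.
#' @return data.frame `(x, y, intensity)` of maxima (0-based coordinates).
#' @export
detect_local_maxima <- function(image, roi, neighborhood_px = 5L) {
  if (neighborhood_px < 3L || neighborhood_px %% 2L == 0L)
    stop("neighborhood_px must be odd and >= 3")
  if (roi$x_max <= roi$x_min || roi$y_max <= roi$y_min)
    stop(ddh_condition("ddh_empty_roi", "ROI is empty after clipping"))
  mf <- max_filter(image, neighborhood_px)
  rows <- (roi$y_min + 1L):roi$y_max
  cols <- (roi$x_min + 1L):roi$x_max
  sub <- image[rows, cols, drop = FALSE]
  hit <- sub == mf[rows, cols, drop = FALSE] & sub > 0
  idx <- which(hit, arr.ind = TRUE)
  df <- data.frame(x = cols[idx[, 2]] - 1L, y = rows[idx[, 1]] - 1L,
                   intensity = sub[idx])
  df <- df[order(df$y, df$x), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "neighborhood_px") <- as.integer(neighborhood_px)
  df
}

#' Thin ilium maxima to one ridge point per image row
#'
#' Keeps, for each row, the local maximum of highest intensity (ties broken
#' toward the smallest x); rows without maxima are skipped. Fewer than
#' `k_min` surviving points is an "insufficient ridge support" failure and
#' the frame is disqualified upstream.
#'
#' When `roi` is supplied, rows whose winning candidate lies on (or ties
#' with a candidate on) the ROI's x border are dropped: a bright band whose
#' centre has drifted outside the narrow ROI still leaves plateau pixels
#' clipped at the border, and those clipped pixels would masquerade as
#' ridge points.
#'
#' @param maxima data.frame from [detect_local_maxima()].
#' @param roi optional `roi_spec` the maxima were detected in.
#' @param k_min minimum number of ridge points.
#' @return data.frame `(x, y, intensity)`, one row per image row.
#' @export
select_ilium_points <- function(maxima, roi = NULL, k_min = 10L) {
  if (is.null(maxima) || nrow(maxima) == 0L)
    stop(ddh_condition("ddh_insufficient_ridge_support",
                       "no local maxima to select from"))
  o <- order(maxima$y, -maxima$intensity, maxima$x)
  m <- maxima[o, , drop = FALSE]
  keep <- m[!duplicated(m$y), , drop = FALSE]
  if (!is.null(roi)) {
    border <- maxima$x == roi$x_min | maxima$x == roi$x_max - 1L
    bad_rows <- unique(maxima$y[border][
      maxima$intensity[border] >= keep$intensity[match(maxima$y[border], keep$y)]])
    keep <- keep[!(keep$y %in% bad_rows), , drop = FALSE]
  }
  rownames(keep) <- NULL
  if (nrow(keep) < k_min)
    stop(ddh_condition("ddh_insufficient_ridge_support",
                       sprintf("insufficient ridge support: %d points < k_min = %d",
                               nrow(keep), k_min)))
  keep
}

#' Fit a ridge line by orthogonal (total) least squares
#'
#' The line minimising the sum of squared perpendicular distances: anchored
#' at the centroid, directed along the principal axis of the centred
#' points. Ordinary y-on-x regression is ill-conditioned for the
#' near-vertical ilium, hence total least squares.
#'
#' @param points data.frame or matrix with columns/entries `x`, `y`.
#' @return object of class `ridge_line`: list `anchor` (centroid),
#'   `direction` (unit vector, screen coordinates), `angle_deg`
#'   (orientation in `[0, 180)` from the image horizontal, y down;
#'   90 = vertical).
#' @export
fit_line <- function(points) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  if (nrow(pts) < 2L) stop("need at least 2 points")
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  if (all(abs(cc) < 1e-12)) stop("all points coincident")
  cv <- crossprod(cc) / nrow(pts)
  eg <- eigen(cv, symmetric = TRUE)
  d <- eg$vectors[, 1]
  ang <- (atan2(d[2], d[1]) * 180 / pi) %% 180
  # canonical direction: the one whose screen angle equals angle_deg
  d <- c(cos(ang * pi / 180), sin(ang * pi / 180))
  structure(list(anchor = unname(ctr), direction = unname(d),
                 angle_deg = ang, n_points = nrow(pts)),
            class = "ridge_line")
}

#' Perpendicular residuals of points about a ridge line
#'
#' @param line `ridge_line`.
#' @param points data.frame with `x`, `y`.
#' @return numeric vector of unsigned perpendicular distances, pixels.
#' @export
line_residuals <- function(line, points) {
  dx <- points$x - line$anchor[1]
  dy <- points$y - line$anchor[2]
  abs(dx * line$direction[2] - dy * line$direction[1])
}

#' Trimmed orthogonal least-squares ridge fit
#'
#' Total least squares is sensitive to the structured outliers real frames
#' produce (distractor streaks crossing the ROI, reverberation copies of
#' the bone, band-edge pixels clipped by the ROI border). The standard
#' remedy: fit, drop points whose perpendicular residual exceeds
#' `resid_mult` times the median residual (floored at 1.5 px so exact fits
#' are not over-trimmed), refit; `trim_iter` rounds. Trimming never removes
#' more than half the points.
#'
#' @param points data.frame with `x`, `y`.
#' @param trim_iter trimming rounds (0 = plain TLS).
#' @param resid_mult residual multiplier for the trim threshold.
#' @return `ridge_line` fitted on the retained points; the retained points
#'   are attached as attribute `points`.
#' @export
fit_line_robust <- function(points, trim_iter = 2L, resid_mult = 2.5) {
  pts <- as.data.frame(points)
  line <- fit_line(pts)
  for (i in seq_len(trim_iter)) {
    r <- line_residuals(line, pts)
    thr <- max(resid_mult * stats::median(r), 1.5)
    keep <- r <= thr
    if (all(keep) || sum(keep) < max(2L, nrow(pts) %/% 2L)) break
    pts <- pts[keep, , drop = FALSE]
    line <- fit_line(pts)
  }
  attr(line, "points") <- pts
  line
}

#' @export
print.ridge_line <- function(x, ...) {
  cat(sprintf("ridge line: angle %.3f deg, anchor (%.2f, %.2f), n = %d\n",
              x$angle_deg, x$anchor[1], x$anchor[2], x$n_points))
  invisible(x)
}

#' Iliac-verticality quality gate
#'
#' A frame is a usable standard plane only if the fitted ilium line is close
#' to vertical; the gate accepts iliac angles in `[gate[1], gate[2]]`
#' degrees, bounds inclusive (default 87–93).
#'
#' @param line `ridge_line` of the ilium.
#' @param gate inclusive `(low, high)` bounds in degrees.
#' @return object of class `quality_result`: list `iliac_angle_deg`,
#'   `qualified`, `n_support_points`.
#' @export
assess_quality <- function(line, gate = c(87, 93)) {
  stopifnot(inherits(line, "ridge_line"), length(gate) == 2L, gate[1] <= gate[2])
  structure(list(iliac_angle_deg = line$angle_deg,
                 qualified = line$angle_deg >= gate[1] & line$angle_deg <= gate[2],
                 n_support_points = line$n_points),
            class = "quality_result")
}

#' Export an ROI as an (x, y, intensity) surface
#'
#' The 2D-to-3D transfer used for inspecting signal heterogeneity: one
#' triple per ROI pixel, sorted lexicographically by `(y, x)`; the original
#' ROI is reconstructible from the triples.
#'
#' @param image numeric matrix.
#' @param roi `roi_spec`.
#' @return data.frame `(x, y, intensity)`.
#' @export
export_intensity_surface <- function(image, roi) {
  if (roi$x_max <= roi$x_min || roi$y_max <= roi$y_min)
    stop(ddh_condition("ddh_empty_roi", "ROI is empty"))
  xs <- roi$x_min:(roi$x_max - 1L)
  ys <- roi$y_min:(roi$y_max - 1L)
  g <- expand.grid(x = xs, y = ys)          # x varies fastest => (y, x) sorted
  g$intensity <- image[cbind(g$y + 1L, g$x + 1L)]
  g[order(g$y, g$x), , drop = FALSE]
}

# Subpixel ridge refinement. The detected maxima are integer positions
# with up to +-(band half-width) speckle jitter; re-estimating the ridge
# position as the background-subtracted intensity centroid in a
# +-halfwidth window about the fitted line averages that jitter, and
# refitting tightens the angle. `along = "rows"` scans one centroid per
# image row (near-vertical ridges: the ilium); `along = "cols"` one per
# column (near-horizontal ridges: the roof). Positions spanned by the
# retained ridge points are used whether or not they produced a winning
# maximum.
refine_line_centroid <- function(image, roi, line, span, halfwidth = 2L,
                                 iters = 2L, along = c("rows", "cols")) {
  along <- match.arg(along)
  for (it in seq_len(iters)) {
    a <- if (along == "rows") 2L else 1L   # independent coordinate index
    b <- 3L - a
    if (abs(line$direction[a]) < 1e-6) break
    lim_lo <- if (along == "rows") roi$x_min else roi$y_min
    lim_hi <- if (along == "rows") roi$x_max else roi$y_max
    pos <- rep(NA_real_, length(span))
    for (k in seq_along(span)) {
      t <- span[k]
      c0 <- line$anchor[b] + (t - line$anchor[a]) *
        line$direction[b] / line$direction[a]
      lo <- max(lim_lo, floor(c0) - halfwidth)
      hi <- min(lim_hi - 1L, ceiling(c0) + halfwidth)
      if (hi < lo) next
      cs <- lo:hi
      v <- if (along == "rows") image[t + 1L, cs + 1L] else image[cs + 1L, t + 1L]
      wt <- v - min(v)
      if (sum(wt) <= 0) next
      pos[k] <- sum(wt * cs) / sum(wt)
    }
    ok <- !is.na(pos)
    if (sum(ok) < 2L) break
    pts <- if (along == "rows") data.frame(x = pos[ok], y = span[ok])
           else data.frame(x = span[ok], y = pos[ok])
    line <- fit_line(pts)
  }
  line
}

#' Measure the iliac angle and gate a frame
#'
#' Convenience composition of [build_roi()], [detect_local_maxima()],
#' [select_ilium_points()], [fit_line()] and [assess_quality()].
#'
#' Since the analysis targets the bright bone ridge, maxima dimmer than
#' `min_intensity_frac` times the brightest maximum in the ROI (background
#' speckle, soft tissue) are screened out before the per-row selection.
#'
#' @param image numeric matrix (preprocessed frame).
#' @param eap `(x, y)` estimated apex.
#' @param neighborhood_px max-filter window side.
#' @param k_min minimum ridge support.
#' @param gate quality gate bounds, degrees.
#' @param min_intensity_frac bone-intensity screen as a fraction of the
#'   brightest maximum in the ROI.
#' @return list `quality` (`quality_result`), `line` (`ridge_line`),
#'   `points` (selected ridge points), `roi`.
#' @export
measure_iliac <- function(image, eap, neighborhood_px = 5L, k_min = 10L,
                          gate = c(87, 93), min_intensity_frac = 0.5) {
  roi <- build_roi(eap, c(ncol(image), nrow(image)))
  maxima <- detect_local_maxima(image, roi, neighborhood_px)
  bright <- maxima
  if (nrow(maxima) > 0L)
    bright <- maxima[maxima$intensity >=
                       min_intensity_frac * max(maxima$intensity), ,
                     drop = FALSE]
  pts <- select_ilium_points(bright, roi, k_min)
  line <- fit_line_robust(pts)
  kept <- attr(line, "points")
  # refine on rows above the apex only: the roof emanates just below it
  # and would drag the row centroids sideways
  top <- min(kept$y)
  bot <- min(max(kept$y), floor(eap[2]))
  line <- refine_line_centroid(image, roi, line,
                               span = top:max(bot, top + 1L), along = "rows")
  line$n_points <- nrow(kept)
  list(quality = assess_quality(line, gate), line = line,
       points = pts, roi = roi, maxima = maxima)
}
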