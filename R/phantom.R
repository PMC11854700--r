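# Synthetic B-mode phantom generator. Frames contain a bright near-vertical
# ilium segment terminating at a known apex point and an oblique acetabular
# roof segment forming a controlled alpha angle, degraded by the artifact
# classes that plague clinical hip ultrasound: multiplicative speckle,
# reverberation echoes below bone, soft-tissue distractor streaks, blur.
# Every generating parameter is recorded as ground truth, so the phantom is
# the oracle for the downstream apex / ridge / alpha stages.

#' Parameters of a synthetic hip-ultrasound phantom
#'
#' Defaults describe a plausible coronal standard-plane frame at the 256x256
#' analysis resolution: a vertical ilium (90 degrees), a healthy roof
#' (alpha 65 degrees), moderate speckle, three reverberation echoes and two
#' soft-tissue distractor streaks.
#'
#' @param image_size `(width, height)` in pixels.
#' @param apex `(x, y)` apex point, 0-based continuous pixel coordinates.
#' @param iliac_angle_deg orientation of the ilium line in degrees from the
#'   image horizontal (90 = vertical); must lie in (60, 120).
#' @param alpha_deg angle between the ilium line and the acetabular-roof
#'   line, degrees, in (0, 90). Values below 60 define DDH.
#' @param ilium_intensity,roof_intensity peak line intensities in `[0, 255]`.
#' @param line_thickness_px full width of the Gaussian cross-profile of the
#'   bone lines, pixels.
#' @param speckle_scale scale of the multiplicative Rayleigh speckle field
#'   (0 disables speckle).
#' @param reverb_count number of reverberation echoes below the bone.
#' @param reverb_spacing_px depth offset between successive echoes, pixels.
#' @param reverb_decay per-echo intensity multiplier in (0, 1).
#' @param distractor_count number of random soft-tissue streaks.
#' @param blur_sigma_px Gaussian blur applied to the clean scene, pixels
#'   (0 disables).
#' @param background_noise_sd additive Gaussian background noise, intensity
#'   units.
#' @param roof_side side toward which the roof descends, `"left"`/`"right"`.
#' @param roof_offset_px distance from the apex to the start of the roof
#'   segment, measured along the roof direction (the roof edge sits
#'   infero-medial to the apex, so the roof-edge search is nontrivial).
#' @param roof_length_px length of the roof segment, pixels.
#' @param ilium_length_px length of the ilium segment above the apex,
#'   pixels.
#' @param rater_noise_sd_qualified,rater_noise_sd_disqualified standard
#'   deviation (degrees) of simulated human alpha measurements on qualified
#'   and disqualified frames.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   images.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = c(256L, 256L),
                           apex = c(128, 120),
                           iliac_angle_deg = 90,
                           alpha_deg = 65,
                           ilium_intensity = 220,
                           roof_intensity = 200,
                           line_thickness_px = 3,
                           speckle_scale = 0.3,
                           reverb_count = 3L,
                           reverb_spacing_px = 12,
                           reverb_decay = 0.5,
                           distractor_count = 2L,
                           blur_sigma_px = 1,
                           background_noise_sd = 2,
                           roof_side = c("right", "left"),
                           roof_offset_px = 3,
                           roof_length_px = 55,
                           ilium_length_px = 120,
                           rater_noise_sd_qualified = 1,
                           rater_noise_sd_disqualified = 4,
                           seed = 1L) {
  roof_side <- match.arg(roof_side)
  p <- list(image_size = as.integer(image_size), apex = as.numeric(apex),
            iliac_angle_deg = iliac_angle_deg, alpha_deg = alpha_deg,
            ilium_intensity = ilium_intensity, roof_intensity = roof_intensity,
            line_thickness_px = line_thickness_px,
            speckle_scale = speckle_scale, reverb_count = as.integer(reverb_count),
            reverb_spacing_px = reverb_spacing_px, reverb_decay = reverb_decay,
            distractor_count = as.integer(distractor_count),
            blur_sigma_px = blur_sigma_px,
            background_noise_sd = background_noise_sd,
            roof_side = roof_side, roof_offset_px = roof_offset_px,
            roof_length_px = roof_length_px, ilium_length_px = ilium_length_px,
            rater_noise_sd_qualified = rater_noise_sd_qualified,
            rater_noise_sd_disqualified = rater_noise_sd_disqualified,
            seed = as.integer(seed))
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  stopifnot(length(p$image_size) == 2L, all(p$image_size >= 32L))
  if (!(p$alpha_deg > 0 && p$alpha_deg < 90))
    stop("alpha_deg must lie in (0, 90)")
  if (!(p$iliac_angle_deg > 60 && p$iliac_angle_deg < 120))
    stop("iliac_angle_deg must lie in (60, 120)")
  for (f in c("ilium_intensity", "roof_intensity"))
    if (p[[f]] < 0 || p[[f]] > 255) stop(f, " must lie in [0, 255]")
  if (p$reverb_count < 0L) stop("reverb_count must be >= 0")
  if (p$reverb_count > 0L && !(p$reverb_decay > 0 && p$reverb_decay < 1))
    stop("reverb_decay must lie in (0, 1)")
  if (p$distractor_count < 0L) stop("distractor_count must be >= 0")
  if (p$speckle_scale < 0) stop("speckle_scale must be >= 0")
  if (p$blur_sigma_px < 0) stop("blur_sigma_px must be >= 0")
  geo <- phantom_scene(p)
  w <- p$image_size[1]; h <- p$image_size[2]
  inside <- function(q) q[1] >= 0 && q[1] <= w - 1 && q[2] >= 0 && q[2] <= h - 1
  if (!inside(p$apex)) stop("apex lies outside the frame")
  if (!inside(geo$roof[[1]]) || !inside(geo$roof[[2]]))
    stop("roof segment lies outside the frame")
  invisible(p)
}

#' Disable every noise source of a phantom
#'
#' Convenience used by tests and examples: zeroes speckle, reverberation,
#' distractors, blur and background noise so the scene is the pure geometric
#' construction.
#'
#' @param params `phantom_params` object (or arguments forwarded to
#'   [phantom_params()]).
#' @return modified `phantom_params`.
#' @export
noise_free <- function(params = phantom_params()) {
  params$speckle_scale <- 0
  params$reverb_count <- 0L
  params$distractor_count <- 0L
  params$blur_sigma_px <- 0
  params$background_noise_sd <- 0
  params
}

# Scene geometry (segment endpoints) implied by the parameters, in 0-based
# (x, y) screen coordinates. Orientation convention: angle from +x with y
# downward, so the ilium direction is (cos t, sin t) and the upward half of
# the line carries the bone.
phantom_scene <- function(p) {
  t_i <- p$iliac_angle_deg * pi / 180
  d_i <- c(cos(t_i), sin(t_i))            # along the ilium line, downward half
  apex <- p$apex
  ilium <- list(apex - p$ilium_length_px * d_i, apex)
  s <- if (p$roof_side == "right") 1 else -1
  phi <- (p$iliac_angle_deg - s * p$alpha_deg) * pi / 180
  d_r <- c(cos(phi), sin(phi))
  if (s < 0) d_r <- -d_r                   # descend toward the roof side
  roof <- list(apex + p$roof_offset_px * d_r,
               apex + (p$roof_offset_px + p$roof_length_px) * d_r)
  list(ilium = ilium, roof = roof,
       roof_angle_deg = ((phi * 180 / pi) %% 180))
}

# Distance from every pixel centre to a segment, vectorised over the grid.
segment_distance <- function(X, Y, p0, p1) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  L2 <- vx^2 + vy^2
  if (L2 == 0) return(sqrt((X - p0[1])^2 + (Y - p0[2])^2))
  t <- ((X - p0[1]) * vx + (Y - p0[2]) * vy) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((X - (p0[1] + t * vx))^2 + (Y - (p0[2] + t * vy))^2)
}

# Render a segment as a flat-top streak with a soft Gaussian shoulder and
# blend by maximum (bright structures occlude, they do not sum). The flat
# top emulates the saturated specular band of cortical bone under log
# compression, and gives the ridge a plateau along the line — the regime
# the equality-masking local-maximum detector is designed for.
draw_segment <- function(canvas, X, Y, p0, p1, intensity, thickness) {
  half <- thickness / 2
  shoulder <- 0.75
  d <- segment_distance(X, Y, p0, p1)
  excess <- pmax(d - half, 0)
  pmax(canvas, intensity * exp(-excess^2 / (2 * shoulder^2)))
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (j in seq_along(k)) {             # vertical pass, replicate edges
    idx <- pmin(pmax(seq_len(h) + (j - r - 1L), 1L), h)
    out <- out + k[j] * img[idx, , drop = FALSE]
  }
  img <- out; out <- matrix(0, h, w)
  for (j in seq_along(k)) {             # horizontal pass
    idx <- pmin(pmax(seq_len(w) + (j - r - 1L), 1L), w)
    out <- out + k[j] * img[, idx, drop = FALSE]
  }
  out
}

#' Generate a synthetic B-mode frame with ground truth
#'
#' Renders the bone scene (ilium segment ending at the apex, roof segment
#' starting just infero-medial to it), adds `reverb_count` attenuated copies
#' of the bone displaced deeper (+y) by multiples of `reverb_spacing_px`,
#' random soft-tissue streaks, Gaussian blur, multiplicative Rayleigh
#' speckle and additive background noise, then clips to `[0, 255]`.
#'
#' @param params a [phantom_params()] object.
#' @return list with `image` (numeric matrix) and `truth`
#'   (`phantom_truth`: apex, iliac_angle_deg, alpha_deg, ddh_label,
#'   qualified_label, scene segment endpoints).
#' @export
generate_phantom <- function(params = phantom_params()) {
  p <- validate_phantom_params(params)
  w <- p$image_size[1]; h <- p$image_size[2]
  geo <- phantom_scene(p)

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(p$seed)
    expr
  }

  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)

  img <- withr_seed({
    canvas <- matrix(15, h, w)                       # soft-tissue floor
    segs <- list(list(geo$ilium, p$ilium_intensity),
                 list(geo$roof, p$roof_intensity))
    for (s in segs)
      canvas <- draw_segment(canvas, X, Y, s[[1]][[1]], s[[1]][[2]],
                             s[[2]], p$line_thickness_px)
    if (p$reverb_count > 0L)
      for (k in seq_len(p$reverb_count)) {
        dy <- c(0, k * p$reverb_spacing_px)
        gain <- p$reverb_decay^k
        for (s in segs)
          canvas <- draw_segment(canvas, X, Y, s[[1]][[1]] + dy,
                                 s[[1]][[2]] + dy, s[[2]] * gain,
                                 p$line_thickness_px)
      }
    if (p$distractor_count > 0L)
      for (k in seq_len(p$distractor_count)) {
        q0 <- c(runif(1, 0, w - 1), runif(1, 0, h - 1))
        ang <- runif(1, 0, pi); len <- runif(1, 30, 90)
        q1 <- q0 + len * c(cos(ang), sin(ang))
        canvas <- draw_segment(canvas, X, Y, q0, q1,
                               runif(1, 60, 140), runif(1, 2, 5))
      }
    canvas <- gaussian_blur(canvas, p$blur_sigma_px)
    if (p$speckle_scale > 0) {
      # Rayleigh field with unit mean: sigma * sqrt(-2 log U), sigma = sqrt(2/pi)
      R <- sqrt(2 / pi) * sqrt(-2 * log(matrix(runif(h * w), h, w)))
      canvas <- canvas * (1 + p$speckle_scale * (R - 1))
    }
    if (p$background_noise_sd > 0)
      canvas <- canvas + matrix(rnorm(h * w, 0, p$background_noise_sd), h, w)
    pmin(pmax(canvas, 0), 255)
  })

  truth <- structure(list(
    apex = p$apex,
    iliac_angle_deg = p$iliac_angle_deg,
    alpha_deg = p$alpha_deg,
    ddh_label = is_ddh_alpha(p$alpha_deg),
    qualified_label = is_qualified_angle(p$iliac_angle_deg),
    roof_side = p$roof_side,
    scene = geo,
    seed = p$seed), class = "phantom_truth")
  list(image = img, truth = truth)
}

#' Label helpers shared by generator and classifier
#'
#' `is_ddh_alpha`: DDH iff alpha < 60 degrees (strictly). `is_qualified_angle`:
#' standard-plane quality iff the iliac angle lies in `[87, 93]`, bounds
#' inclusive.
#'
#' @param alpha_deg,iliac_angle_deg angles in degrees.
#' @return logical.
#' @export
is_ddh_alpha <- function(alpha_deg) alpha_deg < 60

#' @rdname is_ddh_alpha
#' @export
is_qualified_angle <- function(iliac_angle_deg)
  iliac_angle_deg >= 87 & iliac_angle_deg <= 93

#' Simulate repeated human alpha measurements for a frame
#'
#' Emulates the reliability study design: `n_raters` observers each measure
#' the alpha angle `n_repeats` times; measurement noise is Gaussian with a
#' standard deviation that depends on frame quality (disqualified frames are
#' harder to measure, so their sd is larger).
#'
#' @param alpha_deg true alpha angle.
#' @param qualified logical quality flag.
#' @param sd_qualified,sd_disqualified noise sd, degrees.
#' @param n_raters,n_repeats design of the reliability study.
#' @return matrix `n_raters` x `n_repeats` of measured angles.
#' @export
simulate_rater_alphas <- function(alpha_deg, qualified,
                                  sd_qualified = 1, sd_disqualified = 4,
                                  n_raters = 2L, n_repeats = 2L) {
  sd <- if (qualified) sd_qualified else sd_disqualified
  matrix(alpha_deg + rnorm(n_raters * n_repeats, 0, sd), n_raters, n_repeats)
}

#' Generate a cohort of phantoms
#'
#' Samples per-frame parameters from the supplied ranges (scalar = fixed,
#' length-2 = uniform), generates each frame with a per-frame seed derived
#' from `seed`, and returns the frames plus a manifest. When `dir` is given,
#' images are written as PNG and the manifest as `manifest.csv`.
#'
#' Default ranges describe the screening population the package emulates:
#' iliac angle Uniform(80, 100) — roughly a third of frames qualified —
#' alpha Uniform(45, 75), straddling the 60-degree DDH threshold, and the
#' apex point uniform over the central part of the frame (`apex_x` in
#' (100, 156), `apex_y` in (90, 150)).
#'
#' @param n number of frames (>= 1).
#' @param ranges named list overriding sampling ranges for any
#'   [phantom_params()] field (e.g. `list(alpha_deg = c(50, 70))`); the
#'   apex coordinates are addressed as `apex_x` and `apex_y`.
#' @param seed integer master seed.
#' @param dir optional output directory.
#' @param noise if FALSE, every frame is generated with all noise sources
#'   disabled (see [noise_free()]).
#' @param render if FALSE, skip image synthesis and return ground truth and
#'   manifest only (fast path for statistical simulations).
#' @param raters if TRUE, attach simulated rater alpha measurements
#'   (`rater_r<j>_m<k>` manifest columns) drawn with the quality-dependent
#'   noise sds.
#' @return list with `frames` (list of `generate_phantom` outputs, or truth
#'   only when `render = FALSE`) and `manifest` (data.frame).
#' @export
generate_cohort <- function(n, ranges = list(), seed = 1L, dir = NULL,
                            noise = TRUE, render = TRUE, raters = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be >= 1")
  n <- as.integer(n)
  base <- phantom_params()
  defaults <- list(iliac_angle_deg = c(80, 100), alpha_deg = c(45, 75),
                   apex_x = c(100, 156), apex_y = c(90, 150))
  ranges <- modifyList(defaults, ranges)
  bad <- setdiff(names(ranges), c(names(unclass(base)), "apex_x", "apex_y"))
  if (length(bad)) stop("unknown parameter(s) in ranges: ",
                        paste(bad, collapse = ", "))
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  frames <- vector("list", n)
  rows <- vector("list", n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  frame_seeds <- sample.int(.Machine$integer.max - 1L, n)
  for (i in seq_len(n)) {
    p <- base
    for (nm in names(ranges)) {
      r <- ranges[[nm]]
      v <- if (length(r) == 2L && is.numeric(r)) runif(1, r[1], r[2]) else r
      if (nm == "apex_x") p$apex[1] <- v
      else if (nm == "apex_y") p$apex[2] <- v
      else p[[nm]] <- v
    }
    p$seed <- frame_seeds[i]
    p <- structure(p, class = "phantom_params")
    if (!noise) p <- noise_free(p)
    validate_phantom_params(p)
    path <- NA_character_
    if (render) {
      fr <- generate_phantom(p)
      if (!is.null(dir)) {
        path <- file.path(dir, sprintf("phantom_%04d.png", i))
        write_image_png(fr$image, path)
      }
    } else {
      geo <- phantom_scene(p)
      fr <- list(image = NULL,
                 truth = structure(list(
                   apex = p$apex, iliac_angle_deg = p$iliac_angle_deg,
                   alpha_deg = p$alpha_deg,
                   ddh_label = is_ddh_alpha(p$alpha_deg),
                   qualified_label = is_qualified_angle(p$iliac_angle_deg),
                   roof_side = p$roof_side, scene = geo, seed = p$seed),
                   class = "phantom_truth"))
    }
    fr$params <- p
    row <- data.frame(path = path, apex_x = p$apex[1], apex_y = p$apex[2],
                      iliac_angle_deg = p$iliac_angle_deg,
                      alpha_deg = p$alpha_deg,
                      ddh_label = fr$truth$ddh_label,
                      qualified_label = fr$truth$qualified_label,
                      seed = p$seed, stringsAsFactors = FALSE)
    if (raters) {
      m <- simulate_rater_alphas(p$alpha_deg, fr$truth$qualified_label,
                                 p$rater_noise_sd_qualified,
                                 p$rater_noise_sd_disqualified)
      fr$truth$simulated_rater_alphas <- m
      for (r in seq_len(nrow(m)))
        for (k in seq_len(ncol(m)))
          row[[sprintf("rater_r%d_m%d", r, k)]] <- m[r, k]
    }
    frames[[i]] <- fr
    rows[[i]] <- row
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) write_manifest(manifest, file.path(dir, "manifest.csv"))
  list(frames = frames, manifest = manifest)
}
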