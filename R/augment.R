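# Training-time augmentation: a random resize (0.875-1.2) and 224-pixel
# crop shared by all chains, then three photometric effects per chain drawn
# from a seven-entry catalog, chains mixed with Dirichlet(alpha = 1)
# weights (the AugMix construction). Photometric effects never move
# keypoints; only the shared geometric transform does, so keypoint
# equivariance is exact.

#' Augmentation specification
#'
#' The seven-effect catalog with its parameter ranges: histogram equalize
#' (applied with probability 0.5 when drawn into a chain), posterize
#' (2-4 bits), solarize (threshold 156-256), contrast up (x1-4), contrast
#' down (x0.2-1), brightness up (x1-3), brightness down (x0.4-1). Effect
#' strength in `[0.2, 0.8]` linearly interpolates each effect's parameter
#' between its identity value and the sampled value (for equalize, which
#' has no parameter, the output is interpolated instead).
#'
#' @param resize_range random resize factor range.
#' @param crop_size crop side, pixels.
#' @param n_effects effects per chain.
#' @param n_chains mixture chains (3, the AugMix default).
#' @param strength_range effect strength range.
#' @param dirichlet_alpha concentration of the mixing weights.
#' @param equalize_prob probability that a drawn equalize is applied.
#' @return list of class `augment_spec`.
#' @export
augment_spec <- function(resize_range = c(0.875, 1.2), crop_size = 224L,
                         n_effects = 3L, n_chains = 3L,
                         strength_range = c(0.2, 0.8), dirichlet_alpha = 1,
                         equalize_prob = 0.5) {
  structure(list(resize_range = resize_range, crop_size = as.integer(crop_size),
                 n_effects = as.integer(n_effects), n_chains = as.integer(n_chains),
                 strength_range = strength_range,
                 dirichlet_alpha = dirichlet_alpha,
                 equalize_prob = equalize_prob,
                 catalog = c("equalize", "posterize", "solarize",
                             "contrast_up", "contrast_down",
                             "brightness_up", "brightness_down")),
            class = "augment_spec")
}

equalize_image <- function(img) {
  v <- pmin(pmax(round(img), 0), 255)
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  nz <- which(counts > 0)
  if (length(nz) <= 1L) return(img)
  cdf_min <- cdf[nz[1]]
  lut <- (cdf - cdf_min) / (length(v) - cdf_min) * 255
  lut[lut < 0] <- 0
  matrix(lut[v + 1L], nrow(img), ncol(img))
}

#' Apply one photometric effect at its raw sampled parameter
#'
#' Effects operate on `[0, 255]` grayscale; outputs are clipped back to
#' `[0, 255]` and keep the input shape. `magnitude` is the raw catalog
#' parameter (bits for posterize, threshold for solarize, multiplier for
#' contrast/brightness; ignored for equalize).
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param effect catalog entry name.
#' @param magnitude sampled parameter, within the entry's range.
#' @return transformed matrix.
#' @export
apply_effect <- function(image, effect, magnitude = NULL) {
  out <- switch(effect,
    equalize = equalize_image(image),
    posterize = {
      bits <- as.integer(round(magnitude))
      if (bits < 1L || bits > 8L) stop("posterize bits out of range")
      stepv <- 2^(8L - bits)
      floor(pmin(pmax(image, 0), 255) / stepv) * stepv
    },
    solarize = {
      if (magnitude < 0 || magnitude > 256) stop("solarize threshold out of range")
      ifelse(image >= magnitude, 255 - image, image)
    },
    contrast_up = ,
    contrast_down = {
      if (magnitude <= 0) stop("contrast multiplier out of range")
      mean(image) + (image - mean(image)) * magnitude
    },
    brightness_up = ,
    brightness_down = {
      if (magnitude < 0) stop("brightness multiplier out of range")
      image * magnitude
    },
    stop("unknown effect: ", effect))
  out <- pmin(pmax(out, 0), 255)
  matrix(out, nrow(image), ncol(image))
}

# Effect at a given strength: interpolate the parameter toward its identity
# value (equalize: interpolate the output).
apply_effect_strength <- function(image, effect, magnitude, strength) {
  if (effect == "equalize")
    return((1 - strength) * image + strength * apply_effect(image, "equalize"))
  neutral <- switch(effect, posterize = 8, solarize = 256,
                    contrast_up = 1, contrast_down = 1,
                    brightness_up = 1, brightness_down = 1)
  m <- neutral + strength * (magnitude - neutral)
  if (effect == "posterize") m <- max(1, round(m))
  apply_effect(image, effect, m)
}

sample_effect_magnitude <- function(effect) {
  switch(effect,
         equalize = NA_real_,
         posterize = sample(2:4, 1),
         solarize = runif(1, 156, 256),
         contrast_up = runif(1, 1, 4),
         contrast_down = runif(1, 0.2, 1),
         brightness_up = runif(1, 1, 3),
         brightness_down = runif(1, 0.4, 1))
}

#' Random resize and crop, keypoint-consistent
#'
#' Resizes by a factor drawn from `resize_range`, then crops `crop_size`
#' pixels at a uniform position. Keypoints map as
#' `k' = scale * k - offset`; the returned transform record inverts the
#' mapping exactly. At scale 0.875 a 256-pixel frame resizes to exactly
#' 224, leaving `(0, 0)` as the only valid offset.
#'
#' @param image numeric matrix.
#' @param keypoints matrix/vector of `(x, y)` rows, or NULL.
#' @param spec [augment_spec()].
#' @param seed optional integer seed (local to the call).
#' @return list `image` (crop_size square), `keypoints`, `transform`
#'   (list `scale`, `offset`).
#' @export
random_resize_crop <- function(image, keypoints = NULL, spec = augment_spec(),
                               seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  cs <- spec$crop_size
  scale <- runif(1, spec$resize_range[1], spec$resize_range[2])
  out_h <- max(cs, round(nrow(image) * scale))
  out_w <- max(cs, round(ncol(image) * scale))
  rs <- resize_bilinear(image, out_h, out_w)
  ox <- if (out_w > cs) sample.int(out_w - cs + 1L, 1L) - 1L else 0L
  oy <- if (out_h > cs) sample.int(out_h - cs + 1L, 1L) - 1L else 0L
  img <- rs[(oy + 1L):(oy + cs), (ox + 1L):(ox + cs), drop = FALSE]
  tr <- list(scale = scale, offset = c(ox, oy))
  kp <- NULL
  if (!is.null(keypoints)) kp <- transform_keypoints(keypoints, tr)
  list(image = img, keypoints = kp, transform = tr)
}

#' Apply / invert the geometric transform on keypoints
#'
#' @param keypoints `(x, y)` vector or matrix of rows.
#' @param transform record from [random_resize_crop()].
#' @return transformed keypoints, same shape.
#' @export
transform_keypoints <- function(keypoints, transform) {
  kp <- rbind(keypoints)
  out <- sweep(kp * transform$scale, 2, transform$offset)
  if (is.null(dim(keypoints))) drop(out) else out
}

#' @rdname transform_keypoints
#' @export
invert_keypoints <- function(keypoints, transform) {
  kp <- rbind(keypoints)
  out <- sweep(kp, 2, transform$offset, "+") / transform$scale
  if (is.null(dim(keypoints))) drop(out) else out
}

#' AugMix-style augmentation of a frame
#'
#' One geometric transform (random resize + crop) is applied first and
#' shared by all chains, so the keypoint mapping is well defined. Each of
#' `n_chains` chains then applies `n_effects` randomly drawn photometric
#' effects at random strengths, and the chain outputs are mixed with
#' weights drawn from a Dirichlet distribution.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param keypoints `(x, y)` vector/matrix or NULL.
#' @param spec [augment_spec()].
#' @param seed optional integer seed (local to the call).
#' @param weights optional fixed mixing weights (testing hook); must be
#'   nonnegative and sum to 1.
#' @return list `image`, `keypoints`, `transform`, `weights`.
#' @export
augmix_compose <- function(image, keypoints = NULL, spec = augment_spec(),
                           seed = NULL, weights = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  geo <- random_resize_crop(image, keypoints, spec)
  base <- geo$image
  if (is.null(weights)) {
    g <- rgamma(spec$n_chains, shape = spec$dirichlet_alpha)
    weights <- g / sum(g)
  }
  if (length(weights) != spec$n_chains || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("mixing weights must be nonnegative and sum to 1")
  mixed <- matrix(0, nrow(base), ncol(base))
  chains <- vector("list", spec$n_chains)
  for (ch in seq_len(spec$n_chains)) {
    img <- base
    effects <- sample(spec$catalog, spec$n_effects)
    for (e in effects) {
      strength <- runif(1, spec$strength_range[1], spec$strength_range[2])
      m <- sample_effect_magnitude(e)
      if (e == "equalize" && runif(1) >= spec$equalize_prob) next
      img <- apply_effect_strength(img, e, m, strength)
    }
    chains[[ch]] <- img
    mixed <- mixed + weights[ch] * img
  }
  list(image = mixed, keypoints = geo$keypoints, transform = geo$transform,
       weights = weights, chains = chains)
}
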