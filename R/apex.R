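# Apex-point estimation. The landmark is learned as a heatmap-regression
# problem: each annotated frame yields a Gaussian target map peaking at the
# apex, and a per-pixel classifier trained with binary cross-entropy scores
# every location; the estimate (eAP) is the decoded heatmap peak.
#
# The reference backbone is deliberately small — a single learned
# convolution filter over a (2r+1)^2 patch with a sigmoid output, i.e.
# convolutional logistic regression — trainable on CPU in seconds. Heavier
# published keypoint backbones are pluggable through the same contract
# (anything with a predict_heatmap method), not re-implemented: their value
# lies in trained weights on clinical data that are not available here.

#' Gaussian heatmap target for an annotated apex
#'
#' Unnormalised Gaussian bump around the (possibly fractional) annotation,
#' rescaled so the maximum over the grid is exactly 1 at the pixel nearest
#' the annotation.
#'
#' @param apex `(x, y)` 0-based continuous coordinates, inside the grid.
#' @param shape `(width, height)` in pixels.
#' @param sigma_px spread of the bump, pixels (> 0).
#' @return numeric matrix in `[0, 1]`.
#' @export
make_heatmap_target <- function(apex, shape = c(256L, 256L), sigma_px = 2) {
  w <- shape[1]; h <- shape[2]
  if (sigma_px <= 0) stop("sigma_px must be > 0")
  if (apex[1] < 0 || apex[1] > w - 1 || apex[2] < 0 || apex[2] > h - 1)
    stop("apex lies outside the target shape")
  dx2 <- (0:(w - 1) - apex[1])^2
  dy2 <- (0:(h - 1) - apex[2])^2
  g <- exp(-(outer(dy2, dx2, "+")) / (2 * sigma_px^2))
  g / max(g)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Patch design matrix: rows = sampled pixels, cols = (2r+1)^2 zero-padded
# patch intensities (image normalised to [0, 1]).
extract_patches <- function(img, xs, ys, r) {
  h <- nrow(img); w <- ncol(img)
  hp <- h + 2L * r
  pad <- matrix(0, hp, w + 2L * r)
  pad[(r + 1L):(r + h), (r + 1L):(r + w)] <- img / 255
  # top-left corner of each patch in the padded matrix (1-based)
  base <- (xs) * hp + (ys + 1L)            # linear index of (ys+1, xs+1) in pad
  offs <- as.vector(outer(0:(2L * r), (0:(2L * r)) * hp, "+"))
  idx <- outer(base, offs, "+")
  matrix(pad[idx], nrow = length(xs))
}

#' Training configuration for the reference apex estimator
#'
#' Optimizer settings are defaults, not contracts; they live here so runs
#' are reproducible from the config alone.
#'
#' @param patch_radius patch half-width r; features are the (2r+1)^2 patch.
#' @param sigma_px heatmap target spread, pixels.
#' @param epochs passes over the training pixels.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size in pixels.
#' @param n_background background pixels sampled per image (all pixels with
#'   target > 0.01 are always included).
#' @param min_confidence peak heatmap value below which a frame is declared
#'   to carry no apex signal.
#' @param seed integer seed for sampling and initialisation.
#' @return list of class `apex_config`.
#' @export
apex_config <- function(patch_radius = 7L, sigma_px = 2, epochs = 30L,
                        lr = 0.05, batch_size = 1024L, n_background = 300L,
                        min_confidence = 0.2, seed = 1L) {
  structure(list(patch_radius = as.integer(patch_radius), sigma_px = sigma_px,
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 n_background = as.integer(n_background),
                 min_confidence = min_confidence, seed = as.integer(seed)),
            class = "apex_config")
}

#' Train the reference apex estimator
#'
#' Fits the patch-based heatmap model by minibatch Adam on the mean
#' pixelwise binary cross-entropy between the sigmoid output and the
#' Gaussian heatmap target. Per image, every pixel with target above 0.01
#' plus `n_background` uniformly sampled background pixels enter the
#' training set. Deterministic given the config seed.
#'
#' @param dataset list of frames, each a list with `image` (256x256 matrix)
#'   and `apex` (`(x, y)`); [generate_cohort()] output frames (with
#'   `truth$apex`) are accepted directly.
#' @param config [apex_config()].
#' @return object of class `apex_estimator`.
#' @export
train_apex_estimator <- function(dataset, config = apex_config()) {
  if (length(dataset) == 0L) stop("empty training dataset")
  frames <- lapply(dataset, function(f) {
    apex <- if (!is.null(f$apex)) f$apex else f$truth$apex
    if (is.null(f$image) || is.null(apex)) stop("each frame needs image and apex")
    if (!all(dim(f$image) == c(256L, 256L)))
      stop("training images must be 256x256")
    list(image = f$image, apex = apex)
  })
  r <- config$patch_radius
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  Xs <- vector("list", length(frames)); Ts <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    tgt <- make_heatmap_target(f$apex, c(256L, 256L), config$sigma_px)
    fg <- which(tgt > 0.01)
    bg <- sample(setdiff(seq_len(length(tgt)), fg),
                 min(config$n_background, length(tgt) - length(fg)))
    lin <- c(fg, bg)
    ys <- (lin - 1L) %% 256L            # 0-based row
    xs <- (lin - 1L) %/% 256L           # 0-based col
    Xs[[i]] <- extract_patches(f$image, xs, ys, r)
    Ts[[i]] <- tgt[lin]
  }
  X <- do.call(rbind, Xs); Tg <- unlist(Ts)
  n <- nrow(X); k <- ncol(X)

  w <- rnorm(k, 0, 0.01); b <- 0
  mw <- vw <- numeric(k); mb <- vb <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = config$batch_size)) {
      ii <- ord[s:min(s + config$batch_size - 1L, n)]
      Xi <- X[ii, , drop = FALSE]
      p <- sigmoid(drop(Xi %*% w) + b)
      g <- p - Tg[ii]
      gw <- drop(crossprod(Xi, g)) / length(ii)
      gb <- mean(g)
      step <- step + 1L
      mw <- b1 * mw + (1 - b1) * gw; vw <- b2 * vw + (1 - b2) * gw^2
      mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
      w <- w - config$lr * (mw / (1 - b1^step)) / (sqrt(vw / (1 - b2^step)) + eps)
      b <- b - config$lr * (mb / (1 - b1^step)) / (sqrt(vb / (1 - b2^step)) + eps)
    }
  }
  structure(list(weights = w, bias = b, config = config, kind = "patch_logistic"),
            class = "apex_estimator")
}

#' Predict the full heatmap for a frame
#'
#' Applies the learned filter as a convolution (zero padding) and a sigmoid,
#' so every pixel's output lies in (0, 1).
#'
#' @param estimator `apex_estimator`.
#' @param image numeric matrix.
#' @return numeric matrix of heatmap values.
#' @export
predict_heatmap <- function(estimator, image) {
  UseMethod("predict_heatmap")
}

#' @export
predict_heatmap.apex_estimator <- function(estimator, image) {
  r <- estimator$config$patch_radius
  h <- nrow(image); w <- ncol(image)
  hp <- h + 2L * r; wp <- w + 2L * r
  pad <- matrix(0, hp, wp)
  pad[(r + 1L):(r + h), (r + 1L):(r + w)] <- image / 255
  z <- matrix(estimator$bias, h, w)
  k <- 0L
  for (dx in 0:(2L * r)) for (dy in 0:(2L * r)) {
    k <- k + 1L
    wk <- estimator$weights[k]
    if (wk != 0)
      z <- z + wk * pad[(dy + 1L):(dy + h), (dx + 1L):(dx + w)]
  }
  sigmoid(z)
}

#' Decode the apex estimate from a frame
#'
#' Takes the heatmap argmax and refines it by a quarter-pixel shift toward
#' the larger of the two neighbours along each axis (the standard heatmap
#' decoding rule). A peak below the configured `min_confidence` raises a
#' "no apex signal" error.
#'
#' @param estimator `apex_estimator`, or an object accepted by
#'   [predict_heatmap()]; alternatively a bare heatmap matrix.
#' @param image numeric 256x256 matrix (ignored when `estimator` is already
#'   a heatmap).
#' @param min_confidence override for the no-signal threshold.
#' @return list of class `apex_estimate`: `eap` (`(x, y)` continuous
#'   pixels) and `confidence` (peak heatmap value).
#' @export
estimate_apex <- function(estimator, image = NULL, min_confidence = NULL) {
  if (inherits(estimator, "apex_oracle"))
    return(structure(list(eap = estimator$apex, confidence = 1),
                     class = "apex_estimate"))
  if (is.matrix(estimator)) {
    hm <- estimator
    if (is.null(min_confidence)) min_confidence <- 0
  } else {
    hm <- predict_heatmap(estimator, image)
    if (is.null(min_confidence))
      min_confidence <- estimator$config$min_confidence %||% 0.2
  }
  peak <- max(hm)
  if (!is.finite(peak) || peak <= 0 || peak < min_confidence)
    stop(ddh_condition("ddh_no_apex_signal", "no apex signal in heatmap"))
  ij <- which(hm == peak, arr.ind = TRUE)[1, ]
  y <- ij[1] - 1L; x <- ij[2] - 1L
  h <- nrow(hm); w <- ncol(hm)
  off <- function(lo, hi) {
    if (is.na(lo) || is.na(hi) || lo == hi) 0 else 0.25 * sign(hi - lo)
  }
  left  <- if (x > 0) hm[y + 1, x] else NA
  right <- if (x < w - 1) hm[y + 1, x + 2] else NA
  up    <- if (y > 0) hm[y, x + 1] else NA
  down  <- if (y < h - 1) hm[y + 2, x + 1] else NA
  eap <- c(x + off(left, right), y + off(up, down))
  structure(list(eap = unname(eap), confidence = peak), class = "apex_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Oracle apex estimator (ground-truth pass-through)
#'
#' Used to test the downstream pipeline independently of the learned model:
#' `estimate_apex` on an oracle returns the stored ground-truth apex with
#' confidence 1.
#'
#' @param apex `(x, y)` ground-truth apex.
#' @return object of class `apex_oracle`.
#' @export
apex_oracle <- function(apex) {
  structure(list(apex = as.numeric(apex)), class = c("apex_oracle"))
}

#' @export
predict_heatmap.apex_oracle <- function(estimator, image) {
  make_heatmap_target(estimator$apex,
                      c(ncol(image), nrow(image)), sigma_px = 1)
}

#' Pixel localization error of an apex estimate
#'
#' Euclidean distance in pixels between estimate and ground truth, both in
#' the preprocessed-image frame.
#'
#' @param eap `(x, y)` estimate (or `apex_estimate`).
#' @param truth `(x, y)` ground truth.
#' @return distance in pixels.
#' @export
localization_error <- function(eap, truth) {
  if (inherits(eap, "apex_estimate")) eap <- eap$eap
  sqrt(sum((as.numeric(eap) - as.numeric(truth))^2))
}

#' Mean localization error over a frame set
#'
#' @param estimator `apex_estimator`.
#' @param frames list of frames with `image` and ground-truth apex
#'   (`apex` or `truth$apex`).
#' @return list `mean`, `se`, `errors`.
#' @export
evaluate_apex_estimator <- function(estimator, frames) {
  errs <- vapply(frames, function(f) {
    apex <- if (!is.null(f$apex)) f$apex else f$truth$apex
    est <- estimate_apex(estimator, f$image)
    localization_error(est, apex)
  }, numeric(1))
  list(mean = mean(errs), se = sd(errs) / sqrt(length(errs)), errors = errs)
}

#' Save / load an apex estimator as JSON
#'
#' Plain-text checkpoint: weights, bias and config.
#'
#' @param estimator `apex_estimator`.
#' @param path file path.
#' @return `save_apex_estimator`: `path` invisibly;
#'   `load_apex_estimator`: the estimator.
#' @export
save_apex_estimator <- function(estimator, path) {
  jsonlite::write_json(list(weights = estimator$weights, bias = estimator$bias,
                            config = unclass(estimator$config),
                            kind = estimator$kind),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_apex_estimator
#' @export
load_apex_estimator <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = o$weights, bias = o$bias,
                 config = structure(as.list(o$config), class = "apex_config"),
                 kind = o$kind),
            class = "apex_estimator")
}
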