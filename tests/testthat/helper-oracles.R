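# Independent brute-force oracles. These deliberately avoid the code paths
# they check: per-pixel submatrix scans instead of shift-and-pmax, angle
# minimisation instead of the eigen solution, pair counting instead of
# ranks.

# Local maxima by direct neighborhood scan over every pixel of the ROI.
brute_local_maxima <- function(image, roi, neighborhood_px) {
  r <- (neighborhood_px - 1L) %/% 2L
  h <- nrow(image); w <- ncol(image)
  out <- list()
  for (yy in (roi$y_min + 1L):roi$y_max) {
    for (xx in (roi$x_min + 1L):roi$x_max) {
      win <- image[max(1L, yy - r):min(h, yy + r),
                   max(1L, xx - r):min(w, xx + r)]
      v <- image[yy, xx]
      if (v > 0 && v == max(win))
        out[[length(out) + 1L]] <- c(xx - 1L, yy - 1L, v)
    }
  }
  if (!length(out))
    return(data.frame(x = integer(), y = integer(), intensity = double()))
  m <- do.call(rbind, out)
  df <- data.frame(x = m[, 1], y = m[, 2], intensity = m[, 3])
  df[order(df$y, df$x), ]
}

# Orthogonal-residual line angle by 1-D minimisation over the orientation.
brute_tls_angle <- function(points) {
  cx <- mean(points$x); cy <- mean(points$y)
  rss <- function(theta_deg) {
    t <- theta_deg * pi / 180
    sum(((points$x - cx) * sin(t) - (points$y - cy) * cos(t))^2)
  }
  grid <- seq(0, 180, by = 0.05)
  v <- vapply(grid, rss, numeric(1))
  i <- which.min(v)
  lo <- grid[max(1L, i - 2L)]; hi <- grid[min(length(grid), i + 2L)]
  stats::optimize(rss, c(lo, hi), tol = 1e-10)$minimum %% 180
}

# AUC by counting concordant label pairs, ties half.
brute_auc <- function(labels, scores) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Pooled-variance two-sample t from first principles.
brute_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Benjamini-Hochberg from the definition: adj_i = min over j with
# p_j >= p_i of p_j * m / rank_j, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  raw <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(raw)))
  pmin(1, adj)[order(o)]
}

# A reproducible random test image.
random_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}
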