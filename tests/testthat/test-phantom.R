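test_that("phantom labels follow their defining thresholds", {
  fr <- generate_phantom(noise_free(phantom_params(alpha_deg = 55)))
  expect_true(fr$truth$ddh_label)
  expect_true(fr$truth$qualified_label)

  for (al in c(59.9, 60, 60.1)) {
    fr <- generate_phantom(noise_free(phantom_params(alpha_deg = al)))
    expect_identical(fr$truth$ddh_label, al < 60)
  }
  for (th in c(86.9, 87, 90, 93, 93.1)) {
    fr <- generate_phantom(noise_free(phantom_params(iliac_angle_deg = th)))
    expect_identical(fr$truth$qualified_label, th >= 87 && th <= 93)
  }
})

test_that("noise-free vertical ilium has its per-row intensity peak at apex.x", {
  p <- noise_free(phantom_params(iliac_angle_deg = 90))
  fr <- generate_phantom(p)
  apex <- fr$truth$apex
  for (y in seq(10, apex[2] - 10, by = 10)) {
    row <- fr$image[y + 1, ]
    peak <- which(row == max(row)) - 1      # plateau: take its centre
    expect_lt(abs(mean(peak) - apex[1]), 0.5)
  }
})

test_that("same params and seed give bit-identical images", {
  p <- phantom_params(seed = 42L)
  a <- generate_phantom(p); b <- generate_phantom(p)
  expect_identical(a$image, b$image)
  p2 <- phantom_params(seed = 43L)
  expect_false(identical(generate_phantom(p2)$image, a$image))
})

test_that("invalid parameters are rejected", {
  expect_error(phantom_params(alpha_deg = 95), "alpha")
  expect_error(phantom_params(alpha_deg = 0), "alpha")
  expect_error(phantom_params(iliac_angle_deg = 50), "iliac")
  expect_error(phantom_params(ilium_intensity = 300), "255")
  expect_error(phantom_params(apex = c(-5, 120)), "apex")
  expect_error(phantom_params(apex = c(250, 120), roof_length_px = 100),
               "roof")
})

test_that("rotation covariance: scene endpoints rotate about the apex", {
  base <- noise_free(phantom_params(iliac_angle_deg = 88, alpha_deg = 60))
  delta <- 4
  rot <- noise_free(phantom_params(iliac_angle_deg = 88 + delta,
                                   alpha_deg = 60))
  g0 <- generate_phantom(base)$truth$scene
  g1 <- generate_phantom(rot)$truth$scene
  apex <- base$apex
  rotate <- function(p) {
    t <- delta * pi / 180
    d <- p - apex
    # screen coordinates (y down): +delta in orientation rotates (x,y) by
    # the matrix [cos, -sin; sin, cos]
    apex + c(cos(t) * d[1] - sin(t) * d[2], sin(t) * d[1] + cos(t) * d[2])
  }
  for (seg in c("ilium", "roof"))
    for (k in 1:2)
      expect_equal(g1[[seg]][[k]], rotate(g0[[seg]][[k]]), tolerance = 1e-9)
})

test_that("generate_cohort samples consistent labels and respects n", {
  co <- generate_cohort(100, ranges = list(iliac_angle_deg = c(80, 100)),
                        seed = 3, render = FALSE)
  expect_identical(nrow(co$manifest), 100L)
  expect_identical(co$manifest$qualified_label,
                   is_qualified_angle(co$manifest$iliac_angle_deg))
  expect_identical(co$manifest$ddh_label,
                   is_ddh_alpha(co$manifest$alpha_deg))
  expect_error(generate_cohort(0), "n must be")
  expect_error(generate_cohort(3, ranges = list(bogus = 1)), "bogus")
})

test_that("qualified fraction matches the uniform measure of the gate", {
  # iliac ~ U[80, 100]: P(qualified) = (93 - 87) / 20 = 0.30
  co <- generate_cohort(500, ranges = list(iliac_angle_deg = c(80, 100)),
                        seed = 11, render = FALSE)
  frac <- mean(co$manifest$qualified_label)
  expect_lt(abs(frac - 0.30), 3 * sqrt(0.3 * 0.7 / 500))
})

test_that("simulated rater noise depends on frame quality", {
  set.seed(8)
  mq <- replicate(200, sd(simulate_rater_alphas(60, TRUE, 1, 4)))
  md <- replicate(200, sd(simulate_rater_alphas(60, FALSE, 1, 4)))
  expect_lt(mean(mq), mean(md))
  co <- generate_cohort(20, seed = 5, render = FALSE, raters = TRUE)
  expect_true(all(c("rater_r1_m1", "rater_r2_m2") %in% names(co$manifest)))
  expect_identical(dim(co$frames[[1]]$truth$simulated_rater_alphas), c(2L, 2L))
})
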