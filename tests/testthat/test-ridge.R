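test_that("ROI follows the stated width/offset and clips at borders", {
  roi <- build_roi(c(128, 140), c(256, 256))
  expect_identical(unclass(roi)[c("x_min", "x_max", "y_min", "y_max")],
                   list(x_min = 123L, x_max = 133L, y_min = 0L, y_max = 145L))
  roi <- build_roi(c(2, 140), c(256, 256))
  expect_identical(c(roi$x_min, roi$x_max), c(0L, 7L))
  roi <- build_roi(c(128, 254), c(256, 256))
  expect_identical(roi$y_max, 256L)
  expect_error(build_roi(c(-1, 10), c(256, 256)), "outside")
})

test_that("local maxima: unique peak, plateau semantics, empty ROI", {
  img <- matrix(0, 5, 5); img[3, 3] <- 7
  roi <- ddhscreen:::roi_spec(0, 5, 0, 5)
  mx <- detect_local_maxima(img, roi, 3)
  expect_identical(nrow(mx), 1L)
  expect_identical(c(mx$x, mx$y, mx$intensity), c(2, 2, 7))

  const <- matrix(4, 6, 6)
  mx <- detect_local_maxima(const, ddhscreen:::roi_spec(1, 5, 1, 5), 3)
  expect_identical(nrow(mx), 16L)       # every ROI pixel is a plateau member

  expect_error(detect_local_maxima(img, ddhscreen:::roi_spec(3, 3, 0, 5), 3),
               "empty")
  expect_error(detect_local_maxima(img, roi, 4), "odd")
})

test_that("local maxima equal the brute-force neighborhood scan", {
  for (seed in 1:6) {
    img <- random_image(32, 32, seed)
    roi <- ddhscreen:::roi_spec(0, 32, 0, 32)
    for (nb in c(3L, 5L, 7L)) {
      got <- detect_local_maxima(img, roi, nb)
      want <- brute_local_maxima(img, roi, nb)
      expect_equal(got$x, want$x)
      expect_equal(got$y, want$y)
      expect_equal(got$intensity, want$intensity)
    }
  }
})

test_that("per-row selection keeps the brightest candidate and enforces k_min", {
  m <- data.frame(x = c(5, 8, 3, 6), y = c(1, 1, 2, 3),
                  intensity = c(200, 180, 90, 90))
  sel <- select_ilium_points(m, k_min = 3)
  expect_identical(nrow(sel), 3L)
  expect_identical(sel$x[sel$y == 1], 5)          # brighter of the two
  one_per_row <- data.frame(x = 1:5, y = 1:5, intensity = 5:1)
  expect_identical(select_ilium_points(one_per_row, k_min = 5)$x, 1:5)
  # ties break toward smallest x
  tie <- data.frame(x = c(9, 4), y = c(2, 2), intensity = c(50, 50))
  expect_identical(select_ilium_points(tie, k_min = 1)$x, 4)
  expect_error(select_ilium_points(m, k_min = 10), "insufficient ridge support")
  expect_error(select_ilium_points(m[0, ], k_min = 1), "no local maxima")
})

test_that("total least squares fit matches exact and brute-force answers", {
  vert <- data.frame(x = rep(50, 20), y = 0:19)
  expect_equal(fit_line(vert)$angle_deg, 90)
  diag45 <- data.frame(x = 0:19, y = 0:19)
  expect_equal(fit_line(diag45)$angle_deg, 45)
  expect_error(fit_line(data.frame(x = 1, y = 1)), "at least 2")
  expect_error(fit_line(data.frame(x = c(2, 2), y = c(3, 3))), "coincident")

  set.seed(42)
  for (rep in 1:10) {
    t <- runif(1, 0, 180) * pi / 180
    n <- 30
    s <- runif(n, -20, 20)
    pts <- data.frame(x = 100 + s * cos(t) + rnorm(n, 0, 0.8),
                      y = 100 + s * sin(t) + rnorm(n, 0, 0.8))
    got <- fit_line(pts)$angle_deg
    want <- brute_tls_angle(pts)
    d <- abs(got - want) %% 180
    expect_lt(min(d, 180 - d), 1e-6)
  }
})

test_that("quality gate is inclusive and a pure threshold", {
  line_at <- function(a) {
    t <- a * pi / 180
    fit_line(data.frame(x = c(0, 10 * cos(t)), y = c(0, 10 * sin(t))))
  }
  for (case in list(c(86.9, 0), c(87, 1), c(90, 1), c(93, 1), c(93.1, 0))) {
    q <- assess_quality(line_at(case[1]))
    expect_identical(q$qualified, case[2] == 1)
    expect_equal(q$iliac_angle_deg, case[1], tolerance = 1e-9)
  }
})

test_that("intensity surface export is lossless and ordered", {
  img <- random_image(16, 16, 3)
  roi <- ddhscreen:::roi_spec(4, 6, 7, 9)
  surf <- export_intensity_surface(img, roi)
  expect_identical(nrow(surf), 4L)
  expect_true(!is.unsorted(surf$y))
  rebuilt <- matrix(surf$intensity, 2, 2, byrow = TRUE)
  expect_equal(rebuilt, img[8:9, 5:6])
  expect_error(export_intensity_surface(img, ddhscreen:::roi_spec(4, 4, 0, 2)),
               "empty")
})

test_that("iliac angle recovery on noise-free phantoms tracks the gate", {
  for (th in c(85, 87, 90, 93, 95)) {
    fr <- generate_phantom(noise_free(phantom_params(iliac_angle_deg = th,
                                                     alpha_deg = 65)))
    m <- measure_iliac(fr$image, fr$truth$apex)
    expect_lt(abs(m$quality$iliac_angle_deg - th), 0.5)
    # decisions are only determined away from the gate boundaries
    if (min(abs(th - 87), abs(th - 93)) >= 0.5)
      expect_identical(m$quality$qualified, fr$truth$qualified_label)
  }
})

test_that("robust fit discards structured outliers the plain fit cannot", {
  set.seed(7)
  s <- 0:29
  pts <- data.frame(x = 100 + rnorm(30, 0, 0.3), y = s)        # vertical
  out <- data.frame(x = 112 + 0.5 * (0:9), y = seq(2, 20, 2))  # distractor
  both <- rbind(cbind(pts, intensity = 200), cbind(out, intensity = 200))
  naive <- fit_line(both)
  robust <- fit_line_robust(both)
  expect_gt(abs(naive$angle_deg - 90), 2)
  expect_lt(abs(robust$angle_deg - 90), 1)
})
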