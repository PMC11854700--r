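test_that("heatmap target is a unit-peak Gaussian bump", {
  hm <- make_heatmap_target(c(10, 10), c(64, 64), sigma_px = 2)
  expect_equal(hm[11, 11], 1.0)
  expect_equal(hm[11, 13], exp(-0.5), tolerance = 1e-12)   # 2 px = sigma
  expect_equal(hm[13, 11], exp(-0.5), tolerance = 1e-12)
  # mass oracle: integral of the bump is 2*pi*sigma^2 for sigma << size
  expect_equal(sum(make_heatmap_target(c(32, 32), c(64, 64), 2)),
               2 * pi * 4, tolerance = 1e-3)
  expect_error(make_heatmap_target(c(70, 10), c(64, 64), 2), "outside")
  expect_error(make_heatmap_target(c(10, 10), c(64, 64), 0), "sigma")
})

test_that("heatmap decoding refines a quarter pixel toward the larger neighbour", {
  hm <- matrix(0, 128, 128)
  hm[61, 51] <- 1                                    # peak at (x=50, y=60)
  hm[61, 50] <- 0.5; hm[61, 52] <- 0.5               # symmetric: no shift
  hm[60, 51] <- 0.4; hm[62, 51] <- 0.4
  est <- estimate_apex(hm)
  expect_equal(est$eap, c(50, 60))
  hm[61, 52] <- 0.6                                  # right > left
  expect_equal(estimate_apex(hm)$eap, c(50.25, 60))
  hm[60, 51] <- 0.7                                  # up > down
  expect_equal(estimate_apex(hm)$eap, c(50.25, 59.75))
  expect_error(estimate_apex(matrix(0, 8, 8)), "no apex signal")
})

test_that("oracle estimator passes ground truth through exactly", {
  fr <- generate_phantom(noise_free(phantom_params(apex = c(130.5, 118.25))))
  est <- estimate_apex(apex_oracle(fr$truth$apex), fr$image)
  expect_identical(est$eap, fr$truth$apex)
  expect_equal(est$confidence, 1)
})

test_that("localization error is the Euclidean pixel distance", {
  expect_equal(localization_error(c(0, 0), c(3, 4)), 5)
  expect_equal(localization_error(c(7.5, -2), c(7.5, -2)), 0)
  # batch summary oracle: errors {5, 0, 1} -> mean 2, se = sqrt(7)/sqrt(3)
  model <- apex_oracle(c(0, 0))
  frames <- list(list(image = matrix(1, 8, 8), apex = c(3, 4)),
                 list(image = matrix(1, 8, 8), apex = c(0, 0)),
                 list(image = matrix(1, 8, 8), apex = c(1, 0)))
  ev <- evaluate_apex_estimator(model, frames)
  expect_equal(ev$errors, c(5, 0, 1))
  expect_equal(ev$mean, 2)
  expect_equal(ev$se, sqrt(7) / sqrt(3), tolerance = 1e-12)
})

test_that("training rejects bad input", {
  expect_error(train_apex_estimator(list()), "empty")
  bad <- list(list(image = matrix(0, 64, 64), apex = c(1, 1)))
  expect_error(train_apex_estimator(bad), "256x256")
})

test_that("estimator outputs are sigmoid-bounded and training is seed-deterministic", {
  frames <- phantom_set(8, seed = 101)
  cfg <- apex_config(epochs = 2L, seed = 3)
  e1 <- train_apex_estimator(frames, cfg)
  e2 <- train_apex_estimator(frames, cfg)
  expect_identical(e1$weights, e2$weights)
  hm <- predict_heatmap(e1, frames[[1]]$image)
  expect_true(all(hm > 0 & hm < 1))
})

test_that("reference model localizes held-out phantoms and shifts equivariantly", {
  model <- reference_model()
  ev <- evaluate_apex_estimator(model, heldout_set())
  expect_lt(ev$mean, 6)
  # translation equivariance: moving the scene moves the estimate along
  base <- noise_free(phantom_params(apex = c(124, 116)))
  f0 <- generate_phantom(base)
  e0 <- estimate_apex(model, f0$image)$eap
  for (d in list(c(6, 0), c(0, 7), c(-5, 4))) {
    sh <- noise_free(phantom_params(apex = c(124, 116) + d))
    f1 <- generate_phantom(sh)
    e1 <- estimate_apex(model, f1$image)$eap
    expect_lt(max(abs((e1 - e0) - d)), 1)
  }
})

test_that("held-out error does not degrade with training set size", {
  # The reference model saturates below 0.3 px with 25 training frames on
  # this world, so a strictly decreasing learning curve is unobservable;
  # the substantive property is that more data never hurts (to within the
  # plateau noise) and every size meets the accuracy contract.
  sizes <- c(25, 100, 400)
  test_frames <- heldout_set()
  means <- vapply(seq_along(sizes), function(i) {
    tr <- phantom_set(sizes[i], seed = 6000 + i)
    m <- train_apex_estimator(tr, apex_config(seed = 7))
    evaluate_apex_estimator(m, test_frames)$mean
  }, numeric(1))
  expect_true(all(means <= 6))
  expect_lte(means[3], means[1] + 0.05)
  expect_lte(means[2], means[1] + 0.05)
})

test_that("checkpoints round-trip through JSON", {
  model <- reference_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_apex_estimator(model, path)
  back <- load_apex_estimator(path)
  expect_equal(back$weights, model$weights, tolerance = 1e-12)
  img <- heldout_set()[[1]]$image
  expect_equal(estimate_apex(back, img)$eap, estimate_apex(model, img)$eap)
})
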