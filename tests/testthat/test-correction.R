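test_that("mean correction subtracts autofluorescence with quadrature errors", {
  expect_equal(correct_mean(1000, 300)$mean_T, 700)
  atb <- correct_mean(300, 300)
  expect_equal(atb$mean_T, 0)
  expect_identical(atb$flags, "below_autofluorescence")
  cm <- correct_mean(1000, 300, 10, 10)
  expect_equal(cm$sigma_mean_T, sqrt(200), tolerance = 1e-9)
})

test_that("variance correction removes autofluorescence and shot noise", {
  sn <- shot_noise_model(delta = 2)
  expect_equal(correct_variance(5000, 1000, sn, 100)$var_T, 3600)

  # delta = 0 reduces to plain autofluorescence subtraction
  expect_equal(correct_variance(5000, 1000, shot_noise_model(delta = 0), 100)$var_T,
               4000)

  clamped <- correct_variance(1000, 500, shot_noise_model(delta = 10), 100)
  expect_equal(clamped$var_T, 0)
  expect_identical(clamped$flags, "negative_variance_clamped")

  expect_error(correct_variance(5000, 1000, mean_T = 100), "shot_noise_model")
})

test_that("concentration and total noise formulas are mutual inverses", {
  expect_equal(concentration_cv2(0.10, 0.05), 0.05 / 1.05, tolerance = 1e-12)
  expect_equal(concentration_cv2(0.3, 0), 0.3)
  expect_equal(total_cv2_from_components(0.04, 0.05), 0.092, tolerance = 1e-12)
  expect_equal(total_cv2_from_components(0, 0.2), 0.2)
  expect_equal(total_cv2_from_components(concentration_cv2(0.10, 0.05), 0.05),
               0.10, tolerance = 1e-12)

  for (cv2_C in seq(0, 0.5, by = 0.1)) {
    for (cv2_V in seq(0, 0.5, by = 0.1)) {
      tot <- total_cv2_from_components(cv2_C, cv2_V)
      expect_equal(concentration_cv2(tot, cv2_V), cv2_C, tolerance = 1e-12)
    }
  }
  expect_warning(concentration_cv2(0.01, 0.05), "below volume noise")
})

test_that("reporter noise differences scale by the shared volume factor", {
  expect_equal(delta_concentration_cv2(0.10, 0.08, 0.05), 0.02 / 1.05,
               tolerance = 1e-12)
  expect_equal(delta_concentration_cv2(0.07, 0.07, 0.3), 0)
  expect_equal(delta_concentration_cv2(0.10, 0.08, 0), 0.02, tolerance = 1e-12)
})

test_that("independent lognormal C and V combine to the predicted total noise", {
  n <- 1e6
  withr::with_seed(61, {
    C <- rlnorm(n, meanlog = log(40) - log(1.04) / 2, sdlog = sqrt(log(1.04)))
    V <- rlnorm(n, meanlog = log(50) - log(1.05) / 2, sdlog = sqrt(log(1.05)))
  })
  I <- C * V
  cv2_sample <- var(I) / mean(I)^2
  # Monte-Carlo error on the sample CV^2, from the spread of (I - <I>)^2
  se_cv2 <- sd((I - mean(I))^2) / sqrt(n) / mean(I)^2
  expect_lt(abs(cv2_sample - 0.092), 3 * (se_cv2 + 2e-4))
})

test_that("gate -> fit -> correct recovers the generated expression noise", {
  true_cv2 <- total_cv2_from_components(0.08, 0.01)
  sim <- simulate_population(population_spec(n_events = 2e4, mean_C = 200,
                                             cv2_C = 0.08, cv2_V = 0.01,
                                             seed = 62))
  auto <- simulate_population(population_spec(n_events = 2e4, mean_C = 0,
                                              seed = 63))
  res <- gate_and_fit(sim$events)
  auto_est <- gate_and_fit(auto$events)$estimate
  auto_est$day_id <- "d1"; auto_est$replicate_id <- "r1"
  af <- aggregate_autofluorescence(list(auto_est))
  corr <- correct_expression(res$estimate, af, shot_noise_model(delta = 12))
  expect_lt(abs(corr$cv2_I - true_cv2) / true_cv2, 0.10)
  expect_length(corr$flags, 0)

  # without the shot-noise correction the noise is overestimated by ~d^2/mean
  uncorr <- correct_expression(res$estimate, af, shot_noise_model(delta = 0))
  expect_gt(uncorr$cv2_I, corr$cv2_I)
  predicted_excess <- 144 / corr$mean_T
  expect_lt(abs((uncorr$cv2_I - corr$cv2_I) - predicted_excess) / predicted_excess,
            0.15)
})

test_that("correction warns when the signal does not clear the autofluorescence", {
  est <- fake_estimate(900, 5, 5e4, 500, "d1", "r1")
  af <- aggregate_autofluorescence(list(fake_estimate(1000, 5, 4e4, 400,
                                                      "d1", "r1")))
  expect_warning(corr <- correct_expression(est, af, shot_noise_model(delta = 0)),
                 "validity")
  expect_identical(corr$flags, "below_autofluorescence")
  expect_true(is.na(corr$cv2_I))
})
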