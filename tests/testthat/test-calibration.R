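test_that("identical replicates aggregate to their common value", {
  ests <- lapply(1:3, function(r) fake_estimate(300, 10, 5000, 200, "d1",
                                                paste0("r", r)))
  af <- aggregate_autofluorescence(ests)
  expect_equal(af$overall_mean, 300)
  expect_lte(af$se_overall_mean, 10)
  expect_equal(af$overall_var, 5000)
})

test_that("discordant replicates inflate the day-level error", {
  ests <- list(fake_estimate(100, 10, 5000, 100, "d1", "r1"),
               fake_estimate(200, 10, 5000, 100, "d1", "r2"))
  af <- aggregate_autofluorescence(ests)
  expect_equal(af$overall_mean, 150)
  # fixed-effect error would be 10/sqrt(2) = 7.07; the between-replicate
  # component must inflate it (DerSimonian-Laird gives exactly 50 here)
  expect_gt(af$se_overall_mean, 7.08)
  expect_equal(af$se_overall_mean, 50, tolerance = 1e-6)
})

test_that("explicit exclusions are honored and bookkept", {
  ests <- list(fake_estimate(300, 10, 5000, 100, "d1", "r1"),
               fake_estimate(300, 10, 5000, 100, "d1", "r2"),
               fake_estimate(9000, 10, 5000, 100, "d1", "G6")) # contaminated well
  af <- aggregate_autofluorescence(ests, exclusions = "d1:G6")
  expect_equal(af$overall_mean, 300)
  expect_identical(sum(af$per_replicate$excluded), 1L)

  expect_error(aggregate_autofluorescence(ests[1],
                                          exclusions = "d1:r1"),
               "all replicates excluded")
  broken <- fake_estimate(300, NA, 5000, 100, "d1", "r1")
  expect_error(aggregate_autofluorescence(list(broken)), "error bars")
})

test_that("aggregation is permutation-invariant over replicates and days", {
  ests <- list(fake_estimate(280, 8, 4000, 90, "d1", "r1"),
               fake_estimate(310, 12, 5200, 110, "d1", "r2"),
               fake_estimate(295, 9, 4800, 95, "d2", "r1"),
               fake_estimate(305, 11, 5100, 105, "d2", "r2"))
  af1 <- aggregate_autofluorescence(ests)
  af2 <- aggregate_autofluorescence(rev(ests))
  expect_equal(af1$overall_mean, af2$overall_mean, tolerance = 1e-10)
  expect_equal(af1$se_overall_mean, af2$se_overall_mean, tolerance = 1e-10)
  expect_equal(af1$overall_var, af2$overall_var, tolerance = 1e-10)
  # overall lies within the span of day values
  expect_gte(af1$overall_mean, min(af1$per_day$mean))
  expect_lte(af1$overall_mean, max(af1$per_day$mean))
})

test_that("bead summaries show CV^2 dropping with mean and validate inputs", {
  beads <- simulate_beads(m = c(1e3, 1e4, 1e5), c = 0.01, delta = 12,
                          offset_O = 100, n = 3000, seed = 51)
  bs <- summarize_beads(beads)
  expect_identical(nrow(bs), 3L)
  expect_true(all(diff(bs$cv2[order(bs$mean_I)]) < 0))

  expect_error(summarize_beads(beads[1]), "underdetermined")
  dup <- summarize_beads(c(beads[1], beads[1]))
  expect_equal(dup$mean_I[1], dup$mean_I[2])
  expect_equal(dup$var_I[1], dup$var_I[2])

  # single table + per-event labels
  fl <- c(beads[[1]]$fl_h, beads[[2]]$fl_h)
  lab <- rep(c("lo", "hi"), each = 3000)
  bs2 <- summarize_beads(fl, labels = lab)
  expect_setequal(bs2$label, c("lo", "hi"))
})

test_that("the simple linear fit inverts exact shot-noise curves", {
  delta <- 10; O <- 100
  means <- c(1e3, 1e4, 1e5)
  cv2 <- delta^2 / means - delta^2 * O / means^2
  bs <- fake_bead_summary(means, cv2 * means^2)
  # the constructed points lie exactly on the line; lm warns about the
  # perfect fit when computing coefficient errors
  fit <- suppressWarnings(fit_shot_noise_simple(bs))
  expect_equal(fit$delta, delta, tolerance = 1e-9)
  expect_equal(fit$offset_O, O, tolerance = 1e-9)
  expect_identical(fit$method, "simple_linear")

  expect_error(fit_shot_noise_simple(fake_bead_summary(c(1e3, 1e3), c(1e5, 1e5))),
               "singular")
})

test_that("the simple fit recovers delta from simulated zero-CV beads", {
  beads <- simulate_beads(m = c(1e3, 1e4, 1e5), c = 0, delta = 10,
                          offset_O = 100, n = 1e4, seed = 52)
  fit <- fit_shot_noise_simple(summarize_beads(beads))
  expect_lt(abs(fit$delta - 10) / 10, 0.05)
})

test_that("the shared-CV^2 moment system is solved exactly on constructed moments", {
  m <- c(900, 9900, 99900); cc <- 0.01; delta <- 12; O <- 100
  bs <- fake_bead_summary(m + O, cc * m^2 + delta^2 * m)
  fit <- fit_shot_noise_shared_cv2(bs)
  expect_equal(fit$delta, delta, tolerance = 1e-6)
  expect_equal(fit$offset_O, O, tolerance = 1e-4)
  expect_equal(fit$shared_cv2, cc, tolerance = 1e-8)
  expect_equal(fit$m, m, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(fit$method, "shared_cv2_moments")

  expect_error(fit_shot_noise_shared_cv2(fake_bead_summary(c(1e3, 1e3, 1e5),
                                                           c(1e5, 1e5, 1e7))),
               "singular")
  expect_error(fit_shot_noise_shared_cv2(fake_bead_summary(c(1e3, 1e4), c(1e5, 1e6))),
               "exactly 3")
})

test_that("shared-CV^2 and simple fits agree when beads truly have zero CV^2", {
  beads <- simulate_beads(m = c(1e3, 1e4, 1e5), c = 0, delta = 12,
                          offset_O = 100, n = 1e4, seed = 53)
  bs <- summarize_beads(beads)
  shared <- fit_shot_noise_shared_cv2(bs, events = beads, n_boot = 100, seed = 54)
  simple <- fit_shot_noise_simple(bs)
  expect_lt(abs(shared$delta - simple$delta), 3 * shared$sigma_delta)
  expect_lt(abs(shared$offset_O - simple$offset_O), 3 * shared$sigma_offset)
})

test_that("bootstrap uncertainties shrink roughly as 1/sqrt(n)", {
  sig <- sapply(c(2000, 8000), function(n) {
    beads <- simulate_beads(m = c(1e3, 1e4, 1e5), c = 0.01, delta = 12,
                            offset_O = 100, n = n, seed = 55)
    fit <- fit_shot_noise_shared_cv2(summarize_beads(beads), events = beads,
                                     n_boot = 120, seed = 56)
    fit$sigma_delta
  })
  # 4x the events should halve the bootstrap error, within bootstrap noise
  expect_gt(sig[1] / sig[2], 1.3)
  expect_lt(sig[1] / sig[2], 3.1)
})

test_that("Eq-4-style curve and its (Y, X) line describe the same relation", {
  delta <- 8; O <- 60
  means <- 10^seq(3, 5, length.out = 7)
  cv2_curve <- delta^2 / means - delta^2 * O / means^2
  Y <- cv2_curve * means
  X <- 1 / means
  expect_equal(Y, delta^2 - delta^2 * O * X, tolerance = 1e-12)
})
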