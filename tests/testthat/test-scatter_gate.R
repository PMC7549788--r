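test_that("the mixture recovers a pure 4D Gaussian population", {
  n <- 1e4
  mu <- c(25000, 65, 18000, 60)
  sds <- 0.1 * mu
  x <- withr::with_seed(10, MASS::mvrnorm(n, mu, diag(sds^2)))
  ev <- event_table(data.frame(fsc_h = x[, 1], fsc_w = x[, 2],
                               ssc_h = x[, 3], ssc_w = x[, 4],
                               fl_h = rep(100, n)))
  model <- fit_scatter_mixture(ev)
  se <- sds / sqrt(n)
  expect_true(all(abs(model$mu - mu) < 3 * se))
  expect_gt(model$pi_good, 0.95)
  expect_true(model$converged)
})

test_that("the mixture weight recovers a 90/10 Gaussian/uniform blend", {
  n <- 1e4
  mu <- c(2000, 1000, 1600, 800)
  sds <- 0.05 * mu
  withr::with_seed(11, {
    n_g <- rbinom(1, n, 0.9)
    g <- MASS::mvrnorm(n_g, mu, diag(sds^2))
    # uniform on a box 5x wider than the +/-2.5 sd core, centred on mu
    u <- sapply(1:4, function(j) runif(n - n_g, mu[j] - 12.5 * sds[j],
                                       mu[j] + 12.5 * sds[j]))
    x <- rbind(g, u)
  })
  ev <- event_table(data.frame(fsc_h = x[, 1], fsc_w = x[, 2],
                               ssc_h = x[, 3], ssc_w = x[, 4], fl_h = 1))
  model <- fit_scatter_mixture(ev)
  expect_lt(abs(model$pi_good - 0.9), 0.03)
})

test_that("too few events is an error", {
  expect_error(fit_scatter_mixture(make_events(10)), "too few events")
})

test_that("EM log-likelihood is non-decreasing on every fitted dataset", {
  for (seed in c(21, 22, 23)) {
    sim <- simulate_population(population_spec(n_events = 5000, seed = seed))
    model <- fit_scatter_mixture(sim$events)
    tr <- model$loglik_trace
    expect_true(all(diff(tr) >= -1e-9 * abs(tr[-length(tr)])))
  }
})

test_that("posteriors follow the density-ratio formula in limiting cases", {
  box <- rbind(rep(0, 4), rep(10, 4))
  base <- list(mu = rep(5, 4), sigma = diag(4), pi_good = 0.5,
               support_box = box, uniform_density = 1e-4,
               log_space = FALSE, converged = TRUE)
  ev1 <- event_table(data.frame(fsc_h = 5, fsc_w = 5, ssc_h = 5, ssc_w = 5,
                                fl_h = 1))

  # pi_good -> 0 forces p = 0 everywhere
  m0 <- structure(utils::modifyList(base, list(pi_good = 0)),
                  class = "scatter_gate_model")
  expect_equal(gate_posteriors(m0, ev1), 0)

  # Gaussian density at mu = (2*pi)^-2 ~ 0.0253; 1e6 x the uniform density
  m1 <- structure(utils::modifyList(base, list(pi_good = 0.9,
                                               uniform_density = (2 * pi)^-2 * 1e-6)),
                  class = "scatter_gate_model")
  expect_equal(gate_posteriors(m1, ev1), 1, tolerance = 1e-5)

  # equal densities at pi_good = 0.5 -> p = 0.5 exactly
  m2 <- structure(utils::modifyList(base, list(uniform_density = (2 * pi)^-2)),
                  class = "scatter_gate_model")
  expect_equal(gate_posteriors(m2, ev1), 0.5, tolerance = 1e-12)

  expect_error(gate_posteriors(list(), ev1), "fitted")
})

test_that("filtering thresholds the posterior exactly and preserves order", {
  ev <- make_events(3, seed = 6)
  flt <- filter_events(ev, c(0.9, 0.4, 0.6), threshold = 0.5)
  expect_identical(n_events(flt$events), 2L)
  expect_equal(flt$retained_fraction, 2 / 3)
  expect_equal(flt$events$fl_h, ev$fl_h[c(1, 3)])

  all_in <- filter_events(ev, c(0.9, 0.4, 0.6), threshold = 0)
  expect_identical(n_events(all_in$events), 3L)
  expect_equal(all_in$retained_fraction, 1)

  expect_error(filter_events(ev, c(0.5, 0.5)), "does not match")
  expect_error(filter_events(ev, c(0.5, 0.5, 0.5), threshold = 2), "\\[0, 1\\]")
})

test_that("lenient and strict gating leave the fluorescence distribution unchanged", {
  # with <= 10% debris, the retained log-fluorescence mean barely moves
  # between near-vacuous and near-certain posterior thresholds
  sim <- simulate_population(population_spec(n_events = 2e4, seed = 31))
  model <- fit_scatter_mixture(sim$events)
  p <- gate_posteriors(model, sim$events)
  lenient <- filter_events(sim$events, p, threshold = exp(-10))
  strict <- filter_events(sim$events, p, threshold = 1 - exp(-10))
  m_len <- mean(log(lenient$events$fl_h))
  m_str <- mean(log(strict$events$fl_h))
  expect_lt(abs(m_len - m_str) / abs(m_len), 0.01)
  expect_gt(n_events(lenient$events), n_events(strict$events))
})

test_that("gating separates labeled debris from viable cells", {
  sim <- simulate_population(population_spec(n_events = 2e4, seed = 32))
  model <- fit_scatter_mixture(sim$events)
  p <- gate_posteriors(model, sim$events)
  accuracy <- mean((p >= 0.5) == sim$truth$viable)
  expect_gt(accuracy, 0.95)
  flt <- filter_events(sim$events, p)
  expect_lt(abs(flt$retained_fraction - 0.9), 0.03)
})
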