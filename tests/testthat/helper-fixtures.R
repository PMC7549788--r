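# shared fixtures, built in code at test time

# small clean event table: 4D Gaussian scatter + lognormal fluorescence
make_events <- function(n = 200, seed = 1) {
  withr::with_seed(seed, {
    mu <- c(25000, 65, 18000, 60)
    scatter <- MASS::mvrnorm(n, mu, diag((0.1 * mu)^2))
    event_table(data.frame(
      fsc_h = scatter[, 1], fsc_w = scatter[, 2],
      ssc_h = scatter[, 3], ssc_w = scatter[, 4],
      fl_h = rlnorm(n, 7, 0.3)))
  })
}

# log_fluor_estimate stand-in with prescribed linear moments, for exercising
# the aggregation arithmetic without running EM
fake_estimate <- function(mean_lin, se_mean, var_lin, se_var, day, rep) {
  structure(list(mu = log(mean_lin), v = 0.1, sigma_mu = 0.01, sigma_v = 0.01,
                 pi_good = 0.99, n_eff = 1000, n_used = 1000, n_dropped = 0,
                 mean_lin = mean_lin, sigma_mean_lin = se_mean,
                 var_lin = var_lin, sigma_var_lin = se_var,
                 converged = TRUE, loglik_trace = numeric(0),
                 sample_id = paste0(day, ":", rep), day_id = day,
                 replicate_id = rep),
            class = "log_fluor_estimate")
}

# bead_summary built from exact values (no sampling)
fake_bead_summary <- function(mean_I, var_I, n = 10000L) {
  out <- tibble::tibble(label = sprintf("pop%d", seq_along(mean_I)),
                        mean_I = mean_I, var_I = var_I,
                        cv2 = var_I / mean_I^2, n = n)
  class(out) <- c("bead_summary", class(out))
  out
}

quiet_fit <- function(...) suppressWarnings(suppressMessages(fit_log_fluor_mixture(...)))

gate_and_fit <- function(events, threshold = 0.5) {
  model <- fit_scatter_mixture(events)
  flt <- filter_events(events, gate_posteriors(model, events), threshold = threshold)
  list(model = model, filtered = flt, estimate = quiet_fit(flt$events))
}
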