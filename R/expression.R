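#' Estimate mean and variance of log-fluorescence
#'
#' Across an isogenic population, single-cell fluorescence is well described
#' by a lognormal distribution, so the log-fluorescence is fitted with a
#' Gaussian. Residual outlying events (doublets, debris that survived
#' gating) are absorbed by a uniform component on the observed log range, and
#' the mixture is fitted by expectation-maximization. The estimate carries
#' standard errors and the linear-scale moments implied by the lognormal.
#'
#' Standard errors are Gaussian sampling errors weighted by the soft outlier
#' assignment: `sigma_mu = sqrt(v / n_eff)` and
#' `sigma_v = v * sqrt(2 / (n_eff - 1))`, where `n_eff` is the summed
#' responsibility of the Gaussian component.
#'
#' Non-positive values cannot be log-transformed and are dropped with a
#' logged count. If all remaining values are identical the fit degenerates to
#' `v = 0` with a warning (not an error).
#'
#' @param fl_values numeric vector of fluorescence pulse heights, or an
#'   [event_table()] (its `fl_h` channel is used).
#' @param config an [em_config()].
#' @param sample_id,day_id,replicate_id provenance labels attached to the
#'   estimate (used by [aggregate_autofluorescence()]).
#' @return A `log_fluor_estimate`: `mu`, `v`, `sigma_mu`, `sigma_v`,
#'   `pi_good`, `n_eff`, `n_used`, `n_dropped`, `mean_lin`, `var_lin`,
#'   `sigma_mean_lin`, `sigma_var_lin`, `converged`, `loglik_trace`, plus the
#'   provenance labels.
#' @export
fit_log_fluor_mixture <- function(fl_values, config = em_config(),
                                  sample_id = NA_character_,
                                  day_id = NA_character_,
                                  replicate_id = NA_character_) {
  if (inherits(fl_values, "event_table")) {
    sample_id <- if (is.na(sample_id)) attr(fl_values, "sample_id") else sample_id
    day_id <- if (is.na(day_id)) attr(fl_values, "day_id") else day_id
    replicate_id <- if (is.na(replicate_id)) attr(fl_values, "replicate_id") else replicate_id
    fl_values <- fl_values$fl_h
  }
  fl_values <- as.numeric(fl_values)
  n_raw <- length(fl_values)
  fl_values <- fl_values[is.finite(fl_values) & fl_values > 0]
  n_dropped <- n_raw - length(fl_values)
  if (n_dropped > 0L) {
    message("fit_log_fluor_mixture: dropped ", n_dropped,
            " non-positive or non-finite value(s)")
  }
  if (length(fl_values) < config$min_events) {
    stop("too few positive fluorescence values (", length(fl_values), " < ",
         config$min_events, ")", call. = FALSE)
  }
  lx <- log(fl_values)
  n <- length(lx)

  if (var(lx) == 0) {
    warning("all fluorescence values identical; returning a zero-variance estimate",
            call. = FALSE)
    return(new_log_fluor_estimate(mu = lx[1], v = 0, sigma_mu = 0, sigma_v = 0,
                                  pi_good = 1, n_eff = n, n_used = n,
                                  n_dropped = n_dropped, converged = TRUE,
                                  loglik_trace = numeric(0),
                                  sample_id = sample_id, day_id = day_id,
                                  replicate_id = replicate_id))
  }

  box <- matrix(range(lx), nrow = 2)
  fit <- fit_gu_mixture(matrix(lx, ncol = 1), box, pi_init = 0.95,
                        mu_init = median(lx), sigma_init = mad(lx)^2,
                        tol = config$tol, max_iter = config$max_iter)
  if (!fit$converged) {
    warning("log-fluorescence EM did not converge in ", config$max_iter,
            " iterations", call. = FALSE)
  }
  mu <- unname(fit$mu)
  v <- max(unname(fit$sigma[1, 1]), 0)
  n_eff <- fit$n_eff
  sigma_mu <- sqrt(v / n_eff)
  sigma_v <- v * sqrt(2 / (n_eff - 1))
  new_log_fluor_estimate(mu = mu, v = v, sigma_mu = sigma_mu, sigma_v = sigma_v,
                         pi_good = fit$pi_good, n_eff = n_eff, n_used = n,
                         n_dropped = n_dropped, converged = fit$converged,
                         loglik_trace = fit$loglik_trace,
                         sample_id = sample_id, day_id = day_id,
                         replicate_id = replicate_id)
}

new_log_fluor_estimate <- function(mu, v, sigma_mu, sigma_v, pi_good, n_eff,
                                   n_used, n_dropped, converged, loglik_trace,
                                   sample_id, day_id, replicate_id) {
  lin <- to_linear_moments(mu, v, sigma_mu, sigma_v)
  structure(c(list(mu = mu, v = v, sigma_mu = sigma_mu, sigma_v = sigma_v,
                   pi_good = pi_good, n_eff = n_eff, n_used = n_used,
                   n_dropped = n_dropped, converged = converged,
                   loglik_trace = loglik_trace,
                   sample_id = sample_id, day_id = day_id,
                   replicate_id = replicate_id),
              lin),
            class = "log_fluor_estimate")
}

#' @export
print.log_fluor_estimate <- function(x, ...) {
  cat("<log_fluor_estimate>\n")
  cat(sprintf("  log scale:    mu = %.4f +/- %.4f   v = %.4f +/- %.4f\n",
              x$mu, x$sigma_mu, x$v, x$sigma_v))
  cat(sprintf("  linear scale: mean = %.4g +/- %.3g   var = %.4g +/- %.3g\n",
              x$mean_lin, x$sigma_mean_lin, x$var_lin, x$sigma_var_lin))
  cat(sprintf("  pi_good = %.3f   n_eff = %.1f / %d events\n",
              x$pi_good, x$n_eff, x$n_used))
  invisible(x)
}

#' Lognormal back-transform of log-scale moments
#'
#' Converts a mean `mu` and variance `v` of log-fluorescence to the mean and
#' variance of the (linear-scale) lognormal distribution they imply:
#' `mean_lin = exp(mu + v/2)` and `var_lin = (exp(v) - 1) * exp(2*mu + v)`.
#' Standard errors are propagated to first order (delta method) treating `mu`
#' and `v` as independent.
#'
#' @param mu,v mean and variance of log-fluorescence; `v` must be >= 0.
#' @param sigma_mu,sigma_v standard errors of `mu` and `v`.
#' @return A list with `mean_lin`, `var_lin`, `sigma_mean_lin`,
#'   `sigma_var_lin`.
#' @export
to_linear_moments <- function(mu, v, sigma_mu = 0, sigma_v = 0) {
  if (!is.finite(mu) || !is.finite(v)) stop("mu and v must be finite", call. = FALSE)
  if (v < 0) stop("log-scale variance v must be non-negative", call. = FALSE)
  mean_lin <- exp(mu + v / 2)
  var_lin <- (exp(v) - 1) * exp(2 * mu + v)
  # d mean/d mu = mean; d mean/d v = mean/2
  sigma_mean_lin <- mean_lin * sqrt(sigma_mu^2 + sigma_v^2 / 4)
  # var = exp(2mu+2v) - exp(2mu+v); d var/d mu = 2*var; d var/d v = 2e^{2mu+2v} - e^{2mu+v}
  dv <- 2 * exp(2 * mu + 2 * v) - exp(2 * mu + v)
  sigma_var_lin <- sqrt((2 * var_lin * sigma_mu)^2 + (dv * sigma_v)^2)
  list(mean_lin = mean_lin, var_lin = var_lin,
       sigma_mean_lin = sigma_mean_lin, sigma_var_lin = sigma_var_lin)
}
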