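#' Fit the viable-cell / debris scatter mixture
#'
#' Separates viable cells from debris by fitting a mixture of a 4-dimensional
#' Gaussian and a uniform distribution to the forward- and side-scatter
#' heights and widths `(fsc_h, fsc_w, ssc_h, ssc_w)`. The Gaussian captures
#' the cluster of viable cells; the uniform component, supported on the
#' per-dimension data bounding box (fixed before EM), absorbs debris and other
#' outliers. Fitting is by expectation-maximization, initialized
#' deterministically from the coordinate-wise median and a trimmed covariance
#' (central 90% per dimension) with a Gaussian weight of 0.9.
#'
#' @param events an [event_table()].
#' @param config an [em_config()]; `config$log_transform = TRUE` fits on
#'   log-transformed channels.
#' @return A `scatter_gate_model` with elements `mu`, `sigma`, `pi_good`,
#'   `support_box` (2 x 4, `[min; max]`), `uniform_density`, `loglik_trace`,
#'   `converged`, `n_used` and `log_space`.
#' @seealso [gate_posteriors()], [filter_events()]
#' @export
fit_scatter_mixture <- function(events, config = em_config()) {
  x <- as.matrix(as_tibble(unclass_event_table(events))[.GATE_CHANNELS])
  if (nrow(x) < config$min_events) {
    stop("too few events to fit the scatter mixture (", nrow(x), " < ",
         config$min_events, ")", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("gating channels contain non-finite values", call. = FALSE)
  if (config$log_transform) x <- log(x)

  box <- apply(x, 2, range)
  mu0 <- apply(x, 2, median)
  sigma0 <- trimmed_cov(x)
  fit <- fit_gu_mixture(x, box, pi_init = 0.9, mu_init = mu0,
                        sigma_init = sigma0, tol = config$tol,
                        max_iter = config$max_iter)
  if (!fit$converged) {
    warning("scatter mixture EM did not converge in ", config$max_iter,
            " iterations", call. = FALSE)
  }
  structure(list(mu = fit$mu, sigma = fit$sigma, pi_good = fit$pi_good,
                 support_box = fit$box, uniform_density = exp(fit$log_u),
                 loglik_trace = fit$loglik_trace, converged = fit$converged,
                 n_used = fit$n, log_space = config$log_transform),
            class = "scatter_gate_model")
}

#' @export
print.scatter_gate_model <- function(x, ...) {
  cat("<scatter_gate_model>\n")
  cat(sprintf("  pi_good: %.4f   events fitted: %d   converged: %s\n",
              x$pi_good, x$n_used, x$converged))
  cat(sprintf("  final log-likelihood: %.2f (%d EM iterations)\n",
              x$loglik_trace[length(x$loglik_trace)], length(x$loglik_trace)))
  cat("  mu:", paste(sprintf("%s=%.3g", .GATE_CHANNELS, x$mu), collapse = ", "), "\n")
  invisible(x)
}

#' Per-event posterior probability of being a viable cell
#'
#' Computes, for each event, the posterior probability that it derives from
#' the Gaussian (viable-cell) component of a fitted scatter mixture:
#' `p_i = pi * N(x_i) / (pi * N(x_i) + (1 - pi) * u)` with `u` the uniform
#' density on the support box. Events outside the support box are scored
#' against the same uniform density level (extended, not zeroed), so far
#' outliers receive `p` near 0 rather than an undefined posterior.
#'
#' @param model a fitted `scatter_gate_model`.
#' @param events an [event_table()].
#' @return Numeric vector of posteriors in `[0, 1]`, one per event.
#' @export
gate_posteriors <- function(model, events) {
  if (!inherits(model, "scatter_gate_model")) {
    stop("gate_posteriors requires a fitted scatter_gate_model", call. = FALSE)
  }
  x <- as.matrix(as_tibble(unclass_event_table(events))[.GATE_CHANNELS])
  if (model$log_space) x <- log(x)
  dn <- log_dmvnorm(x, model$mu, model$sigma)
  lg <- log(model$pi_good) + dn$logd
  lu <- log1p(-model$pi_good) + log(model$uniform_density)
  1 / (1 + exp(lu - lg))
}

#' Filter events on their viable-cell posterior
#'
#' Retains exactly the events whose posterior probability of deriving from the
#' viable-cell component is at least `threshold` (default 0.5), preserving the
#' original event order.
#'
#' @param events an [event_table()].
#' @param posterior posterior vector from [gate_posteriors()], aligned with
#'   `events`.
#' @param threshold retention threshold in `[0, 1]`.
#' @return A list with `events` (the retained [event_table()]) and
#'   `retained_fraction`.
#' @export
filter_events <- function(events, posterior, threshold = 0.5) {
  if (length(posterior) != nrow(events)) {
    stop("posterior length (", length(posterior),
         ") does not match number of events (", nrow(events), ")", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  keep <- posterior >= threshold
  if (!any(keep)) stop("no events retained at threshold ", threshold, call. = FALSE)
  list(events = subset_events(events, keep),
       retained_fraction = mean(keep))
}
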