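# Expectation-maximization for a d-dimensional Gaussian + uniform mixture.
#
# The uniform component lives on a fixed axis-aligned box (by default the data
# bounding box, fixed before EM) and absorbs outliers; the Gaussian captures
# the dominant cluster. Shared by the 4D scatter gate and the 1D
# log-fluorescence fit.

# log N(x; mu, sigma) for rows of x; ridges sigma if Cholesky fails.
# Returns list(logd, sigma, chol) so callers see the regularized sigma.
log_dmvnorm <- function(x, mu, sigma) {
  d <- ncol(x)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-6 * mean(diag(sigma))
    if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-12
    sigma <- sigma + diag(ridge, d)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) {
      dim_bad <- which.min(diag(sigma))
      stop("singular covariance after regularization (dimension ",
           colnames(x)[dim_bad] %||% dim_bad, ")", call. = FALSE)
    }
  }
  z <- backsolve(ch, t(x) - mu, transpose = TRUE)
  logd <- -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
  list(logd = logd, sigma = sigma, chol = ch)
}

# EM driver. x: n x d matrix; box: 2 x d matrix of [min; max] per dimension.
fit_gu_mixture <- function(x, box, pi_init, mu_init, sigma_init,
                           tol = 1e-8, max_iter = 500L) {
  x <- as.matrix(x)
  n <- nrow(x)
  widths <- box[2, ] - box[1, ]
  if (any(widths <= 0)) stop("degenerate uniform support box", call. = FALSE)
  log_u <- -sum(log(widths))

  pi_g <- min(max(pi_init, 1e-6), 1 - 1e-6)
  mu <- mu_init
  sigma <- as.matrix(sigma_init)
  ll_trace <- numeric(0)
  converged <- FALSE
  ll_old <- NA_real_
  r <- rep(1, n)

  for (it in seq_len(max_iter)) {
    dn <- log_dmvnorm(x, mu, sigma)
    sigma <- dn$sigma
    lg <- log(pi_g) + dn$logd
    lu <- log1p(-pi_g) + log_u
    m <- pmax(lg, lu)
    ll_i <- m + log(exp(lg - m) + exp(lu - m))
    ll <- sum(ll_i)
    ll_trace <- c(ll_trace, ll)
    r <- exp(lg - ll_i)
    if (!is.na(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    sr <- sum(r)
    pi_g <- min(max(sr / n, 1e-12), 1 - 1e-12)
    mu <- colSums(r * x) / sr
    xc <- sweep(x, 2, mu)
    sigma <- crossprod(xc * sqrt(r)) / sr
  }
  list(pi_good = pi_g, mu = mu, sigma = sigma, box = box, log_u = log_u,
       loglik_trace = ll_trace, converged = converged, resp = r,
       n_eff = sum(r), n = n)
}

# total log-likelihood of the mixture at given parameters (used by tests and
# by the grid-search oracle comparisons)
gu_mixture_loglik <- function(x, box, pi_good, mu, sigma) {
  x <- as.matrix(x)
  log_u <- -sum(log(box[2, ] - box[1, ]))
  dn <- log_dmvnorm(x, mu, sigma)
  lg <- log(pi_good) + dn$logd
  lu <- log1p(-pi_good) + log_u
  m <- pmax(lg, lu)
  sum(m + log(exp(lg - m) + exp(lu - m)))
}

# trimmed covariance: rows inside the central 90% of every dimension
trimmed_cov <- function(x, trim = 0.05) {
  keep <- rep(TRUE, nrow(x))
  for (j in seq_len(ncol(x))) {
    q <- quantile(x[, j], c(trim, 1 - trim), names = FALSE)
    keep <- keep & x[, j] >= q[1] & x[, j] <= q[2]
  }
  if (sum(keep) < ncol(x) + 1L) keep <- rep(TRUE, nrow(x))
  cov(x[keep, , drop = FALSE])
}

#' EM configuration
#'
#' Tolerances and limits shared by the scatter-gate and log-fluorescence
#' mixture fits. Convergence is declared when the relative change in total
#' log-likelihood falls below `tol`.
#'
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations; non-convergence returns the model
#'   with `converged = FALSE` and a warning.
#' @param min_events minimum number of events required to fit.
#' @param log_transform fit the scatter mixture on log-transformed channels
#'   (off by default; raw instrument values are fitted as reported).
#' @return A list of class `em_config`.
#' @export
em_config <- function(tol = 1e-8, max_iter = 500L, min_events = 50L,
                      log_transform = FALSE) {
  stopifnot(tol > 0, max_iter >= 1, min_events >= 1)
  structure(list(tol = tol, max_iter = max_iter,
                 min_events = as.integer(min_events),
                 log_transform = isTRUE(log_transform)),
            class = "em_config")
}
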