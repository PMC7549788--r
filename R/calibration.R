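#' Aggregate autofluorescence estimates across replicates and days
#'
#' Non-expressing (autofluorescence) strains are measured in replicate on
#' several days. Within each day, the replicate estimates of the linear-scale
#' mean and variance are combined by inverse-variance weighting; when the
#' between-replicate scatter exceeds what the within-replicate errors
#' predict, a between-replicate variance component (DerSimonian-Laird
#' random-effects estimator) inflates the day-level error. Days are then
#' combined into overall estimates of the measured autofluorescence mean
#' `<A_M>` and variance `var(A_M)` by the same rule.
#'
#' Outlier replicates are never excluded automatically: exclusion is an
#' explicit user input (a visibly contaminated well, say), given as
#' `"day:replicate"` labels.
#'
#' @param estimates list of [fit_log_fluor_mixture()] results, each carrying
#'   non-missing `day_id` and `replicate_id` labels.
#' @param exclusions character vector of `"day:replicate"` labels to drop.
#' @return An `autofluorescence_model` with `per_replicate` and `per_day`
#'   tibbles, `overall_mean`, `se_overall_mean`, `overall_var`,
#'   `se_overall_var`, and the honored `excluded` labels.
#' @export
aggregate_autofluorescence <- function(estimates, exclusions = character()) {
  if (length(estimates) == 0L) stop("no autofluorescence estimates supplied", call. = FALSE)
  rows <- lapply(estimates, function(e) {
    if (!inherits(e, "log_fluor_estimate")) {
      stop("estimates must be log_fluor_estimate objects", call. = FALSE)
    }
    if (is.na(e$day_id) || is.na(e$replicate_id)) {
      stop("every estimate needs day_id and replicate_id labels", call. = FALSE)
    }
    bad <- vapply(c("mean_lin", "var_lin", "sigma_mean_lin", "sigma_var_lin"),
                  function(f) is.null(e[[f]]) || !is.finite(e[[f]]), logical(1))
    if (any(bad)) {
      stop("estimate ", e$day_id, ":", e$replicate_id,
           " is missing linear-scale moments or error bars", call. = FALSE)
    }
    tibble(day_id = as.character(e$day_id),
           replicate_id = as.character(e$replicate_id),
           label = paste0(e$day_id, ":", e$replicate_id),
           mean = e$mean_lin, se_mean = e$sigma_mean_lin,
           var = e$var_lin, se_var = e$sigma_var_lin)
  })
  per_replicate <- do.call(rbind, rows)
  per_replicate$excluded <- per_replicate$label %in% exclusions
  if (all(per_replicate$excluded)) {
    stop("all replicates excluded; nothing to aggregate", call. = FALSE)
  }
  used <- per_replicate[!per_replicate$excluded, , drop = FALSE]

  per_day <- do.call(rbind, lapply(split(used, used$day_id), function(d) {
    m <- re_combine(d$mean, d$se_mean)
    v <- re_combine(d$var, d$se_var)
    tibble(day_id = d$day_id[1], mean = m$est, se_mean = m$se,
           var = v$est, se_var = v$se, n_replicates = nrow(d))
  }))
  om <- re_combine(per_day$mean, per_day$se_mean)
  ov <- re_combine(per_day$var, per_day$se_var)

  structure(list(per_replicate = per_replicate, per_day = per_day,
                 overall_mean = om$est, se_overall_mean = om$se,
                 overall_var = ov$est, se_overall_var = ov$se,
                 excluded = exclusions),
            class = "autofluorescence_model")
}

# random-effects (DerSimonian-Laird) inverse-variance combination
re_combine <- function(y, se) {
  stopifnot(length(y) == length(se), length(y) >= 1)
  if (length(y) == 1L) return(list(est = y, se = se))
  se <- pmax(se, 1e-12 * max(abs(y), 1)) # guard exact-zero errors in fixtures
  fit <- metafor::rma(yi = y, sei = se, method = "DL")
  list(est = as.numeric(fit$b), se = as.numeric(fit$se))
}

#' @export
print.autofluorescence_model <- function(x, ...) {
  cat("<autofluorescence_model>\n")
  cat(sprintf("  overall mean <A_M> = %.4g +/- %.3g\n", x$overall_mean, x$se_overall_mean))
  cat(sprintf("  overall var(A_M)  = %.4g +/- %.3g\n", x$overall_var, x$se_overall_var))
  cat(sprintf("  %d day(s), %d replicate(s), %d excluded\n", nrow(x$per_day),
              nrow(x$per_replicate), sum(x$per_replicate$excluded)))
  invisible(x)
}

#' Summarize calibration-bead populations
#'
#' Computes the measured mean, variance and CV^2 of the fluorescence height
#' for each bead population. A Gaussian+uniform mixture (the same
#' outlier-robust fitter used for expression estimates) guards against
#' doublets and stray events; by default it is fitted on the linear scale,
#' which is moment-faithful for the tight, offset-shifted bead populations,
#' with a log-scale option.
#'
#' @param populations a list of [event_table()]s or numeric fluorescence
#'   vectors, one per bead population; or a single event_table plus `labels`.
#' @param labels per-event population labels (when a single table is given) or
#'   per-population names.
#' @param scale `"linear"` (default) or `"log"` mixture fit; `"moments"` skips
#'   the robust fit and uses plain sample moments.
#' @param config an [em_config()].
#' @return A tibble of class `bead_summary` with columns `label`, `mean_I`,
#'   `var_I`, `cv2`, `n`.
#' @export
summarize_beads <- function(populations, labels = NULL,
                            scale = c("linear", "log", "moments"),
                            config = em_config()) {
  scale <- match.arg(scale)
  if (inherits(populations, "event_table") || is.numeric(populations)) {
    if (is.null(labels) || length(labels) != NROW(populations)) {
      stop("a single event table requires per-event labels", call. = FALSE)
    }
    fl <- if (inherits(populations, "event_table")) populations$fl_h else populations
    populations <- split(fl, labels)
  }
  if (length(populations) < 2L) {
    stop("shot-noise calibration is underdetermined with fewer than 2 bead populations",
         call. = FALSE)
  }
  if (is.null(names(populations))) {
    names(populations) <- labels %||% sprintf("pop%d", seq_along(populations))
  }
  rows <- lapply(names(populations), function(nm) {
    p <- populations[[nm]]
    fl <- if (inherits(p, "event_table")) p$fl_h else as.numeric(p)
    fl <- fl[is.finite(fl) & fl > 0]
    if (length(fl) < config$min_events) {
      stop("bead population '", nm, "' has fewer than ", config$min_events,
           " usable events", call. = FALSE)
    }
    keep <- rep(TRUE, length(fl))
    if (scale != "moments") {
      # the mixture guards against doublets and stray events: fit it, then
      # retain events whose Gaussian posterior is >= 0.5 (the same rule as
      # the scatter gate) and take plain moments of the retained events, so
      # the genuine tails of a skewed bead population are not down-weighted
      y <- if (scale == "log") log(fl) else fl
      box <- matrix(range(y), nrow = 2)
      fit <- fit_gu_mixture(matrix(y, ncol = 1), box, pi_init = 0.95,
                            mu_init = median(y), sigma_init = mad(y)^2,
                            tol = config$tol, max_iter = config$max_iter)
      keep <- fit$resp >= 0.5
      if (sum(keep) < config$min_events) keep <- rep(TRUE, length(fl))
    }
    tibble(label = nm, mean_I = mean(fl[keep]), var_I = var(fl[keep]),
           cv2 = var(fl[keep]) / mean(fl[keep])^2, n = sum(keep))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bead_summary", class(out))
  out
}

#' Shot-noise calibration by simple linear fit
#'
#' Under the shot-noise model `I_M = I_T + eps * sqrt(I_T) + O` with
#' `eps ~ N(0, delta^2)`, and ignoring the true variability of the beads, the
#' measured CV^2 of a bead population obeys
#' `CV2_M = delta^2 / <I_M> - delta^2 * O / <I_M>^2`. Writing
#' `Y = CV2_M * <I_M>` and `X = 1 / <I_M>` this is the line
#' `Y = delta^2 - delta^2 * O * X`, so regressing Y on X across bead
#' populations yields `delta^2` as the intercept and `-delta^2 * O` as the
#' slope.
#'
#' @param summaries a [summarize_beads()] result (>= 2 populations with
#'   distinct means).
#' @return A `shot_noise_model` with `delta`, `offset_O`, `sigma_delta`,
#'   `sigma_offset` (regression-based; `NA` with only 2 populations) and
#'   `method = "simple_linear"`.
#' @export
fit_shot_noise_simple <- function(summaries) {
  check_bead_summaries(summaries, min_pop = 2L)
  Y <- summaries$cv2 * summaries$mean_I
  X <- 1 / summaries$mean_I
  fit <- lm(Y ~ X)
  d2 <- unname(coef(fit)[1])
  slope <- unname(coef(fit)[2])
  if (d2 <= 0) {
    stop("simple shot-noise fit produced a non-positive delta^2; ",
         "the beads' true variability is probably not negligible - ",
         "use fit_shot_noise_shared_cv2()", call. = FALSE)
  }
  delta <- sqrt(d2)
  offset <- -slope / d2
  V <- vcov(fit)
  sigma_delta <- sqrt(V[1, 1]) / (2 * delta)
  grad <- c(slope / d2^2, -1 / d2) # d offset / d(intercept, slope)
  sigma_offset <- sqrt(drop(t(grad) %*% V %*% grad))
  shot_noise_model(delta = delta, offset_O = offset,
                   sigma_delta = sigma_delta, sigma_offset = sigma_offset,
                   method = "simple_linear")
}

#' Shot-noise calibration assuming a shared true bead CV^2
#'
#' Rather than ignoring the beads' own variability, this variant assumes the
#' true intensities of all three bead populations share a common CV^2 `c`.
#' With true means `m_b`, the shot-noise model implies the exactly-identified
#' moment system
#' \deqn{\langle I_M \rangle_b = m_b + O, \quad
#'       var(I_M)_b = c\, m_b^2 + \delta^2 m_b, \quad b = 1,2,3,}
#' six equations for the six unknowns `(m_1, m_2, m_3, c, delta^2, O)`. The
#' solver eliminates `m_b = <I_M>_b - O`, reduces to a one-dimensional
#' root-find in `O` below the smallest measured mean, and solves linearly for
#' `(c, delta^2)`. Uncertainties come from a seeded nonparametric bootstrap
#' over events when the per-population event values are supplied.
#'
#' @param summaries a [summarize_beads()] result with exactly 3 populations
#'   of distinct means.
#' @param events optional list of 3 numeric vectors or [event_table()]s (the
#'   per-population events, in the same order) enabling the bootstrap.
#' @param n_boot bootstrap replicates.
#' @param seed bootstrap seed.
#' @return A `shot_noise_model` with `delta`, `offset_O`, `shared_cv2`, their
#'   uncertainties (bootstrap; `NA` without `events`), the recovered true
#'   means `m`, and `method = "shared_cv2_moments"`.
#' @export
fit_shot_noise_shared_cv2 <- function(summaries, events = NULL,
                                      n_boot = 200L, seed = 1L) {
  check_bead_summaries(summaries, min_pop = 3L, max_pop = 3L)
  sol <- solve_shared_cv2(summaries$mean_I, summaries$var_I)
  sigma <- list(delta = NA_real_, offset = NA_real_, cv2 = NA_real_)
  if (!is.null(events)) {
    if (length(events) != 3L) stop("events must list the 3 bead populations", call. = FALSE)
    fls <- lapply(events, function(p) {
      fl <- if (inherits(p, "event_table")) p$fl_h else as.numeric(p)
      fl[is.finite(fl) & fl > 0]
    })
    boots <- withr::with_seed(seed, {
      replicate(n_boot, {
        mom <- vapply(fls, function(fl) {
          idx <- sample.int(length(fl), replace = TRUE)
          c(mean(fl[idx]), var(fl[idx]))
        }, numeric(2))
        out <- tryCatch(solve_shared_cv2(mom[1, ], mom[2, ]),
                        error = function(e) NULL)
        if (is.null(out)) c(NA, NA, NA) else c(out$delta, out$offset, out$c)
      })
    })
    ok <- colSums(is.na(boots)) == 0
    if (sum(ok) >= 10L) {
      sigma <- list(delta = sd(boots[1, ok]), offset = sd(boots[2, ok]),
                    cv2 = sd(boots[3, ok]))
    } else {
      warning("too few successful bootstrap solves; uncertainties set to NA",
              call. = FALSE)
    }
  }
  shot_noise_model(delta = sol$delta, offset_O = sol$offset,
                   sigma_delta = sigma$delta, sigma_offset = sigma$offset,
                   shared_cv2 = sol$c, sigma_shared_cv2 = sigma$cv2,
                   m = sol$m, method = "shared_cv2_moments")
}

# moment-system solver: means_b = m_b + O, vars_b = c m_b^2 + delta^2 m_b
solve_shared_cv2 <- function(means, vars) {
  o <- order(means)
  means <- means[o]; vars <- vars[o]
  cd_at <- function(O) {
    x <- means - O
    A <- rbind(c(x[1]^2, x[1]), c(x[2]^2, x[2]))
    solve(A, vars[1:2])
  }
  g <- function(O) {
    x3 <- means[3] - O
    cd <- cd_at(O)
    vars[3] - cd[1] * x3^2 - cd[2] * x3
  }
  scale <- max(means)
  upper <- min(means) - 1e-9 * scale
  lower <- min(means) - 10 * scale
  Ogrid <- seq(lower, upper, length.out = 2048L)
  gv <- vapply(Ogrid, g, numeric(1))
  gv[!is.finite(gv)] <- NA_real_
  dsign <- diff(sign(gv))
  flips <- which(!is.na(dsign) & dsign != 0)
  cands <- list()
  for (i in flips) {
    root <- tryCatch(uniroot(g, c(Ogrid[i], Ogrid[i + 1L]), tol = 1e-10 * scale),
                     error = function(e) NULL)
    if (is.null(root)) next
    O <- root$root
    cd <- cd_at(O)
    # tolerate slightly negative c/delta^2 from sampling noise (a bead set
    # with true CV^2 near zero lands here about half the time); clamped below
    if (cd[1] >= -0.05 && cd[2] >= -1e-6 * scale && all(means - O > 0)) {
      cands[[length(cands) + 1L]] <- list(offset = O, c = max(cd[1], 0),
                                          delta = sqrt(max(cd[2], 0)),
                                          m = means - O)
    }
  }
  if (length(cands) == 0L) {
    stop("no admissible solution (m_b > 0, c >= 0, delta^2 >= 0) to the ",
         "shared-CV^2 moment system; calibration failed", call. = FALSE)
  }
  # generically unique; if sampling noise yields several admissible roots,
  # take the one closest to the data (largest offset)
  cands[[which.max(vapply(cands, `[[`, numeric(1), "offset"))]]
}

check_bead_summaries <- function(summaries, min_pop, max_pop = Inf) {
  if (!inherits(summaries, "bead_summary")) {
    stop("expected a summarize_beads() result", call. = FALSE)
  }
  k <- nrow(summaries)
  if (k < min_pop || k > max_pop) {
    stop("this calibration needs ",
         if (is.finite(max_pop)) paste("exactly", max_pop) else paste("at least", min_pop),
         " bead populations (got ", k, ")", call. = FALSE)
  }
  rel <- outer(summaries$mean_I, summaries$mean_I,
               function(a, b) abs(a - b) / pmax(a, b))
  if (any(rel[upper.tri(rel)] < 1e-6)) {
    stop("bead populations with indistinguishable means make the calibration singular",
         call. = FALSE)
  }
  invisible(summaries)
}

#' Construct a shot-noise model
#'
#' Mostly produced by the calibration fits; constructing one by hand (e.g.
#' `shot_noise_model(delta = 0)`) is the explicit way to skip the shot-noise
#' correction in [correct_variance()].
#'
#' @param delta shot-noise strength (square-root intensity units); >= 0.
#' @param offset_O additive digitizer offset (intensity units).
#' @param sigma_delta,sigma_offset uncertainties.
#' @param shared_cv2,sigma_shared_cv2 common true bead CV^2 (moment variant).
#' @param m recovered true bead means (moment variant).
#' @param method calibration method label.
#' @return A `shot_noise_model` list.
#' @export
shot_noise_model <- function(delta, offset_O = 0, sigma_delta = NA_real_,
                             sigma_offset = NA_real_, shared_cv2 = NULL,
                             sigma_shared_cv2 = NA_real_, m = NULL,
                             method = "manual") {
  if (!is.finite(delta) || delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (!is.null(shared_cv2) && shared_cv2 < 0) stop("shared_cv2 must be >= 0", call. = FALSE)
  structure(list(delta = delta, offset_O = offset_O,
                 sigma_delta = sigma_delta, sigma_offset = sigma_offset,
                 shared_cv2 = shared_cv2, sigma_shared_cv2 = sigma_shared_cv2,
                 m = m, method = method),
            class = "shot_noise_model")
}

#' @export
print.shot_noise_model <- function(x, ...) {
  cat("<shot_noise_model> method:", x$method, "\n")
  cat(sprintf("  delta = %.3f +/- %s   O = %.2f +/- %s\n", x$delta,
              fmt_or_na(x$sigma_delta), x$offset_O, fmt_or_na(x$sigma_offset)))
  if (!is.null(x$shared_cv2)) {
    cat(sprintf("  shared true bead CV^2 = %.4g +/- %s\n", x$shared_cv2,
                fmt_or_na(x$sigma_shared_cv2)))
  }
  invisible(x)
}

fmt_or_na <- function(x) if (is.na(x)) "NA" else sprintf("%.3g", x)
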