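# Correcting measured fluorescence moments for autofluorescence and shot
# noise, and decomposing expression noise into concentration and volume
# components. All error propagation is first-order (delta method) with
# independent inputs: reporter, autofluorescence and bead measurements come
# from separate samples.

#' Correct a measured mean for autofluorescence
#'
#' `<I_T> = <I_M> - <A_M>`: the measured autofluorescence mean (which
#' includes the digitizer offset) is subtracted from the measured reporter
#' mean, cancelling both the autofluorescence and the offset. Errors add in
#' quadrature. A non-positive result is flagged (`below_autofluorescence`)
#' but still returned, since averaging over replicates downstream can remain
#' unbiased.
#'
#' @param mean_M measured reporter mean.
#' @param mean_A measured autofluorescence mean.
#' @param sigma_mean_M,sigma_mean_A standard errors.
#' @return List with `mean_T`, `sigma_mean_T`, `flags`.
#' @export
correct_mean <- function(mean_M, mean_A, sigma_mean_M = 0, sigma_mean_A = 0) {
  stopifnot(is.finite(mean_M), is.finite(mean_A),
            is.finite(sigma_mean_M), is.finite(sigma_mean_A))
  mean_T <- mean_M - mean_A
  flags <- character(0)
  if (mean_T <= 0) flags <- "below_autofluorescence"
  list(mean_T = mean_T,
       sigma_mean_T = sqrt(sigma_mean_M^2 + sigma_mean_A^2),
       flags = flags)
}

#' Correct a measured variance for autofluorescence and shot noise
#'
#' `var(I_T) = var(I_M) - var(A_M) - delta^2 * <I_T>`. The shot-noise term
#' must come from an explicit [shot_noise_model()]; pass
#' `shot_noise_model(delta = 0)` to deliberately skip the shot-noise
#' correction (which reduces the formula to plain autofluorescence
#' subtraction). Negative corrected variances are clamped to zero with a
#' `negative_variance_clamped` flag rather than erroring, so that
#' high-throughput screens degrade gracefully.
#'
#' @param var_M measured reporter variance.
#' @param var_A measured autofluorescence variance.
#' @param shot_noise a [shot_noise_model()].
#' @param mean_T corrected mean from [correct_mean()].
#' @param sigma_var_M,sigma_var_A,sigma_mean_T standard errors.
#' @return List with `var_T`, `sigma_var_T`, `flags`.
#' @export
correct_variance <- function(var_M, var_A, shot_noise, mean_T,
                             sigma_var_M = 0, sigma_var_A = 0,
                             sigma_mean_T = 0) {
  if (missing(shot_noise) || !inherits(shot_noise, "shot_noise_model")) {
    stop("correct_variance requires a shot_noise_model; pass ",
         "shot_noise_model(delta = 0) to skip the shot-noise correction",
         call. = FALSE)
  }
  stopifnot(is.finite(var_M), is.finite(var_A), is.finite(mean_T))
  delta <- shot_noise$delta
  sigma_delta <- if (is.finite(shot_noise$sigma_delta)) shot_noise$sigma_delta else 0
  var_T <- var_M - var_A - delta^2 * mean_T
  sigma_var_T <- sqrt(sigma_var_M^2 + sigma_var_A^2 +
                        (2 * delta * mean_T * sigma_delta)^2 +
                        (delta^2 * sigma_mean_T)^2)
  flags <- character(0)
  if (var_T < 0) {
    flags <- "negative_variance_clamped"
    var_T <- 0
  }
  list(var_T = var_T, sigma_var_T = sigma_var_T, flags = flags)
}

#' Fully corrected expression estimate for one sample
#'
#' Convenience wrapper combining [correct_mean()] and [correct_variance()]
#' for a fitted reporter sample, an aggregated autofluorescence model and a
#' shot-noise calibration, and computing the corrected noise
#' `CV^2 = var(I_T) / <I_T>^2` with propagated error.
#'
#' A warning is emitted when the measured reporter mean does not exceed the
#' autofluorescence mean: at such low signal the detector response is not
#' trustworthy and no correction can rescue the estimate.
#'
#' @param estimate a [fit_log_fluor_mixture()] result for the reporter.
#' @param autofluor an [aggregate_autofluorescence()] model.
#' @param shot_noise a [shot_noise_model()].
#' @return A `corrected_expression` with `mean_T`, `var_T`, `cv2_I`,
#'   `sigma_mean_T`, `sigma_var_T`, `sigma_cv2` and accumulated `flags`.
#' @export
correct_expression <- function(estimate, autofluor, shot_noise) {
  stopifnot(inherits(estimate, "log_fluor_estimate"),
            inherits(autofluor, "autofluorescence_model"))
  if (estimate$mean_lin <= autofluor$overall_mean) {
    warning("measured mean does not exceed the autofluorescence mean; ",
            "the corrected estimate is outside the method's validity range",
            call. = FALSE)
  }
  cm <- correct_mean(estimate$mean_lin, autofluor$overall_mean,
                     estimate$sigma_mean_lin, autofluor$se_overall_mean)
  cv <- correct_variance(estimate$var_lin, autofluor$overall_var, shot_noise,
                         cm$mean_T, estimate$sigma_var_lin,
                         autofluor$se_overall_var, cm$sigma_mean_T)
  flags <- c(cm$flags, cv$flags)
  if (cm$mean_T > 0) {
    cv2 <- cv$var_T / cm$mean_T^2
    # gradient of v/m^2: (1/m^2, -2v/m^3)
    sigma_cv2 <- sqrt((cv$sigma_var_T / cm$mean_T^2)^2 +
                        (2 * cv$var_T * cm$sigma_mean_T / cm$mean_T^3)^2)
  } else {
    cv2 <- NA_real_
    sigma_cv2 <- NA_real_
  }
  structure(list(mean_T = cm$mean_T, var_T = cv$var_T, cv2_I = cv2,
                 sigma_mean_T = cm$sigma_mean_T, sigma_var_T = cv$sigma_var_T,
                 sigma_cv2 = sigma_cv2, flags = flags,
                 sample_id = estimate$sample_id),
            class = "corrected_expression")
}

#' @export
print.corrected_expression <- function(x, ...) {
  cat("<corrected_expression>",
      if (!is.na(x$sample_id)) paste0("sample: ", x$sample_id), "\n")
  cat(sprintf("  <I_T> = %.4g +/- %.3g   var(I_T) = %.4g +/- %.3g\n",
              x$mean_T, x$sigma_mean_T, x$var_T, x$sigma_var_T))
  cat(sprintf("  CV^2_I = %.4g +/- %.3g\n", x$cv2_I, x$sigma_cv2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Concentration noise from total-intensity and volume noise
#'
#' Total intensity factorizes as `I = C * V` (concentration times volume)
#' with `C` and `V` fluctuating independently, so
#' `CV2_I = CV2_C + CV2_V + CV2_C * CV2_V`. Inverting for the concentration
#' noise:
#' `CV2_C = CV2_I / (1 + CV2_V) - CV2_V / (1 + CV2_V)`.
#' A negative result (total noise below volume noise) is flagged with a
#' warning but reported unclamped for diagnostics.
#'
#' @param cv2_I total-intensity noise (squared CV), >= 0.
#' @param cv2_V cell-volume noise, >= 0; must come from independent
#'   measurements (no size-from-scatter estimator is provided, as scatter is
#'   a non-linear, setup-specific and shot-noise-laden function of size).
#' @return `cv2_C`, the concentration noise.
#' @export
concentration_cv2 <- function(cv2_I, cv2_V) {
  stopifnot(cv2_I >= 0, cv2_V >= 0)
  out <- cv2_I / (1 + cv2_V) - cv2_V / (1 + cv2_V)
  if (any(out < 0)) {
    warning("total noise is below volume noise; concentration CV^2 is negative",
            call. = FALSE)
  }
  out
}

#' Total-intensity noise from its components
#'
#' The exact inverse of [concentration_cv2()]:
#' `CV2_I = CV2_C + CV2_V + CV2_C * CV2_V` for independent concentration and
#' volume fluctuations.
#'
#' @param cv2_C,cv2_V concentration and volume noise, >= 0.
#' @return `cv2_I`.
#' @export
total_cv2_from_components <- function(cv2_C, cv2_V) {
  stopifnot(cv2_C >= 0, cv2_V >= 0)
  cv2_C + cv2_V + cv2_C * cv2_V
}

#' Difference in concentration noise between two reporters
#'
#' Since all reporter strains share the same cell-volume distribution, the
#' difference in concentration noise between two reporters is directly
#' proportional to the difference in their total-intensity noise:
#' `dCV2_C = (CV2_I_a - CV2_I_b) / (1 + CV2_V)`. When the volume noise is
#' unknown, pass `cv2_V = 0`: volume noise is small in practice, so this
#' yields a reasonable estimate of the relative noise difference.
#'
#' @param cv2_I_a,cv2_I_b total-intensity noise of the two reporters.
#' @param cv2_V shared volume noise (default 0).
#' @return `dcv2_C`.
#' @export
delta_concentration_cv2 <- function(cv2_I_a, cv2_I_b, cv2_V = 0) {
  stopifnot(cv2_I_a >= 0, cv2_I_b >= 0, cv2_V >= 0)
  (cv2_I_a - cv2_I_b) / (1 + cv2_V)
}
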