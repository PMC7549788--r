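#' Specification of a synthetic cytometry population
#'
#' Describes the full generative model of a measured bacterial population:
#' total true fluorescence is the product `I_T = C * V` of a lognormal GFP
#' concentration and an independent lognormal cell volume; a lognormal
#' autofluorescence `A_T` adds to it; the instrument measures
#' `fl_h = I_T + A_T + eps * sqrt(I_T + A_T) + O` with photomultiplier shot
#' noise `eps ~ N(0, delta^2)` and digitizer offset `O`. Viable cells draw
#' their four scatter channels from a multivariate Gaussian; debris events
#' draw all five channels uniformly from `debris_box`.
#'
#' Defaults describe a realistic acquisition: 5e4 recorded events, mean
#' expression well above an autofluorescence of 1000 a.u. (20% CV),
#' calibration-scale shot noise `delta = 12` and offset `O = 100`, 10%
#' debris, and a viable-cell scatter cluster with 10% CV and 0.3
#' equicorrelation, with debris spread uniformly up to 3x the cluster center.
#'
#' @param n_events number of events to record.
#' @param mean_C,cv2_C mean and squared CV of the GFP concentration
#'   (lognormal); `mean_C = 0` gives a non-expressing (autofluorescence-only)
#'   strain.
#' @param mean_V,cv2_V mean and squared CV of cell volume (lognormal,
#'   independent of `C`).
#' @param auto_mean,auto_var true autofluorescence moments (lognormal).
#' @param delta,offset_O shot-noise strength and digitizer offset.
#' @param debris_fraction expected fraction of debris events, in `[0, 1)`.
#' @param scatter_mu,scatter_sigma viable-cell scatter Gaussian (4-vector and
#'   4x4 SPD matrix over `fsc_h, fsc_w, ssc_h, ssc_w`).
#' @param debris_box 2 x 5 matrix (`[min; max]` rows) of uniform debris
#'   support over the four scatter channels plus `fl_h`.
#' @param seed RNG seed making the simulation fully reproducible.
#' @return A validated list of class `population_spec`.
#' @export
population_spec <- function(n_events = 5e4,
                            mean_C = 40, cv2_C = 0.1,
                            mean_V = 50, cv2_V = 0.01,
                            auto_mean = 1000, auto_var = 40000,
                            delta = 12, offset_O = 100,
                            debris_fraction = 0.1,
                            scatter_mu = c(fsc_h = 25000, fsc_w = 65,
                                           ssc_h = 18000, ssc_w = 60),
                            scatter_sigma = NULL,
                            debris_box = NULL,
                            seed = 1L) {
  if (is.null(scatter_sigma)) {
    sds <- 0.10 * scatter_mu
    R <- matrix(0.3, 4, 4); diag(R) <- 1
    scatter_sigma <- diag(sds) %*% R %*% diag(sds)
    dimnames(scatter_sigma) <- list(names(scatter_mu), names(scatter_mu))
  }
  if (is.null(debris_box)) {
    fl_hi <- 3 * (auto_mean + mean_C * mean_V + offset_O)
    debris_box <- rbind(lo = c(rep(1e-3, 4), 20),
                        hi = c(3 * scatter_mu, fl_hi))
    colnames(debris_box) <- c(names(scatter_mu), "fl_h")
  }
  spec <- list(n_events = as.integer(n_events), mean_C = mean_C, cv2_C = cv2_C,
               mean_V = mean_V, cv2_V = cv2_V, auto_mean = auto_mean,
               auto_var = auto_var, delta = delta, offset_O = offset_O,
               debris_fraction = debris_fraction, scatter_mu = scatter_mu,
               scatter_sigma = scatter_sigma, debris_box = debris_box,
               seed = as.integer(seed))
  validate_population_spec(spec)
  structure(spec, class = "population_spec")
}

validate_population_spec <- function(s) {
  with(s, {
    if (n_events < 1) stop("n_events must be >= 1", call. = FALSE)
    if (mean_C < 0 || mean_V <= 0) stop("mean_C must be >= 0 and mean_V > 0", call. = FALSE)
    if (cv2_C < 0 || cv2_V < 0 || auto_var < 0) stop("variances must be >= 0", call. = FALSE)
    if (auto_mean < 0) stop("auto_mean must be >= 0", call. = FALSE)
    if (delta < 0) stop("delta must be >= 0", call. = FALSE)
    if (debris_fraction < 0 || debris_fraction >= 1) {
      stop("debris_fraction must lie in [0, 1)", call. = FALSE)
    }
    if (length(scatter_mu) != 4) stop("scatter_mu must have length 4", call. = FALSE)
    ev <- eigen(scatter_sigma, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("scatter_sigma must be positive definite", call. = FALSE)
    if (!all(dim(debris_box) == c(2, 5)) || any(debris_box[2, ] <= debris_box[1, ])) {
      stop("debris_box must be a 2 x 5 [min; max] matrix with positive widths",
           call. = FALSE)
    }
  })
  invisible(s)
}

# lognormal draws with a given mean and squared CV; cv2 = 0 gives constants
rlnorm_mcv2 <- function(n, mean, cv2) {
  if (mean == 0) return(numeric(n) + 0)
  if (cv2 == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a measured cytometry population with ground truth
#'
#' Draws events from the generative model described by a
#' [population_spec()]: latent concentration, volume and autofluorescence for
#' viable cells, shot noise and offset on the measured fluorescence, a 4D
#' Gaussian scatter cluster, and uniformly distributed debris in all five
#' channels. The number of debris events is binomial in `debris_fraction`
#' and the output order is shuffled, all deterministically in `spec$seed`.
#' Measured fluorescence is floored at 1 a.u., mimicking the digitizer: the
#' rare floored events are exactly the kind of outlier the uniform mixture
#' component is there to absorb.
#'
#' @param spec a [population_spec()].
#' @param sample_id,day_id,replicate_id provenance labels for the event table.
#' @return A list with `events` (an [event_table()]) and `truth`, a tibble
#'   aligned with `events` carrying `viable`, `I_T` and `A_T` per event.
#' @export
simulate_population <- function(spec, sample_id = "synthetic",
                                day_id = NA_character_,
                                replicate_id = NA_character_) {
  validate_population_spec(spec)
  withr::with_seed(spec$seed, {
    n <- spec$n_events
    n_debris <- rbinom(1L, n, spec$debris_fraction)
    n_viable <- n - n_debris

    C <- rlnorm_mcv2(n_viable, spec$mean_C, spec$cv2_C)
    V <- rlnorm_mcv2(n_viable, spec$mean_V, spec$cv2_V)
    I_T <- C * V
    A_T <- rlnorm_mcv2(n_viable, spec$auto_mean,
                       if (spec$auto_mean > 0) spec$auto_var / spec$auto_mean^2 else 0)
    tot <- I_T + A_T
    eps <- rnorm(n_viable, 0, spec$delta)
    fl <- tot + eps * sqrt(tot) + spec$offset_O
    scatter <- MASS::mvrnorm(n_viable, spec$scatter_mu, spec$scatter_sigma)
    if (n_viable == 1L) scatter <- matrix(scatter, nrow = 1)

    box <- spec$debris_box
    debris <- matrix(runif(5L * n_debris), nrow = n_debris, ncol = 5L)
    debris <- sweep(sweep(debris, 2, box[2, ] - box[1, ], `*`), 2, box[1, ], `+`)

    df <- tibble(
      fsc_h = c(scatter[, 1], debris[, 1]),
      fsc_w = c(scatter[, 2], debris[, 2]),
      ssc_h = c(scatter[, 3], debris[, 3]),
      ssc_w = c(scatter[, 4], debris[, 4]),
      fl_h = pmax(c(fl, debris[, 5]), 1))
    truth <- tibble(viable = rep(c(TRUE, FALSE), c(n_viable, n_debris)),
                    I_T = c(I_T, rep(NA_real_, n_debris)),
                    A_T = c(A_T, rep(NA_real_, n_debris)))
    ord <- sample.int(n)
    list(events = event_table(df[ord, ], sample_id = sample_id,
                              day_id = day_id, replicate_id = replicate_id),
         truth = truth[ord, ])
  })
}

#' Simulate calibration-bead measurements
#'
#' Each bead population has lognormal true intensities with mean `m_b` and a
#' CV^2 `c` shared across populations, measured through the shot-noise model
#' `I_M = I_T + eps * sqrt(I_T) + O`. Scatter channels are drawn from a
#' tight, fixed Gaussian (beads are uniform particles much larger than
#' bacteria; their scatter is not used by the calibration).
#'
#' @param m vector of true mean intensities, all > 0.
#' @param c shared true squared CV, >= 0.
#' @param delta,offset_O shot-noise strength and offset.
#' @param n events per population.
#' @param seed RNG seed.
#' @param labels population labels (default `pop1`, `pop2`, ...).
#' @return Named list of [event_table()]s, one per population.
#' @export
simulate_beads <- function(m, c = 0, delta = 12, offset_O = 100, n = 1e4,
                           seed = 1L, labels = NULL) {
  if (any(m <= 0)) stop("bead means must all be > 0", call. = FALSE)
  if (c < 0 || delta < 0 || n < 1) stop("invalid bead simulation parameters", call. = FALSE)
  labels <- labels %||% sprintf("pop%d", seq_along(m))
  bead_mu <- c(fsc_h = 30000, fsc_w = 70, ssc_h = 25000, ssc_w = 65)
  withr::with_seed(seed, {
    out <- lapply(seq_along(m), function(b) {
      I_T <- rlnorm_mcv2(n, m[b], c)
      fl <- I_T + rnorm(n, 0, delta) * sqrt(I_T) + offset_O
      scatter <- MASS::mvrnorm(n, bead_mu, diag((0.05 * bead_mu)^2))
      event_table(tibble(fsc_h = scatter[, 1], fsc_w = scatter[, 2],
                         ssc_h = scatter[, 3], ssc_w = scatter[, 4],
                         fl_h = pmax(fl, 1)),
                  sample_id = labels[b])
    })
    names(out) <- labels
    out
  })
}
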